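# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no data files.

# Small element (fast tests): 60-bp LTRs around a 380-bp internal region.
small_te <- function(id = "te1", family = "fam1", seed = 101) {
  with_seed(seed, te_element(id, family,
                             ltr = mobscan:::random_dna(60),
                             internal = mobscan:::random_dna(380)))
}

# Compact reference for ioalign/mask tests: 20-kb chromosome, one small TE,
# 2-kb organelle with two 300-bp nuclear inserts.
small_bundle <- function(seed = 7, n_inserts = 2, insert_len = 300) {
  tes <- make_te_library(1, ltr_len = 60, internal_len = 380, seed = 101)
  build_reference(seed, c(chr1 = 20000), tes, copies_per_element = 1,
                  organelle_length = 2000, n_organelle_inserts = n_inserts,
                  organelle_insert_len = insert_len)
}

# Full-scale study-condition library: 1-Mb genome, three 5-kb elements
# (one copy each), one active as a 2-LTR circle, trace linear background,
# organelle carry-over.  Mirrors the conditions the simulator is built to
# emulate.
study_library <- function(seed, circle_depth, active = 1, insert = "",
                          error_rate = 0.002, organelle_depth = 5) {
  tes <- make_te_library(3, seed = 1000 + seed)
  bundle <- build_reference(seed, c(chr1 = 1000000), tes,
                            copies_per_element = 1,
                            organelle_length = 20000,
                            n_organelle_inserts = 2)
  circ <- make_circle(tes[[active]], "two_ltr", insert = insert)
  sim <- simulate_reads(bundle, list(circ), circle_depth = circle_depth,
                        background_depth = 1,
                        organelle_depth = organelle_depth,
                        error_rate = error_rate, seed = seed)
  list(bundle = bundle, tes = tes, circle = circ, sim = sim,
       active_te = bundle$te_loci$te_id[active])
}

# Write a library's pipeline inputs to a temp dir; returns the config list.
library_config <- function(lib, dir = tempfile("mobrun")) {
  dir.create(dir)
  sl <- stats::setNames(nchar(lib$bundle$chromosomes),
                        names(lib$bundle$chromosomes))
  aln <- idealized_alignments(lib$bundle, lib$sim)
  sam <- file.path(dir, "aln.sam")
  write_sam(aln, sam, sl)
  ref <- file.path(dir, "ref.fa")
  gff <- file.path(dir, "te.gff3")
  org <- file.path(dir, "organelle.fa")
  write_reference_fasta(lib$bundle, ref)
  write_te_gff(lib$bundle, gff)
  write_reference_fasta(lib$bundle, org, "organelles")
  list(sam = sam, ref_fasta = ref, te_gff = gff, organelle_fasta = org,
       out_dir = file.path(dir, "out"))
}
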