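# Synthetic mobilome-seq library simulator: reference genomes with planted
# LTR-retrotransposon copies and organelle insertions, eccDNA circle
# templates, paired-end reads with full ground truth.

#' Construct an LTR retrotransposon element
#'
#' An element is modelled as LTR + internal region + LTR, with the two long
#' terminal repeats byte-identical at creation.
#'
#' @param id element identifier.
#' @param family family name (several elements/copies may share one).
#' @param ltr LTR nucleotide sequence (non-empty).
#' @param internal internal-region nucleotide sequence (non-empty).
#' @return A `TElement` object.
#' @export
te_element <- function(id, family, ltr, internal) {
  stopifnot(is.character(id), nzchar(ltr), nzchar(internal))
  len <- 2L * nchar(ltr) + nchar(internal)
  if (len <= 100L)
    stop("element '", id, "' must be longer than 100 bp (got ", len, ")")
  structure(list(id = id, family = family, ltr = ltr, internal = internal),
            class = "TElement")
}

#' @rdname te_element
#' @param te a `TElement`.
#' @export
te_length <- function(te) 2L * nchar(te$ltr) + nchar(te$internal)

#' @rdname te_element
#' @export
te_sequence <- function(te) paste0(te$ltr, te$internal, te$ltr)

#' Generate a library of random TE elements
#'
#' @param n number of elements; each gets its own family (`fam1`, ...).
#' @param ltr_len,internal_len LTR and internal-region lengths (bp).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return list of [te_element()] objects.
#' @export
make_te_library <- function(n, ltr_len = 400L, internal_len = 4200L, seed = NULL) {
  gen <- function() {
    lapply(seq_len(n), function(i) {
      te_element(id = sprintf("te%d", i), family = sprintf("fam%d", i),
                 ltr = random_dna(ltr_len), internal = random_dna(internal_len))
    })
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Place `k` non-overlapping intervals of widths `widths` on chromosomes,
# avoiding `occupied` (data.frame chrom/start/end).  Bounded retries.
place_intervals <- function(chrom_lengths, widths, occupied, max_tries = 500L) {
  chroms <- names(chrom_lengths)
  out <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
  for (w in widths) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- sample.int(length(chroms), 1L, prob = chrom_lengths)
      if (chrom_lengths[ci] < w) next
      s <- sample.int(chrom_lengths[ci] - w + 1L, 1L) - 1L
      e <- s + w
      clash <- occupied$chrom == chroms[ci] & occupied$start < e & occupied$end > s
      if (!any(clash)) {
        row <- data.frame(chrom = chroms[ci], start = s, end = e)
        occupied <- rbind(occupied, row)
        out <- rbind(out, row)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("placement failed after ", max_tries,
           " retries: chromosomes too small for the requested intervals")
  }
  list(placed = out, occupied = occupied)
}

#' Build a synthetic reference bundle
#'
#' Generates random chromosomes, plants `copies_per_element` copies of each
#' TE element (uniformly, without overlap), generates an organelle genome and
#' embeds `n_organelle_inserts` exact substrings of it in the chromosomes,
#' recording their positions as ground truth for organelle masking.
#' Deterministic for a fixed seed.
#'
#' @param seed integer seed.
#' @param chrom_lengths integer vector of chromosome lengths (bp); each must
#'   be at least 10x the longest element.
#' @param te_library list of [te_element()] objects.
#' @param copies_per_element copies planted per element.
#' @param organelle_length length of the simulated organelle genome (0 = none).
#' @param n_organelle_inserts number of organelle substrings embedded in the
#'   nuclear genome.
#' @param organelle_insert_len length of each embedded substring (bp).
#' @param divergence per-copy substitution rate applied to planted TE copies
#'   (0 = identical copies, max 0.05).
#' @return A `ReferenceBundle`: list with `chromosomes`, `te_loci`,
#'   `organelles`, `nuclear_organelle_inserts` (all coordinates 0-based
#'   half-open), the element library and the seed.
#' @export
build_reference <- function(seed, chrom_lengths, te_library,
                            copies_per_element = 1L,
                            organelle_length = 0L,
                            n_organelle_inserts = 0L,
                            organelle_insert_len = 500L,
                            divergence = 0) {
  stopifnot(length(chrom_lengths) >= 1L, copies_per_element >= 0L,
            divergence >= 0, divergence <= 0.05)
  max_len <- max(vapply(te_library, te_length, integer(1)))
  if (any(chrom_lengths < 10L * max_len))
    stop("each chromosome must be at least 10x the longest element (",
         10L * max_len, " bp)")
  total_te <- copies_per_element * sum(vapply(te_library, te_length, integer(1)))
  if (total_te > 0.9 * sum(chrom_lengths))
    stop("placement failed: chromosomes too small for ",
         copies_per_element, " copies per element")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- sprintf("chr%d", seq_along(chrom_lengths))

  with_seed(seed, {
    chroms <- random_dna(chrom_lengths)
    names(chroms) <- names(chrom_lengths)

    occupied <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
    te_loci <- NULL
    for (te in te_library) {
      L <- te_length(te)
      Lltr <- nchar(te$ltr)
      if (copies_per_element > 0L) {
        pl <- place_intervals(chrom_lengths, rep(L, copies_per_element), occupied)
        occupied <- pl$occupied
        for (ci in seq_len(copies_per_element)) {
          row <- pl$placed[ci, ]
          copy_seq <- diverge_sequence(te_sequence(te), divergence)
          substr(chroms[row$chrom], row$start + 1L, row$end) <- copy_seq
          te_loci <- rbind(te_loci, data.frame(
            te_id = sprintf("%s_c%d", te$id, ci), family = te$family,
            element_id = te$id,
            chrom = row$chrom, start = row$start, end = row$end, strand = "+",
            ltr5_start = row$start, ltr5_end = row$start + Lltr,
            ltr3_start = row$end - Lltr, ltr3_end = row$end,
            stringsAsFactors = FALSE))
        }
      }
    }

    organelles <- character(0)
    inserts <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), organelle = character(0),
                          org_start = integer(0), org_end = integer(0))
    if (organelle_length > 0L) {
      organelles <- c(organelle = random_dna(organelle_length))
      if (n_organelle_inserts > 0L) {
        stopifnot(organelle_insert_len <= organelle_length)
        for (i in seq_len(n_organelle_inserts)) {
          os <- sample.int(organelle_length - organelle_insert_len + 1L, 1L) - 1L
          oe <- os + organelle_insert_len
          pl <- place_intervals(chrom_lengths, organelle_insert_len, occupied)
          occupied <- pl$occupied
          row <- pl$placed[1L, ]
          substr(chroms[row$chrom], row$start + 1L, row$end) <-
            substr(organelles[["organelle"]], os + 1L, oe)
          inserts <- rbind(inserts, data.frame(
            chrom = row$chrom, start = row$start, end = row$end,
            organelle = "organelle", org_start = os, org_end = oe,
            stringsAsFactors = FALSE))
        }
      }
    }

    structure(list(
      chromosomes = chroms,
      te_loci = te_loci %||% data.frame(),
      te_library = te_library,
      organelles = organelles,
      nuclear_organelle_inserts = inserts,
      rdna_locus = NULL,
      divergence = divergence,
      seed = seed), class = "ReferenceBundle")
  })
}

#' @export
print.ReferenceBundle <- function(x, ...) {
  cat("ReferenceBundle:", length(x$chromosomes), "chromosome(s),",
      nrow(x$te_loci), "TE locus/loci,",
      nrow(x$nuclear_organelle_inserts), "organelle insert(s)\n")
  invisible(x)
}

#' Construct an eccDNA circle template
#'
#' Low-level constructor; most users call [make_circle()].  The circle
#' sequence is stored linearised starting at the element 5' end;
#' `junction_offset` is the position where the element 3' end is fused
#' (through `insert_at_junction`, possibly empty) back to the element
#' 5' start.
#'
#' @param source_te id of the source element.
#' @param kind one of `"two_ltr"`, `"one_ltr"`, `"tandem_repeat"`.
#' @param sequence circular nucleotide sequence, linearised.
#' @param junction_offset fusion position on the circle.
#' @param insert_at_junction bases inserted at the junction (e.g. a PBS
#'   remnant), possibly empty.
#' @return A `CircleTemplate`.
#' @export
circle_template <- function(source_te, kind, sequence, junction_offset,
                            insert_at_junction = "") {
  stopifnot(kind %in% c("two_ltr", "one_ltr", "tandem_repeat"),
            junction_offset + nchar(insert_at_junction) == nchar(sequence))
  structure(list(source_te = source_te, kind = kind, sequence = sequence,
                 junction_offset = junction_offset,
                 insert_at_junction = insert_at_junction,
                 length = nchar(sequence)),
            class = "CircleTemplate")
}

#' Build a 2-LTR or 1-LTR circle from an element
#'
#' A 2-LTR circle is the full element read linearly with its 3' end fused to
#' its 5' start (circle length `L + |insert|`); a 1-LTR circle has one LTR
#' copy deleted before fusion (length `L - L_ltr + |insert|`).  A non-empty
#' `insert` (e.g. a primer-binding-site remnant) makes the junction
#' "imperfect".
#'
#' @param te a [te_element()].
#' @param kind `"two_ltr"` or `"one_ltr"`.
#' @param insert nucleotide string inserted at the junction (default empty).
#' @return A `CircleTemplate`.
#' @export
make_circle <- function(te, kind = c("two_ltr", "one_ltr"), insert = "") {
  kind <- match.arg(kind)
  part <- switch(kind,
    two_ltr = te_sequence(te),
    one_ltr = paste0(te$ltr, te$internal))
  circle_template(source_te = te$id, kind = kind,
                  sequence = paste0(part, insert),
                  junction_offset = nchar(part),
                  insert_at_junction = insert)
}

# Wrap flags and junction flank lengths for a circle mate span [a, a+R)
# (a taken modulo C).  The junction cut sits at junction_offset J; the
# insert occupies [J, C).  A span "wraps" when it strictly crosses the cut.
# flank3 = bases on the element-3'-end side, flank5 = bases landing on the
# element 5' start beyond the insert (NA when the span does not wrap).
circle_wrap_info <- function(a, R, C, J) {
  k <- C - J
  # candidate cut positions in unwrapped coordinates [0, 2C)
  w1 <- a < J & (a + R) > J
  w2 <- a >= J & a < (C + J) & (a + R) > (C + J)
  wraps <- w1 | w2
  cut <- ifelse(w1, J, C + J)
  flank3 <- ifelse(wraps, pmin(cut - a, J), NA_integer_)
  flank5 <- ifelse(wraps, pmax(a + R - cut - k, 0L), NA_integer_)
  data.frame(wraps = wraps, flank3 = flank3, flank5 = flank5)
}

#' Simulate a paired-end mobilome-seq library
#'
#' Samples read pairs from three template classes: eccDNA circles (uniform
#' start on the circle with wrap-around, so a predictable fraction of reads
#' spans the junction), the linear nuclear background, and the organelle
#' genome.  Per-base substitution errors are applied at `error_rate`.  The
#' returned truth table records, for every pair, its template of origin and
#' for circle reads whether each mate's span wraps the junction and with
#' what flank lengths.
#'
#' @param bundle a [build_reference()] bundle.
#' @param circles list of [make_circle()] templates (may be empty).
#' @param circle_depth mean fold-coverage on each circle (recycled).
#' @param background_depth mean fold-coverage of the linear genome.
#' @param organelle_depth mean fold-coverage of the organelle genome.
#' @param read_len read length (bp).
#' @param insert_mean,insert_sd fragment-size distribution (bp).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed; the simulation is deterministic for a fixed seed.
#' @return A `MobilomeSim`: list with `reads1`/`reads2` (named sequence
#'   vectors), `truth` (one row per pair), `active` (circle table),
#'   `params` and `seed`.
#' @export
simulate_reads <- function(bundle, circles = list(),
                           circle_depth = 100, background_depth = 1,
                           organelle_depth = 0,
                           read_len = 250L, insert_mean = 500L,
                           insert_sd = 50, error_rate = 0, seed = 1L) {
  stopifnot(inherits(bundle, "ReferenceBundle"))
  if (any(c(circle_depth, background_depth, organelle_depth) < 0))
    stop("depths must be non-negative")
  if (length(circles)) {
    shortest <- min(vapply(circles, `[[`, integer(1), "length"))
    if (read_len >= shortest)
      stop("read_len must be smaller than the shortest circle (", shortest, " bp)")
    if (insert_mean >= shortest)
      stop("insert_mean must be smaller than the shortest circle")
  }
  if (read_len >= insert_mean) stop("read_len must be smaller than insert_mean")
  depth_vec <- rep_len(circle_depth, length(circles))

  templates <- list()
  for (i in seq_along(circles)) {
    cc <- circles[[i]]
    templates[[length(templates) + 1L]] <- list(
      id = paste0("circ:", cc$source_te), origin = "circle",
      name = cc$source_te, seq = cc$sequence, len = cc$length,
      circular = TRUE, J = cc$junction_offset, depth = depth_vec[i])
  }
  for (nm in names(bundle$chromosomes)) {
    templates[[length(templates) + 1L]] <- list(
      id = paste0("chrom:", nm), origin = "genome", name = nm,
      seq = bundle$chromosomes[[nm]], len = nchar(bundle$chromosomes[[nm]]),
      circular = FALSE, J = NA, depth = background_depth)
  }
  for (nm in names(bundle$organelles)) {
    templates[[length(templates) + 1L]] <- list(
      id = paste0("org:", nm), origin = "organelle", name = nm,
      seq = bundle$organelles[[nm]], len = nchar(bundle$organelles[[nm]]),
      circular = FALSE, J = NA, depth = organelle_depth)
  }

  with_seed(seed, {
    r1 <- character(0); r2 <- character(0)
    truth <- list()
    for (tp in templates) {
      n <- round(tp$depth * tp$len / (2 * read_len))
      if (n <= 0) next
      frag <- pmin(pmax(round(stats::rnorm(n, insert_mean, insert_sd)),
                        read_len), tp$len)
      if (tp$circular) {
        start <- floor(stats::runif(n, 0, tp$len))
        doubled <- paste0(tp$seq, tp$seq)
        s1 <- substring(doubled, start + 1L, start + read_len)
        fs <- substring(doubled, start + frag - read_len + 1L, start + frag)
      } else {
        start <- floor(stats::runif(n, 0, tp$len - frag + 1))
        s1 <- substring(tp$seq, start + 1L, start + read_len)
        fs <- substring(tp$seq, start + frag - read_len + 1L, start + frag)
      }
      s2 <- revcomp(fs)
      s1 <- inject_errors(s1, error_rate)
      s2 <- inject_errors(s2, error_rate)
      ids <- sprintf("%s:%06d", tp$id, seq_len(n))
      names(s1) <- ids; names(s2) <- ids
      r1 <- c(r1, s1); r2 <- c(r2, s2)

      row <- data.frame(read_id = ids, origin = tp$origin, template = tp$name,
                        start = start, frag_len = frag,
                        stringsAsFactors = FALSE)
      if (tp$circular) {
        w1 <- circle_wrap_info(start %% tp$len, read_len, tp$len, tp$J)
        a2 <- (start + frag - read_len) %% tp$len
        w2 <- circle_wrap_info(a2, read_len, tp$len, tp$J)
        row$m1_wraps <- w1$wraps; row$m1_flank3 <- w1$flank3; row$m1_flank5 <- w1$flank5
        row$m2_wraps <- w2$wraps; row$m2_flank3 <- w2$flank3; row$m2_flank5 <- w2$flank5
      } else {
        row$m1_wraps <- NA; row$m1_flank3 <- NA_integer_; row$m1_flank5 <- NA_integer_
        row$m2_wraps <- NA; row$m2_flank3 <- NA_integer_; row$m2_flank5 <- NA_integer_
      }
      truth[[length(truth) + 1L]] <- row
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(read_id = character(0), origin = character(0),
                 template = character(0), start = integer(0),
                 frag_len = integer(0),
                 m1_wraps = logical(0), m1_flank3 = integer(0),
                 m1_flank5 = integer(0), m2_wraps = logical(0),
                 m2_flank3 = integer(0), m2_flank5 = integer(0))
    rownames(truth) <- NULL

    active <- if (length(circles)) data.frame(
      te_id = vapply(circles, `[[`, character(1), "source_te"),
      kind = vapply(circles, `[[`, character(1), "kind"),
      circle_depth = depth_vec,
      circle_len = vapply(circles, `[[`, integer(1), "length"),
      junction_offset = vapply(circles, `[[`, integer(1), "junction_offset"),
      insert_len = vapply(circles, function(x) nchar(x$insert_at_junction), integer(1)),
      stringsAsFactors = FALSE)
    else data.frame(te_id = character(0), kind = character(0),
                    circle_depth = numeric(0), circle_len = integer(0),
                    junction_offset = integer(0), insert_len = integer(0))

    structure(list(
      reads1 = r1, reads2 = r2, truth = truth, active = active,
      circles = circles,
      params = list(circle_depth = depth_vec,
                    background_depth = background_depth,
                    organelle_depth = organelle_depth,
                    read_len = read_len, insert_mean = insert_mean,
                    insert_sd = insert_sd, error_rate = error_rate),
      bundle_seed = bundle$seed,
      seed = seed), class = "MobilomeSim")
  })
}

#' @export
print.MobilomeSim <- function(x, ...) {
  cat("MobilomeSim:", nrow(x$truth), "read pairs (",
      sum(x$truth$origin == "circle"), "circle,",
      sum(x$truth$origin == "genome"), "genome,",
      sum(x$truth$origin == "organelle"), "organelle )\n")
  invisible(x)
}

#' Write simulated reads as paired FASTQ files
#'
#' @param sim a [simulate_reads()] object.
#' @param prefix output prefix; writes `<prefix>_1.fastq`, `<prefix>_2.fastq`.
#'   Quality strings are constant `I`.
#' @return invisibly, the two file paths.
#' @export
write_fastq <- function(sim, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    reads <- if (m == 1) sim$reads1 else sim$reads2
    lines <- as.vector(rbind(paste0("@", names(reads), "/", m),
                             unname(reads), "+",
                             strrep("I", nchar(reads))))
    writeLines(lines, paths[m])
  }
  invisible(paths)
}

#' Write the simulation truth table
#'
#' Writes the per-pair provenance table as TSV plus a JSON sidecar with the
#' simulation parameters and active-circle table.
#'
#' @param sim a [simulate_reads()] object.
#' @param prefix output prefix; writes `<prefix>.truth.tsv` and
#'   `<prefix>.truth.json`.
#' @return invisibly, the two file paths.
#' @export
write_truth <- function(sim, prefix) {
  tsv <- paste0(prefix, ".truth.tsv")
  js <- paste0(prefix, ".truth.json")
  utils::write.table(sim$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = sim$seed, params = sim$params,
                            active = sim$active),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Write the reference genome of a bundle as FASTA
#'
#' @param bundle a [build_reference()] bundle.
#' @param path output FASTA path.
#' @param what `"chromosomes"` or `"organelles"`.
#' @return invisibly, `path`.
#' @export
write_reference_fasta <- function(bundle, path, what = c("chromosomes", "organelles")) {
  what <- match.arg(what)
  seqs <- Biostrings::DNAStringSet(bundle[[what]])
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write the TE annotation of a bundle as GFF3
#'
#' @param bundle a [build_reference()] bundle.
#' @param path output GFF3 path (1-based closed coordinates, per the format).
#' @return invisibly, `path`.
#' @export
write_te_gff <- function(bundle, path) {
  loci <- bundle$te_loci
  lines <- "##gff-version 3"
  if (nrow(loci)) {
    lines <- c(lines, sprintf(
      "%s\tmobscan\ttransposable_element\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;family=%s;ltr_len=%d",
      loci$chrom, loci$start + 1L, loci$end, loci$strand,
      loci$te_id, loci$te_id, loci$family, loci$ltr5_end - loci$ltr5_start))
  }
  writeLines(lines, path)
  invisible(path)
}
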