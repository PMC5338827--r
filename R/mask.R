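# Organelle-signal masking: DNA from the mitochondrial and chloroplast
# genomes is integrated in nuclear chromosomes; reads from the (highly
# abundant, circular) organelle genomes pile up on those nuclear copies and
# would mimic eccDNA signal.  The mask marks every nuclear interval with an
# exact organelle match and alignment records overlapping it are dropped.

#' Normalize a set of genomic intervals
#'
#' Sorts and merges (union-reduces) intervals so the result is disjoint
#' with no abutting duplicates.
#'
#' @param gr a `GRanges` (or anything coercible via `as`).
#' @return A reduced, sorted `GRanges`.
#' @export
interval_set <- function(gr) {
  GenomicRanges::reduce(sort(gr), ignore.strand = TRUE)
}

#' @rdname interval_set
#' @export
interval_total_bp <- function(gr) sum(GenomicRanges::width(gr))

#' Build the organelle mask for a nuclear genome
#'
#' Tiles the organelle genome(s) into pseudo-reads of `tile_len` bp every
#' `step` bp (both strands) and marks every nuclear interval containing an
#' exact match of length >= `min_exact` to any tile.  Tiling at `step <=
#' tile_len - min_exact + 1` makes the scan equivalent to matching every
#' `min_exact`-mer of the organelle, so planted organelle insertions are
#' recovered in full.
#'
#' @param reference a [build_reference()] bundle, a named character vector of
#'   chromosome sequences, a `DNAStringSet`, or a FASTA path.
#' @param organelles organelle sequences in the same accepted forms; defaults
#'   to the bundle's own organelles when `reference` is a bundle.
#' @param tile_len tile (pseudo-read) length, bp.
#' @param step tile spacing, bp.
#' @param min_exact minimum exact-match length added to the mask, bp.
#' @return A normalized `GRanges` mask with chromosome seqlengths set.
#' @export
build_organelle_mask <- function(reference, organelles = NULL,
                                 tile_len = 100L, step = 10L,
                                 min_exact = 50L) {
  if (inherits(reference, "ReferenceBundle")) {
    chroms <- Biostrings::DNAStringSet(reference$chromosomes)
    if (is.null(organelles)) organelles <- reference$organelles
  } else chroms <- as_dna_set(reference)
  orgs <- as_dna_set(organelles)
  sl <- stats::setNames(Biostrings::width(chroms), names(chroms))
  empty <- GenomicRanges::GRanges(seqlengths = sl)
  if (!length(orgs)) return(empty)
  if (any(Biostrings::width(orgs) < tile_len))
    stop("tile_len exceeds an organelle length")
  stopifnot(min_exact <= tile_len, step >= 1L)

  kmers <- character(0)
  for (i in seq_along(orgs)) {
    s <- as.character(orgs[[i]])
    n <- nchar(s)
    starts <- unique(c(seq(1L, n - tile_len + 1L, by = step), n - tile_len + 1L))
    tiles <- substring(s, starts, starts + tile_len - 1L)
    km <- unlist(lapply(tiles, function(t) {
      p <- 1:(tile_len - min_exact + 1L)
      substring(t, p, p + min_exact - 1L)
    }), use.names = FALSE)
    kmers <- c(kmers, km)
  }
  kmers <- unique(c(kmers, revcomp(kmers)))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))

  hits <- list()
  for (i in seq_along(chroms)) {
    m <- Biostrings::matchPDict(pd, chroms[[i]])
    r <- IRanges::reduce(unlist(m))
    if (length(r)) hits[[length(hits) + 1L]] <-
      GenomicRanges::GRanges(names(chroms)[i], r)
  }
  if (!length(hits)) return(empty)
  gr <- interval_set(do.call(c, hits))
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqlengths(gr) <- sl
  gr
}

as_dna_set <- function(x) {
  if (is.null(x)) return(Biostrings::DNAStringSet())
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  Biostrings::DNAStringSet(x)
}

#' Remove alignment records overlapping a mask
#'
#' A record is removed iff any of its segments overlaps any mask interval
#' by at least 1 bp (remove-on-any-overlap, the `intersect -v` convention);
#' abutting half-open intervals do not overlap.  Survivors are returned
#' unchanged, in their original order, so the operation is idempotent.
#'
#' @param records a `mob_alignments` table.
#' @param mask a normalized `GRanges` mask.
#' @return The filtered `mob_alignments` table.
#' @export
apply_mask <- function(records, mask) {
  if (!nrow(records) || !length(mask)) return(records)
  gr <- segments_granges(records)
  if (!length(gr)) return(records)
  hit <- IRanges::overlapsAny(gr, mask, ignore.strand = TRUE)
  drop <- unique(S4Vectors::mcols(gr)$rec_id[hit])
  out <- records[!(records$rec_id %in% drop), , drop = FALSE]
  rownames(out) <- NULL
  mob_alignments(out)
}

#' Write an interval set as BED
#'
#' @param gr a `GRanges`.
#' @param path output BED path (0-based half-open, per the format).
#' @return invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
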