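# Per-TE evidence aggregation and the candidate decision rule: a TE locus
# is called an eccDNA candidate when it is covered over at least 90% of its
# length, its mean depth of coverage exceeds 10 rpm, its split-read
# coverage exceeds 10 rpm, and it is longer than 100 bp.

#' Aggregate eccDNA evidence per TE locus
#'
#' Computes, for every TE locus: `breadth` (fraction of bases with
#' per-base depth >= 1), `doc_rpm` (mean per-base depth over the locus,
#' normalized per million mapped records) and `sr_rpm` (mean split-read
#' track rpm over the windows intersecting the locus).
#'
#' @param records mask-filtered `mob_alignments`.
#' @param te_loci TE locus table ([read_te_gff()] or a bundle's `te_loci`).
#' @param sr_track split-read [sr_window_coverage()] track.
#' @param total_mapped mapped-record count of the library; defaults to the
#'   count in `records`.
#' @return A `TEEvidence` data.frame: `te_id`, `family`, `chrom`, `start`,
#'   `end`, `length`, `breadth`, `doc_rpm`, `sr_rpm`.
#' @export
te_evidence <- function(records, te_loci, sr_track, total_mapped = NULL) {
  if (any(te_loci$end <= te_loci$start))
    stop("zero-length TE locus: ",
         paste(te_loci$te_id[te_loci$end <= te_loci$start], collapse = ", "))
  if (is.null(total_mapped)) total_mapped <- count_mapped_records(records)
  sgr <- segments_granges(records[records$is_primary, , drop = FALSE])
  cov <- if (length(sgr)) GenomicRanges::coverage(sgr) else NULL
  sr_gr <- GenomicRanges::GRanges(sr_track$chrom,
                                  IRanges::IRanges(sr_track$start + 1L,
                                                   sr_track$end))

  out <- te_loci[, c("te_id", "family", "chrom", "start", "end")]
  out$length <- te_loci$end - te_loci$start
  out$breadth <- 0; out$doc_rpm <- 0; out$sr_rpm <- 0
  for (i in seq_len(nrow(te_loci))) {
    chrom <- te_loci$chrom[i]
    v <- if (!is.null(cov) && chrom %in% names(cov))
      as.integer(cov[[chrom]][(te_loci$start[i] + 1L):te_loci$end[i]])
    else integer(out$length[i])
    out$breadth[i] <- mean(v >= 1L)
    out$doc_rpm[i] <- if (total_mapped > 0) mean(v) * 1e6 / total_mapped else 0
    lgr <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(te_loci$start[i] + 1L,
                                                   te_loci$end[i]))
    wi <- IRanges::overlapsAny(sr_gr, lgr)
    out$sr_rpm[i] <- if (any(wi)) mean(sr_track$rpm[wi]) else 0
  }
  rownames(out) <- NULL
  out
}

#' Apply the candidate-TE decision rule
#'
#' Thresholds: breadth >= `min_breadth`, depth of coverage strictly >
#' `min_doc_rpm`, split-read coverage strictly > `min_sr_rpm`, length
#' strictly > `min_length`.  Candidates are ordered by descending
#' `doc_rpm` with ties broken by `te_id`.
#'
#' @param evidence a [te_evidence()] data.frame.
#' @param min_breadth minimum covered fraction of the locus.
#' @param min_doc_rpm depth-of-coverage threshold (rpm, strict).
#' @param min_sr_rpm split-read coverage threshold (rpm, strict).
#' @param min_length locus length threshold (bp, strict).
#' @return `evidence` with pass flags, `is_candidate`, ordered as above.
#' @export
call_candidates <- function(evidence, min_breadth = 0.90, min_doc_rpm = 10,
                            min_sr_rpm = 10, min_length = 100) {
  stopifnot(min_breadth > 0, min_doc_rpm > 0, min_sr_rpm > 0, min_length > 0)
  out <- evidence
  out$passes_breadth <- out$breadth >= min_breadth
  out$passes_doc <- out$doc_rpm > min_doc_rpm
  out$passes_sr <- out$sr_rpm > min_sr_rpm
  out$passes_length <- out$length > min_length
  out$is_candidate <- out$passes_breadth & out$passes_doc &
    out$passes_sr & out$passes_length
  out <- out[order(-out$doc_rpm, out$te_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full eccDNA detection pipeline
#'
#' Orchestrates: organelle masking -> window counts -> Poisson covered
#' regions -> negative-binomial peaks -> split-read classification ->
#' junction calls -> candidate table, writing all artifacts plus a
#' machine-readable run log.  Reruns on identical inputs are
#' byte-identical.
#'
#' @param config list with inputs `sam`, `ref_fasta`, `te_gff`, optional
#'   `organelle_fasta`, output directory `out_dir`, and optional
#'   parameter overrides: `window_size`, `alpha_covered`, `alpha_peak`,
#'   `tile_len`, `step`, `min_exact`, `junction_tolerance`,
#'   `min_breadth`, `min_doc_rpm`, `min_sr_rpm`, `min_length`, and
#'   `negbin_fit` (`"all"` or `"covered"`, see Details in the vignette).
#' @return invisibly, a list with every intermediate object (`records`,
#'   `mask`, `track`, `peaks`, `sr_track`, `junctions`, `evidence`,
#'   `candidates`, `total_mapped`, `files`).
#' @export
run_pipeline <- function(config) {
  for (f in c("sam", "ref_fasta", "te_gff")) {
    if (is.null(config[[f]])) stop("config$", f, " is required")
    if (!file.exists(config[[f]])) stop("input not found: ", config[[f]])
  }
  if (!is.null(config$organelle_fasta) && !file.exists(config$organelle_fasta))
    stop("input not found: ", config$organelle_fasta)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  window_size <- config$window_size %||% 100L
  p <- function(nm) file.path(out_dir, nm)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed (partial outputs removed): ", conditionMessage(e))
  }

  tryCatch({
    ref <- Biostrings::readDNAStringSet(config$ref_fasta)
    names(ref) <- sub("\\s.*$", "", names(ref))
    chrom_lengths <- stats::setNames(Biostrings::width(ref), names(ref))
    te_loci <- read_te_gff(config$te_gff)
    records <- read_alignments(config$sam)

    mask <- if (!is.null(config$organelle_fasta))
      build_organelle_mask(ref, config$organelle_fasta,
                           tile_len = config$tile_len %||% 100L,
                           step = config$step %||% 10L,
                           min_exact = config$min_exact %||% 50L)
    else GenomicRanges::GRanges()
    records <- apply_mask(records, mask)
    total_mapped <- count_mapped_records(records)

    grid <- window_grid(chrom_lengths, window_size)
    track <- window_counts(records, grid, mask = mask)
    pois <- fit_poisson(track, alpha_covered = config$alpha_covered %||% 1e-5)
    covered <- covered_windows(track, pois)
    # stage-2 fit set: "all" (default) fits the negative binomial on every
    # non-excluded window and tests the covered ones against it, giving a
    # stable contrast when the covered set collapses onto a single locus;
    # "covered" fits on the covered windows only.
    negbin_fit <- config$negbin_fit %||% "all"
    nb_counts <- if (identical(negbin_fit, "covered"))
      track$raw[track$widx %in% covered] else track$raw[!track$excluded]
    nb <- fit_negbin(nb_counts, alpha_peak = config$alpha_peak %||% 1e-3)
    peaks <- call_peaks(track, covered, nb)
    peaks <- annotate_peaks(peaks, te_loci)

    sr <- classify_sr(records)
    sr_track <- sr_window_coverage(sr, grid, total_mapped, mask = mask)
    junctions <- call_junctions(sr, te_loci,
                                tolerance = config$junction_tolerance %||% 20L)

    evidence <- te_evidence(records, te_loci, sr_track, total_mapped)
    candidates <- call_candidates(
      evidence,
      min_breadth = config$min_breadth %||% 0.90,
      min_doc_rpm = config$min_doc_rpm %||% 10,
      min_sr_rpm = config$min_sr_rpm %||% 10,
      min_length = config$min_length %||% 100)

    wr <- function(fn, writer) { writer(p(fn)); written <<- c(written, p(fn)) }
    wr("mask.bed", function(f) write_bed(mask, f))
    wr("coverage.raw.bedgraph", function(f) write_bedgraph(track, f, "raw"))
    wr("coverage.rpm.bedgraph", function(f) write_bedgraph(track, f, "rpm"))
    wr("sr.rpm.bedgraph", function(f) write_bedgraph(sr_track, f, "rpm"))
    wr("peaks.bed", function(f) write_peaks_bed(peaks, f))
    wr("peaks.tsv", function(f) utils::write.table(
      peaks, f, sep = "\t", quote = FALSE, row.names = FALSE))
    wr("junctions.tsv", function(f) utils::write.table(
      junctions, f, sep = "\t", quote = FALSE, row.names = FALSE))
    wr("te_evidence.tsv", function(f) utils::write.table(
      evidence, f, sep = "\t", quote = FALSE, row.names = FALSE))
    wr("candidates.tsv", function(f) utils::write.table(
      candidates, f, sep = "\t", quote = FALSE, row.names = FALSE))
    wr("runlog.json", function(f) jsonlite::write_json(list(
      package = "mobscan",
      version = as.character(utils::packageVersion("mobscan")),
      inputs = config[c("sam", "ref_fasta", "te_gff", "organelle_fasta")],
      thresholds = list(
        window_size = window_size,
        alpha_covered = config$alpha_covered %||% 1e-5,
        alpha_peak = config$alpha_peak %||% 1e-3,
        negbin_fit = negbin_fit,
        min_breadth = config$min_breadth %||% 0.90,
        min_doc_rpm = config$min_doc_rpm %||% 10,
        min_sr_rpm = config$min_sr_rpm %||% 10,
        min_length = config$min_length %||% 100,
        junction_tolerance = config$junction_tolerance %||% 20L),
      total_mapped = total_mapped,
      n_peaks = nrow(peaks),
      n_sr_records = length(unique(sr$rec_id)),
      n_junctions = nrow(junctions),
      n_candidates = sum(candidates$is_candidate)),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE))

    invisible(list(records = records, mask = mask, track = track,
                   poisson = pois, covered = covered, negbin = nb,
                   peaks = peaks, sr = sr, sr_track = sr_track,
                   junctions = junctions, evidence = evidence,
                   candidates = candidates, total_mapped = total_mapped,
                   files = written))
  }, error = on_fail)
}

#' Read a candidate table written by [run_pipeline()]
#'
#' @param path `candidates.tsv` path.
#' @return The candidate data.frame, with the same column types as
#'   produced by [call_candidates()].
#' @export
read_candidates <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
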