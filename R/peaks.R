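# Windowed coverage and the two-stage peak caller.  The genome is tiled
# into consecutive 100-bp windows; per-window record counts are normalized
# to reads per million mapped (rpm).  Stage 1 keeps "covered" windows whose
# count is extreme under a Poisson fitted to all (non-excluded) windows
# (upper tail p < 1e-5); stage 2 calls "peak" windows among the covered
# ones under a moment-fitted negative binomial (upper tail p < 1e-3).
# Adjacent significant windows merge into peak regions, which are then
# annotated against TE features.

#' Partition chromosomes into consecutive windows
#'
#' Windows tile each chromosome exactly (disjoint, union = chromosome); the
#' trailing window may be shorter than `window_size`.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param window_size window size in bp (default 100).
#' @return A `WindowGrid` data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and a global window index `widx`.
#' @export
window_grid <- function(chrom_lengths, window_size = 100L) {
  stopifnot(window_size >= 1L)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- sprintf("chr%d", seq_along(chrom_lengths))
  out <- lapply(names(chrom_lengths), function(nm) {
    len <- chrom_lengths[[nm]]
    if (len <= 0L) return(NULL)
    s <- seq.int(0L, len - 1L, by = window_size)
    data.frame(chrom = nm, start = s, end = pmin(s + window_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out) %||%
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  if (is.null(out)) out <- data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0))
  out$widx <- seq_len(nrow(out))
  attr(out, "window_size") <- window_size
  attr(out, "chrom_lengths") <- chrom_lengths
  class(out) <- c("WindowGrid", "data.frame")
  out
}

grid_granges <- function(grid) {
  if (!nrow(grid)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(grid$chrom,
                         IRanges::IRanges(start = grid$start + 1L, end = grid$end))
}

#' Per-window record counts with rpm normalization
#'
#' `raw[w]` is the number of alignment records with at least 1 bp of some
#' segment inside window `w`; a record spanning a window boundary increments
#' both windows.  `rpm = raw * 1e6 / total_mapped`.  Windows overlapping the
#' mask are flagged `excluded` and ignored by the model fits.
#'
#' @param records a `mob_alignments` table (already mask-filtered).
#' @param grid a [window_grid()].
#' @param mask optional `GRanges` of masked regions.
#' @param total_mapped rpm denominator; defaults to the number of distinct
#'   mapped primary records in `records`.
#' @return A `WindowTrack` data.frame (`chrom`, `start`, `end`, `widx`,
#'   `raw`, `rpm`, `excluded`) with `total_mapped` and `window_size`
#'   attributes.
#' @export
window_counts <- function(records, grid, mask = NULL, total_mapped = NULL) {
  known <- names(attr(grid, "chrom_lengths"))
  mapped_chroms <- unique(records$chrom[records$is_mapped])
  if (length(setdiff(mapped_chroms, known)))
    stop("record on unknown chromosome: ",
         paste(setdiff(mapped_chroms, known), collapse = ", "))
  if (is.null(total_mapped)) total_mapped <- count_mapped_records(records)
  wgr <- grid_granges(grid)
  raw <- integer(nrow(grid))
  sgr <- segments_granges(records)
  if (length(sgr) && length(wgr)) {
    h <- GenomicRanges::findOverlaps(sgr, wgr, ignore.strand = TRUE)
    pairs <- unique(data.frame(
      rec = S4Vectors::mcols(sgr)$rec_id[S4Vectors::queryHits(h)],
      w = S4Vectors::subjectHits(h)))
    tab <- table(pairs$w)
    raw[as.integer(names(tab))] <- as.integer(tab)
  }
  track <- as.data.frame(grid)
  track$raw <- raw
  track$rpm <- if (total_mapped > 0) raw * 1e6 / total_mapped else raw * 0
  track$excluded <- if (!is.null(mask) && length(mask) && length(wgr))
    IRanges::overlapsAny(wgr, mask, ignore.strand = TRUE) else
    rep(FALSE, nrow(grid))
  attr(track, "window_size") <- attr(grid, "window_size")
  attr(track, "chrom_lengths") <- attr(grid, "chrom_lengths")
  attr(track, "total_mapped") <- total_mapped
  class(track) <- c("WindowTrack", "data.frame")
  track
}

#' Exact Poisson upper-tail probability P(X >= x)
#'
#' @param x observed count(s).
#' @param lambda Poisson mean.
#' @return P(X >= x); 1 for `x <= 0`.  With `lambda = 0` a nonzero count
#'   has probability 0 (trivially covered).
#' @export
poisson_upper_tail <- function(x, lambda) {
  ifelse(x <= 0, 1, stats::ppois(x - 1, lambda, lower.tail = FALSE))
}

#' Fit the stage-1 Poisson background model
#'
#' `lambda` is the arithmetic mean of raw counts over all non-excluded
#' windows (the maximum-likelihood fit), zeros included by default.
#'
#' @param track a [window_counts()] track.
#' @param alpha_covered upper-tail threshold for "covered" windows.
#' @param include_zeros include zero-count windows in the fit.
#' @return A `PoissonModel` (list with `lambda`, `alpha_covered`).
#' @export
fit_poisson <- function(track, alpha_covered = 1e-5, include_zeros = TRUE) {
  x <- track$raw[!track$excluded]
  if (!include_zeros) x <- x[x > 0]
  if (!length(x)) stop("no non-excluded windows to fit")
  structure(list(lambda = mean(x), alpha_covered = alpha_covered),
            class = "PoissonModel")
}

#' Covered windows under the Poisson model
#'
#' @param track a [window_counts()] track.
#' @param model a [fit_poisson()] model.
#' @return Integer vector of covered window indices (`widx`): non-excluded
#'   windows with upper-tail P(X >= raw) < `alpha_covered`.
#' @export
covered_windows <- function(track, model) {
  p <- poisson_upper_tail(track$raw, model$lambda)
  track$widx[!track$excluded & p < model$alpha_covered]
}

#' Moment-fit a negative binomial to covered-window counts
#'
#' Method of moments: `p = mean/var`, `r = mean^2/(var - mean)`.  When the
#' counts are under-dispersed (`var <= mean`) the fit falls back to a
#' Poisson with the same mean, and the fallback is recorded.
#'
#' @param counts raw counts of the covered windows (>= 2 values required;
#'   with fewer the model is unavailable and `NULL` is returned, in which
#'   case the caller reports no peaks).
#' @param alpha_peak upper-tail threshold for peak windows.
#' @return A `NegBinModel` (list with `r`, `p`, `fitted_mean`, `fitted_var`,
#'   `poisson_fallback`, `alpha_peak`) or `NULL`.
#' @export
fit_negbin <- function(counts, alpha_peak = 1e-3) {
  if (length(counts) < 2L) return(NULL)
  m <- mean(counts)
  v <- stats::var(counts)
  if (v <= m) {
    return(structure(list(r = NA_real_, p = NA_real_, fitted_mean = m,
                          fitted_var = v, poisson_fallback = TRUE,
                          alpha_peak = alpha_peak), class = "NegBinModel"))
  }
  structure(list(r = m^2 / (v - m), p = m / v, fitted_mean = m,
                 fitted_var = v, poisson_fallback = FALSE,
                 alpha_peak = alpha_peak), class = "NegBinModel")
}

#' Exact negative-binomial upper-tail probability P(X >= x)
#'
#' Uses the Poisson tail at the fitted mean when the model fell back.
#'
#' @param x observed count(s).
#' @param model a [fit_negbin()] model.
#' @return P(X >= x); 1 for `x <= 0`.
#' @export
negbin_upper_tail <- function(x, model) {
  if (isTRUE(model$poisson_fallback))
    return(poisson_upper_tail(x, model$fitted_mean))
  ifelse(x <= 0, 1,
         stats::pnbinom(x - 1, size = model$r, prob = model$p,
                        lower.tail = FALSE))
}

#' Call peak regions
#'
#' A window is significant iff it is covered and its raw count has
#' upper-tail probability < `alpha_peak` under the negative binomial.
#' Adjacent (boundary-sharing) significant windows are merged into peak
#' regions; p-values are raw, with no multiple-testing correction (bare
#' thresholds are applied throughout).
#'
#' @param track a [window_counts()] track.
#' @param covered covered window indices from [covered_windows()].
#' @param model a [fit_negbin()] model (or `NULL` for no peaks).
#' @return A data.frame of `PeakRegion`s: `chrom`, `start`, `end`,
#'   `n_windows`, `max_raw`, `min_p`.
#' @export
call_peaks <- function(track, covered, model) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      max_raw = integer(0), min_p = numeric(0))
  if (is.null(model) || !length(covered)) return(empty)
  sub <- track[track$widx %in% covered, , drop = FALSE]
  pv <- negbin_upper_tail(sub$raw, model)
  sig <- sub[pv < model$alpha_peak, , drop = FALSE]
  sigp <- pv[pv < model$alpha_peak]
  if (!nrow(sig)) return(empty)
  run <- cumsum(c(1L, diff(sig$widx) != 1L))
  out <- do.call(rbind, lapply(split(seq_len(nrow(sig)), run), function(i) {
    data.frame(chrom = sig$chrom[i[1]], start = min(sig$start[i]),
               end = max(sig$end[i]), n_windows = length(i),
               max_raw = max(sig$raw[i]), min_p = min(sigp[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Annotate peak regions against features
#'
#' Each peak is labeled with every feature overlapping it by >= 1 bp;
#' peaks with no overlapping feature are labeled `"unannotated"`.
#'
#' @param peaks a [call_peaks()] data.frame.
#' @param features a `GRanges` with an `ID` (or `Name`) metadata column, a
#'   `te_loci` data.frame, or a GFF3 path.
#' @return `peaks` with a `labels` column (comma-separated feature ids).
#' @export
annotate_peaks <- function(peaks, features) {
  fgr <- features_granges(features)
  peaks$labels <- rep("unannotated", nrow(peaks))
  if (!nrow(peaks) || !length(fgr)) return(peaks)
  pgr <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(peaks$start + 1L, peaks$end))
  h <- GenomicRanges::findOverlaps(pgr, fgr, ignore.strand = TRUE)
  ids <- feature_ids(fgr)
  lab <- tapply(ids[S4Vectors::subjectHits(h)], S4Vectors::queryHits(h),
                function(x) paste(unique(x), collapse = ","))
  peaks$labels[as.integer(names(lab))] <- as.character(lab)
  peaks
}

features_granges <- function(features) {
  if (inherits(features, "GRanges")) return(features)
  if (is.character(features) && length(features) == 1L)
    return(te_loci_granges(read_te_gff(features)))
  if (is.data.frame(features)) return(te_loci_granges(features))
  stop("unsupported feature annotation type")
}

te_loci_granges <- function(loci) {
  if (!nrow(loci)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start + 1L, loci$end),
                               strand = loci$strand %||% "*")
  S4Vectors::mcols(gr)$ID <- loci$te_id
  S4Vectors::mcols(gr)$family <- loci$family %||% NA_character_
  gr
}

feature_ids <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$ID)) return(as.character(mc$ID))
  if (!is.null(mc$Name)) return(as.character(mc$Name))
  as.character(seq_along(gr))
}

#' Read a TE annotation GFF3 into a locus table
#'
#' Coordinates are converted from GFF's 1-based closed to 0-based half-open.
#' Malformed (non-comment, < 9 column) lines raise an error naming the line.
#'
#' @param path GFF3 file path.
#' @return A `te_loci` data.frame: `te_id`, `family`, `chrom`, `start`,
#'   `end`, `strand` (plus LTR spans when a `ltr_len` attribute is present).
#' @export
read_te_gff <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) < 9L)
      stop("malformed GFF line ", i, " in ", path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  ids <- if (!is.null(mc$ID)) as.character(mc$ID) else as.character(mc$Name)
  fam <- if (!is.null(mc$family)) as.character(mc$family) else ids
  out <- data.frame(
    te_id = ids, family = fam,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  out$strand[out$strand == "*"] <- "+"
  if (!is.null(mc$ltr_len)) {
    ll <- as.integer(as.character(mc$ltr_len))
    out$ltr5_start <- out$start
    out$ltr5_end <- out$start + ll
    out$ltr3_start <- out$end - ll
    out$ltr3_end <- out$end
  }
  out
}

#' Export a window track as bedGraph
#'
#' @param track a [window_counts()] track.
#' @param path output path.
#' @param what `"raw"` or `"rpm"`.
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, what = c("rpm", "raw")) {
  what <- match.arg(what)
  df <- data.frame(track$chrom, track$start, track$end, track[[what]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export peak regions as BED6
#'
#' Name = labels, score = -10*log10(min_p) style -log10 capped at 1000.
#'
#' @param peaks an annotated peak data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (!nrow(peaks)) { writeLines(character(0), path); return(invisible(path)) }
  score <- pmin(round(-log10(pmax(peaks$min_p, 1e-300))), 1000)
  df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   peaks$labels %||% ".", score, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
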