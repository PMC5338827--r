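# Split-read detection: junction-spanning reads of an eccDNA circle align
# as two segments at the element's two ends.  This module provides a
# gapless seed-and-extend split aligner (for FASTQ-level validation), a
# FLAG-based split-read classifier for SAM-derived records, split-read
# coverage tracks, and 2-LTR circular-junction calling with perfect /
# imperfect (inserted bases, e.g. a PBS remnant) classes.

#' Split-alignment acceptance parameters
#'
#' The four acceptance thresholds mirror the accuracy / minimum score /
#' minimum segment length / read-coverage parameters of split-aware
#' read mappers: every reported segment must reach `min_identity` and
#' `min_segment_len`, the segments together must cover at least
#' `min_read_coverage` of the read, and their summed matched bases must
#' reach `min_score`.
#'
#' @param min_identity minimum per-segment identity (fraction).
#' @param min_score minimum summed matched bases.
#' @param min_segment_len minimum segment length (bp).
#' @param min_read_coverage minimum fraction of the read covered by
#'   segments.
#' @param seed_len exact seed length used for anchoring.
#' @return A `SplitAlignParams` list.
#' @export
split_align_params <- function(min_identity = 0.95, min_score = 24L,
                               min_segment_len = 25L,
                               min_read_coverage = 0.95, seed_len = 15L) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_read_coverage > 0, min_read_coverage <= 1,
            min_score > 0, min_segment_len > 0, seed_len > 0)
  structure(list(min_identity = min_identity, min_score = min_score,
                 min_segment_len = min_segment_len,
                 min_read_coverage = min_read_coverage,
                 seed_len = seed_len), class = "SplitAlignParams")
}

#' Build an exact-seed index over reference sequences
#'
#' Hashes every `seed_len`-mer of every reference sequence to its
#' positions; used by [split_align()] to anchor candidate diagonals.
#'
#' @param seqs named character vector (or `DNAStringSet`) of reference
#'   sequences.
#' @param seed_len seed length.
#' @return A `SeedIndex`.
#' @export
seed_index <- function(seqs, seed_len = 15L) {
  if (inherits(seqs, "DNAStringSet")) {
    nm <- names(seqs); seqs <- as.character(seqs); names(seqs) <- nm
  }
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[[i]])
    if (n < seed_len) next
    pos <- 1:(n - seed_len + 1L)
    km <- substring(seqs[[i]], pos, pos + seed_len - 1L)
    sp <- split(pos, km)
    for (key in names(sp)) {
      idx[[key]] <- rbind(idx[[key]], cbind(i, sp[[key]]))
    }
  }
  structure(list(seqs = seqs, lens = nchar(seqs), seed_len = seed_len,
                 hash = idx), class = "SeedIndex")
}

# Match indicator of `read` against sequence `i` of the index on diagonal
# `d` (0-based: query position q aligns to reference position d + q,
# 1-based).  Returns the cumulative match count vector plus the in-bounds
# query range.
diagonal_matches <- function(read, refseq, reflen, d) {
  R <- nchar(read)
  qlo <- max(1L, 1L - d)
  qhi <- min(R, reflen - d)
  m <- logical(R)
  if (qhi >= qlo) {
    rr <- charToRaw(substr(read, qlo, qhi))
    fr <- charToRaw(substr(refseq, d + qlo, d + qhi))
    m[qlo:qhi] <- rr == fr
  }
  list(cum = cumsum(m), qlo = qlo, qhi = qhi)
}

# Candidate diagonals (i, d) for a read against the index, from exact
# seed hits, in canonical (i, d) order.
candidate_diagonals <- function(read, index) {
  R <- nchar(read); k <- index$seed_len
  if (R < k) return(NULL)
  qpos <- 1:(R - k + 1L)
  kmers <- substring(read, qpos, qpos + k - 1L)
  out <- NULL
  for (j in seq_along(kmers)) {
    h <- index$hash[[kmers[j]]]
    if (!is.null(h)) out <- rbind(out, cbind(h[, 1L], h[, 2L] - qpos[j]))
  }
  if (is.null(out)) return(NULL)
  out <- unique(out)
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' Gapless seed-and-extend split alignment of one read
#'
#' Anchors exact seeds, evaluates candidate diagonals on both strands and
#' reports the best two-segment split under the acceptance thresholds
#' (each segment gapless, `>= min_segment_len`, identity `>=
#' min_identity`; summed query coverage `>= min_read_coverage` of the
#' read; summed matched bases `>= min_score`), maximizing total matched
#' bases with a fixed deterministic tie-break (forward strand, then
#' smaller first-segment length, smaller query gap, then reference
#' order).  Reads whose best full-length contiguous placement already
#' reaches `min_identity` are not split (they are ordinary alignments)
#' and yield `NULL`, as does a read with no qualifying split.
#'
#' @param read read sequence (character).
#' @param index a [seed_index()].
#' @param params a [split_align_params()].
#' @return `NULL`, or a `SplitEvidence` list with `segments` (two rows:
#'   `chrom`, `start`, `end` 0-based half-open, `strand`, `qstart`,
#'   `qend`, `matched_bases`), `inserted` (query bases between the
#'   segments, in alignment orientation) and `score`.
#' @export
split_align <- function(read, index, params = split_align_params()) {
  R <- nchar(read)
  minZ <- params$min_segment_len
  min_cov <- as.integer(ceiling(params$min_read_coverage * R))
  gmax <- R - min_cov
  best <- NULL

  for (orient in c("+", "-")) {
    s <- if (orient == "+") read else revcomp(read)
    diags <- candidate_diagonals(s, index)
    if (is.null(diags)) next
    nd <- nrow(diags)
    pre <- vector("list", nd)
    # full-length contiguous placement suppresses splitting
    for (j in seq_len(nd)) {
      i <- diags[j, 1L]; d <- diags[j, 2L]
      dm <- diagonal_matches(s, index$seqs[[i]], index$lens[[i]], d)
      pre[[j]] <- dm
      if (dm$qlo == 1L && dm$qhi == R && dm$cum[R] >= params$min_identity * R)
        return(NULL)
    }
    if (R < 2L * minZ) next

    # per-breakpoint best prefix/suffix over diagonals (first max wins,
    # diagonals are in canonical order)
    pref <- matrix(-1L, nd, R)   # score of [1..b] on diagonal j
    suff <- matrix(-1L, nd, R)   # score of [b+1..R] on diagonal j
    for (j in seq_len(nd)) {
      dm <- pre[[j]]
      if (dm$qlo == 1L) {
        ub <- dm$qhi
        if (ub >= 1L) pref[j, 1:ub] <- dm$cum[1:ub]
      }
      if (dm$qhi == R) {
        lb <- dm$qlo  # suffix [b+1..R] valid iff b+1 >= qlo
        for (b in max(1L, lb - 1L):(R - 1L)) suff[j, b] <- dm$cum[R] - dm$cum[b]
      }
    }

    for (b1 in minZ:(R - minZ)) {
      for (g in 0:min(gmax, R - minZ - b1)) {
        b2 <- b1 + g
        len2 <- R - b2
        if (len2 < minZ) next
        s1 <- pref[, b1]
        s1[s1 < params$min_identity * b1] <- -1L
        j1 <- which.max(s1)
        if (s1[j1] < 0) next
        s2 <- suff[, b2]
        s2[s2 < params$min_identity * len2] <- -1L
        j2 <- which.max(s2)
        if (s2[j2] < 0) next
        total <- s1[j1] + s2[j2]
        if (total < params$min_score) next
        if (!is.null(best) && total <= best$score) next
        d1 <- unname(diags[j1, 2L]); i1 <- unname(diags[j1, 1L])
        d2 <- unname(diags[j2, 2L]); i2 <- unname(diags[j2, 1L])
        best <- list(
          score = as.integer(total), orient = orient, b1 = b1, b2 = b2,
          segments = data.frame(
            chrom = unname(names(index$seqs)[c(i1, i2)]),
            start = as.integer(c(d1, d2 + b2)),  # 0-based: ref pos of q is d+q
            end = as.integer(c(d1 + b1, d2 + R)),
            strand = orient,
            qstart = as.integer(c(0L, b2)), qend = as.integer(c(b1, R)),
            matched_bases = as.integer(c(s1[j1], s2[j2])),
            stringsAsFactors = FALSE, row.names = NULL),
          inserted = substr(s, b1 + 1L, b2))
      }
    }
  }
  if (is.null(best)) return(NULL)
  structure(best, class = "SplitEvidence")
}

#' Classify split reads from alignment records
#'
#' A record is split-read (SR) evidence iff it is a primary record, its
#' pair is flagged not-proper, and it carries two or more aligned
#' segments; secondary records never contribute.
#'
#' @param records a `mob_alignments` table.
#' @return The subset of `records` belonging to SR evidence records.
#' @export
classify_sr <- function(records) {
  if (!nrow(records)) return(records)
  nseg <- stats::ave(as.integer(records$is_mapped), records$rec_id,
                     FUN = sum)
  keep <- records$is_primary & !records$proper_pair & nseg >= 2L &
    records$is_mapped
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  mob_alignments(out)
}

#' Split-read window coverage track
#'
#' Same counting and rpm semantics as [window_counts()], restricted to SR
#' evidence; the rpm denominator stays the full library's mapped-record
#' count.
#'
#' @param evidence SR records from [classify_sr()].
#' @param grid a [window_grid()].
#' @param total_mapped mapped-record count of the full library.
#' @param mask optional `GRanges` of masked regions.
#' @return A `WindowTrack`.
#' @export
sr_window_coverage <- function(evidence, grid, total_mapped, mask = NULL) {
  window_counts(evidence, grid, mask = mask, total_mapped = total_mapped)
}

#' Call 2-LTR circular junctions from split evidence
#'
#' For each split record whose two segments land in one TE locus (or in
#' two copies of the same family, reported at the upstream segment's
#' locus): if the query-first segment ends within `tolerance` of the TE
#' 3' terminus and the query-second segment starts within `tolerance` of
#' the 5' terminus, the read spans the circle junction --- `perfect` when
#' no bases are inserted between the segments, `imperfect` otherwise
#' (e.g. a primer-binding-site remnant).  All other same-TE splits are
#' `internal`.
#'
#' @param evidence SR records ([classify_sr()] subset) or a list of
#'   [split_align()] `SplitEvidence` objects.
#' @param te_loci a TE locus table ([read_te_gff()] or a bundle's
#'   `te_loci`).
#' @param tolerance maximum distance (bp) from the element termini.
#' @return A data.frame of `JunctionCall`s: `te_id`, `read_id`,
#'   `dist_to_3prime_end`, `dist_to_5prime_start`, `inserted`, `klass`.
#' @export
call_junctions <- function(evidence, te_loci, tolerance = 20L) {
  empty <- data.frame(te_id = character(0), read_id = character(0),
                      dist_to_3prime_end = integer(0),
                      dist_to_5prime_start = integer(0),
                      inserted = character(0), klass = character(0),
                      stringsAsFactors = FALSE)
  segs <- evidence_segments(evidence)
  segs <- segs[!is.na(segs$qstart), , drop = FALSE]
  if (!nrow(segs) || !nrow(te_loci)) return(empty)
  nseg <- stats::ave(rep(1L, nrow(segs)), segs$rec_id, FUN = sum)
  segs <- segs[nseg >= 2L, , drop = FALSE]
  if (!nrow(segs)) return(empty)
  segs <- segs[order(segs$rec_id, segs$qstart), ]

  # one locus per segment: maximal-overlap TE locus (NA if none)
  lgr <- te_loci_granges(te_loci)
  sgr <- GenomicRanges::GRanges(segs$chrom,
                                IRanges::IRanges(segs$start + 1L, segs$end))
  h <- GenomicRanges::findOverlaps(sgr, lgr, ignore.strand = TRUE)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    sgr[S4Vectors::queryHits(h)], lgr[S4Vectors::subjectHits(h)]))
  o <- order(S4Vectors::queryHits(h), -ov)
  firsts <- o[!duplicated(S4Vectors::queryHits(h)[o])]
  locus_idx <- rep(NA_integer_, nrow(segs))
  locus_idx[S4Vectors::queryHits(h)[firsts]] <- S4Vectors::subjectHits(h)[firsts]

  a <- segs[!duplicated(segs$rec_id), , drop = FALSE]
  b <- segs[!duplicated(segs$rec_id, fromLast = TRUE), , drop = FALSE]
  la <- locus_idx[!duplicated(segs$rec_id)]
  lb <- locus_idx[!duplicated(segs$rec_id, fromLast = TRUE)]
  ok <- !is.na(la) & !is.na(lb) &
    (te_loci$te_id[la] == te_loci$te_id[lb] |
       te_loci$family[la] == te_loci$family[lb])
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(empty)
  a <- a[ok, ]; b <- b[ok, ]
  loc <- te_loci[la[ok], ]   # family-level calls report the upstream locus

  minus <- loc$strand == "-"
  off3 <- ifelse(minus, abs(a$start - loc$start), abs(loc$end - a$end))
  off5 <- ifelse(minus, abs(loc$end - b$end), abs(b$start - loc$start))
  gap <- b$qstart - a$qend
  known <- if (!is.null(a$known_insert)) a$known_insert else
    rep(NA_character_, nrow(a))
  inserted <- ifelse(gap <= 0L, "",
                     ifelse(!is.na(known), known,
                            ifelse(!is.na(a$seq),
                                   substr(a$seq, a$qend + 1L, b$qstart),
                                   strrep("N", pmax(gap, 0L)))))
  klass <- ifelse(off3 <= tolerance & off5 <= tolerance,
                  ifelse(nchar(inserted) == 0L, "perfect", "imperfect"),
                  "internal")
  res <- data.frame(te_id = loc$te_id, read_id = a$read_id,
                    dist_to_3prime_end = off3, dist_to_5prime_start = off5,
                    inserted = inserted, klass = klass,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Flatten SR evidence (records table or SplitEvidence list) to a segment df.
evidence_segments <- function(evidence) {
  if (inherits(evidence, "mob_alignments") || is.data.frame(evidence)) {
    df <- as.data.frame(evidence)
    return(df[df$is_mapped %||% TRUE, , drop = FALSE])
  }
  if (inherits(evidence, "SplitEvidence")) evidence <- list(evidence)
  rows <- lapply(seq_along(evidence), function(i) {
    ev <- evidence[[i]]
    if (is.null(ev)) return(NULL)
    df <- ev$segments
    df$rec_id <- ev$read_id %||% sprintf("split%d", i)
    df$read_id <- df$rec_id
    df$seq <- NA_character_
    df$known_insert <- ev$inserted
    df
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(rec_id = character(0), qstart = integer(0)))
  do.call(rbind, rows)
}

#' Artificial 2-LTR junction reference for an element
#'
#' Returns the last `flank` bases of the element fused to its first
#' `flank` bases (length `2 * flank`): the sequence a perfect circle
#' junction read should align to contiguously.
#'
#' @param te a [te_element()].
#' @param flank flank length (bp); must not exceed the element length
#'   (and is typically at most the LTR length).
#' @return A nucleotide string of length `2 * flank`.
#' @export
build_junction_reference <- function(te, flank) {
  L <- te_length(te)
  if (flank > L) stop("flank exceeds element length")
  if (flank == 0L) return("")
  s <- te_sequence(te)
  paste0(substr(s, L - flank + 1L, L), substr(s, 1L, flank))
}
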