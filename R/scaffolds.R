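# Assembly-based detection support: externally assembled scaffolds are
# scored for significant read recruitment (rpm, negative-binomial upper
# tail), annotated with their best similarity hit, and a consensus
# sequence can be searched against a genome for family members.

#' Score de novo assembly scaffolds
#'
#' Normalizes per-scaffold read counts to reads per million assembly reads
#' (rpm), fits a negative binomial by moments on the rpm values across
#' scaffolds, and flags scaffolds with upper-tail p < `alpha` as
#' significantly covered.
#'
#' @param stats data.frame with `scaffold_id`, `length`, `read_count`.
#' @param total_assembly_reads total reads used for the assembly (> 0).
#' @param alpha significance threshold (default 0.05).
#' @return A `ScaffoldStat` data.frame sorted by descending rpm, with
#'   `rpm`, `p_value` and `significant` columns.  With fewer than two
#'   scaffolds significance is undefined (`NA`) and rpm is still
#'   reported.
#' @export
score_scaffolds <- function(stats, total_assembly_reads, alpha = 0.05) {
  stopifnot(total_assembly_reads > 0,
            all(c("scaffold_id", "read_count") %in% names(stats)))
  out <- stats
  out$rpm <- out$read_count * 1e6 / total_assembly_reads
  if (nrow(out) >= 2L) {
    model <- fit_negbin(out$rpm, alpha_peak = alpha)
    out$p_value <- negbin_upper_tail(ceiling(out$rpm), model)
    out$significant <- out$p_value < alpha
  } else {
    out$p_value <- NA_real_
    out$significant <- NA
  }
  out <- out[order(-out$rpm, out$scaffold_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a 12-column tabular similarity-hit file
#'
#' Standard tabular format: query, subject, percent identity, HSP length,
#' mismatches, gap opens, query start/end, subject start/end, e-value,
#' bit score.  Malformed rows raise an error naming the row.
#'
#' @param path file path.
#' @return A `SimilarityHit` data.frame.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != 12L)
      stop("malformed similarity row ", i, " in ", path,
           " (expected 12 tab-separated columns)")
  }
  if (!length(parts))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), hsp_length = integer(0),
                      mismatches = integer(0), gap_opens = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      e_value = numeric(0), bit_score = numeric(0)))
  m <- do.call(rbind, parts)
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  out <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                    identity = num(3), hsp_length = as.integer(num(4)),
                    mismatches = as.integer(num(5)),
                    gap_opens = as.integer(num(6)),
                    q_start = as.integer(num(7)), q_end = as.integer(num(8)),
                    s_start = as.integer(num(9)), s_end = as.integer(num(10)),
                    e_value = num(11), bit_score = num(12),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$identity) | is.na(out$hsp_length) | is.na(out$e_value))
  if (length(bad)) stop("malformed similarity row ", bad[1], " in ", path)
  out
}

#' Best-hit annotation of scaffolds
#'
#' Keeps, per scaffold, the single hit with the lowest e-value among hits
#' with `e_value < max_e` and `hsp_length >= min_hsp` (ties: highest HSP
#' length, then subject id); scaffolds with no qualifying hit are
#' unannotated.  Deterministic under input permutation.
#'
#' @param hits a [read_blast_tab()] data.frame (or path).
#' @param min_hsp minimum HSP length (bp).
#' @param max_e maximum e-value (strict).
#' @param scaffold_ids optional full scaffold id set, so unannotated
#'   scaffolds appear with `NA` hits.
#' @return data.frame mapping `scaffold_id` to its best hit (or `NA`).
#' @export
best_hit_annotation <- function(hits, min_hsp = 100L, max_e = 1e-2,
                                scaffold_ids = NULL) {
  if (is.character(hits)) hits <- read_blast_tab(hits)
  all_ids <- sort(unique(c(hits$query_id, scaffold_ids)))
  keep <- hits[hits$e_value < max_e & hits$hsp_length >= min_hsp, , drop = FALSE]
  keep <- keep[order(keep$query_id, keep$e_value, -keep$hsp_length,
                     keep$subject_id), , drop = FALSE]
  best <- keep[!duplicated(keep$query_id), , drop = FALSE]
  i <- match(all_ids, best$query_id)
  data.frame(scaffold_id = all_ids,
             subject_id = best$subject_id[i],
             identity = best$identity[i],
             hsp_length = best$hsp_length[i],
             e_value = best$e_value[i],
             annotated = !is.na(i),
             stringsAsFactors = FALSE)
}

#' Family-member search thresholds
#'
#' Defaults target full-length LTR-retrotransposon family members: HSP
#' longer than 4 kb, at least 70% identity, e-value below 1e-50.
#'
#' @param min_hsp minimum HSP length (bp, strict).
#' @param min_identity minimum percent identity.
#' @param max_e maximum e-value (strict).
#' @return A `FamilySearchParams` list.
#' @export
family_search_params <- function(min_hsp = 4000L, min_identity = 70,
                                 max_e = 1e-50) {
  stopifnot(min_hsp > 0, min_identity > 0, max_e > 0)
  structure(list(min_hsp = min_hsp, min_identity = min_identity,
                 max_e = max_e), class = "FamilySearchParams")
}

#' Find genomic family members of a consensus element
#'
#' Either filters a precomputed similarity-hit table, or runs an internal
#' desk-scale gapless local-similarity scan of the consensus against a
#' genome: exact seeds define candidate diagonals, the best-scoring local
#' segment per diagonal is found with match +1 / mismatch -2 scoring, and
#' an e-value is assigned with ungapped Karlin-Altschul statistics
#' (lambda = 1.28, K = 0.46 for that scoring).  Hits passing all three
#' thresholds are merged per genomic locus.
#'
#' @param consensus consensus nucleotide sequence (character).
#' @param genome named character vector / `DNAStringSet` / FASTA path, or
#'   `NULL` when `hits` are supplied.
#' @param params a [family_search_params()].
#' @param hits optional precomputed [read_blast_tab()] table (subject
#'   coordinates are the genomic loci).
#' @param seed_len exact seed length for the internal scan.
#' @return data.frame of merged loci: `chrom`, `start`, `end` (0-based
#'   half-open), `n_hits`.
#' @export
find_family_members <- function(consensus, genome = NULL,
                                params = family_search_params(),
                                hits = NULL, seed_len = 12L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_hits = integer(0))
  if (is.null(genome) && is.null(hits))
    stop("either a genome or a precomputed hit table is required")

  if (!is.null(hits)) {
    keep <- hits[hits$hsp_length > params$min_hsp &
                   hits$identity >= params$min_identity &
                   hits$e_value < params$max_e, , drop = FALSE]
    if (!nrow(keep)) return(empty)
    gr <- GenomicRanges::GRanges(
      keep$subject_id,
      IRanges::IRanges(pmin(keep$s_start, keep$s_end),
                       pmax(keep$s_start, keep$s_end)))
    red <- interval_set(gr)
    cnt <- GenomicRanges::countOverlaps(red, gr)
    return(data.frame(chrom = as.character(GenomeInfoDb::seqnames(red)),
                      start = GenomicRanges::start(red) - 1L,
                      end = GenomicRanges::end(red), n_hits = cnt))
  }

  gen <- as_dna_set(genome)
  gseq <- as.character(gen)
  idx <- seed_index(gseq, seed_len)
  total_n <- sum(nchar(gseq))
  m_len <- nchar(consensus)
  lambda <- 1.28; K <- 0.46   # ungapped Karlin-Altschul, +1/-2 scoring

  found <- list()
  for (orient in c("+", "-")) {
    qs <- if (orient == "+") consensus else revcomp(consensus)
    diags <- candidate_diagonals(qs, idx)
    if (is.null(diags)) next
    # require a little seed support to bound the scan
    for (j in seq_len(nrow(diags))) {
      i <- diags[j, 1L]; d <- diags[j, 2L]
      dm <- diagonal_matches(qs, idx$seqs[[i]], idx$lens[[i]], d)
      if (dm$qhi < dm$qlo) next
      mvec <- diff(c(0, dm$cum))[dm$qlo:dm$qhi] > 0
      ks <- kadane(ifelse(mvec, 1, -2))
      if (ks$score <= 0) next
      q1 <- dm$qlo + ks$from - 1L; q2 <- dm$qlo + ks$to - 1L
      hsp_len <- q2 - q1 + 1L
      matches <- dm$cum[q2] - (if (q1 > 1L) dm$cum[q1 - 1L] else 0L)
      identity <- 100 * matches / hsp_len
      e_val <- K * m_len * total_n * exp(-lambda * ks$score)
      if (hsp_len > params$min_hsp && identity >= params$min_identity &&
          e_val < params$max_e) {
        found[[length(found) + 1L]] <- data.frame(
          chrom = names(idx$seqs)[i],
          start = d + q1 - 1L, end = d + q2, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(found)) return(empty)
  df <- do.call(rbind, found)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
  red <- interval_set(gr)
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red),
             n_hits = GenomicRanges::countOverlaps(red, gr))
}

# Maximum-scoring contiguous subarray (Kadane), 1-based from/to.
kadane <- function(x) {
  best <- 0; bf <- 0L; bt <- 0L
  cur <- 0; cf <- 1L
  for (i in seq_along(x)) {
    if (cur <= 0) { cur <- 0; cf <- i }
    cur <- cur + x[i]
    if (cur > best) { best <- cur; bf <- cf; bt <- i }
  }
  list(score = best, from = bf, to = bt)
}
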