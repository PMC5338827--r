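# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive re-derivations (pmf summation, exhaustive diagonal
# enumeration, position-by-position scans) kept separate from the package's
# own code paths.

# Upper-tail P(X >= x) by direct pmf summation; the summation bound is the
# 1e-18 upper quantile so the truncated mass is far below the comparison
# tolerance.
brute_pois_tail <- function(x, lambda) {
  if (x <= 0) return(1)
  hi <- max(x, stats::qpois(1e-18, lambda, lower.tail = FALSE)) + 1000
  sum(stats::dpois(x:hi, lambda))
}

brute_nb_tail <- function(x, size, prob) {
  if (x <= 0) return(1)
  hi <- max(x, stats::qnbinom(1e-18, size = size, prob = prob,
                              lower.tail = FALSE)) + 1000
  sum(stats::dnbinom(x:hi, size = size, prob = prob))
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# Exhaustive two-breakpoint split aligner over every diagonal of every
# reference sequence, applying the same acceptance thresholds and the same
# deterministic tie-break as split_align: any qualifying full-length
# contiguous placement suppresses splitting; among splits, maximize total
# matched bases, first-found wins in (orientation +, b1 asc, gap asc,
# sequence asc, diagonal asc) order.
brute_split_align <- function(read, seqs, params) {
  R <- nchar(read)
  minZ <- params$min_segment_len
  min_cov <- as.integer(ceiling(params$min_read_coverage * R))
  gmax <- R - min_cov
  refraw <- lapply(seqs, charToRaw)
  lens <- nchar(seqs)
  best <- NULL

  for (orient in c("+", "-")) {
    s <- if (orient == "+") read else oracle_revcomp(read)
    sraw <- charToRaw(s)
    # per-(seq, diagonal) cumulative matches; diagonal d means query q sits
    # at reference position d + q (1-based)
    cums <- list()
    meta <- list()
    for (i in seq_along(seqs)) {
      for (d in (-R):(lens[i] - 1L)) {
        qlo <- max(1L, 1L - d); qhi <- min(R, lens[i] - d)
        if (qhi < qlo) next
        m <- logical(R)
        m[qlo:qhi] <- sraw[qlo:qhi] == refraw[[i]][(d + qlo):(d + qhi)]
        cums[[length(cums) + 1L]] <- cumsum(m)
        meta[[length(meta) + 1L]] <- c(i = i, d = d, qlo = qlo, qhi = qhi)
      }
    }
    # contiguous suppression
    for (j in seq_along(cums)) {
      mt <- meta[[j]]
      if (mt["qlo"] == 1L && mt["qhi"] == R &&
          cums[[j]][R] >= params$min_identity * R) return(NULL)
    }
    if (R < 2L * minZ) next

    # best prefix/suffix per breakpoint (first max in canonical order)
    best1 <- rep(-1L, R); arg1 <- rep(NA_integer_, R)
    best2 <- rep(-1L, R); arg2 <- rep(NA_integer_, R)
    for (j in seq_along(cums)) {
      mt <- meta[[j]]; cm <- cums[[j]]
      if (mt["qlo"] == 1L) {
        bs <- 1:mt[["qhi"]]
        up <- bs[cm[bs] > best1[bs]]
        best1[up] <- cm[up]; arg1[up] <- j
      }
      if (mt["qhi"] == R) {
        bs <- max(1L, mt[["qlo"]] - 1L):(R - 1L)
        sc <- cm[R] - cm[bs]
        up <- sc > best2[bs]
        best2[bs[up]] <- sc[up]; arg2[bs[up]] <- j
      }
    }
    for (b1 in minZ:(R - minZ)) {
      for (g in 0:min(gmax, R - minZ - b1)) {
        b2 <- b1 + g; len2 <- R - b2
        if (len2 < minZ) next
        s1 <- best1[b1]; s2 <- best2[b2]
        if (s1 < params$min_identity * b1) next
        if (s2 < params$min_identity * len2) next
        total <- s1 + s2
        if (total < params$min_score) next
        if (!is.null(best) && total <= best$score) next
        m1 <- meta[[arg1[b1]]]; m2 <- meta[[arg2[b2]]]
        d1 <- unname(m1["d"]); d2 <- unname(m2["d"])
        best <- list(score = as.integer(total), orient = orient,
                     segments = data.frame(
                       chrom = unname(names(seqs)[c(m1["i"], m2["i"])]),
                       start = as.integer(c(d1, d2 + b2)),
                       end = as.integer(c(d1 + b1, d2 + R)),
                       strand = orient,
                       qstart = as.integer(c(0L, b2)),
                       qend = as.integer(c(b1, R)),
                       matched_bases = as.integer(c(s1, s2)),
                       stringsAsFactors = FALSE, row.names = NULL),
                     inserted = substr(s, b1 + 1L, b2))
      }
    }
  }
  best
}

# Brute-force organelle homology scan: every nuclear position whose
# min_exact-mer occurs anywhere in the organelle set (either strand).
brute_organelle_scan <- function(chroms, organelles, min_exact = 50L) {
  km <- new.env(hash = TRUE, parent = emptyenv())
  for (o in organelles) {
    for (s in c(o, oracle_revcomp(o))) {
      n <- nchar(s)
      if (n < min_exact) next
      for (p in 1:(n - min_exact + 1L))
        km[[substr(s, p, p + min_exact - 1L)]] <- TRUE
    }
  }
  hits <- list()
  for (nm in names(chroms)) {
    cs <- chroms[[nm]]
    n <- nchar(cs)
    covered <- logical(n)
    if (n >= min_exact) for (p in 1:(n - min_exact + 1L)) {
      if (!is.null(km[[substr(cs, p, p + min_exact - 1L)]]))
        covered[p:(p + min_exact - 1L)] <- TRUE
    }
    if (any(covered)) {
      r <- rle(covered)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      hits[[nm]] <- data.frame(chrom = nm, start = starts[keep] - 1L,
                               end = ends[keep])
    }
  }
  if (!length(hits)) return(data.frame(chrom = character(0),
                                       start = integer(0), end = integer(0)))
  do.call(rbind, c(hits, make.row.names = FALSE))
}
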