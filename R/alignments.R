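# Alignment records: a flat segment table with one row per aligned segment
# and one row per unmapped record.  Coordinates are 0-based half-open
# internally; conversion to/from SAM's 1-based closed happens only at the
# format boundary.

#' Construct an alignment-record table
#'
#' Builds the package's flat alignment representation (one row per aligned
#' segment, one row per unmapped record) from a data.frame, filling flag
#' and bookkeeping columns with defaults: a mapped, properly paired,
#' primary single-segment mate 1 covering its full read.
#'
#' @param df data.frame with at least `read_id`, `chrom`, `start`, `end`
#'   (0-based half-open); optional overrides for any record column
#'   (`mate`, `is_mapped`, `mate_mapped`, `proper_pair`, `is_primary`,
#'   `strand`, `qstart`, `qend`, `matched_bases`, `read_length`,
#'   `seg_index`, `seq`).
#' @return A `mob_alignments` table.
#' @export
alignment_records <- function(df) {
  n <- nrow(df)
  df$mate <- df$mate %||% rep(1L, n)
  df$is_mapped <- df$is_mapped %||% rep(TRUE, n)
  df$mate_mapped <- df$mate_mapped %||% rep(TRUE, n)
  df$proper_pair <- df$proper_pair %||% rep(TRUE, n)
  df$is_primary <- df$is_primary %||% rep(TRUE, n)
  df$strand <- df$strand %||% rep("+", n)
  df$seg_index <- df$seg_index %||% rep(1L, n)
  df$rec_id <- df$rec_id %||% paste(df$read_id, df$mate, sep = ":")
  width <- ifelse(df$is_mapped, df$end - df$start, 0L)
  df$qstart <- df$qstart %||% rep(0L, n)
  df$qend <- df$qend %||% (df$qstart + width)
  df$read_length <- df$read_length %||% df$qend
  df$matched_bases <- df$matched_bases %||% width
  df$seq <- df$seq %||% rep(NA_character_, n)
  mob_alignments(df[, c("rec_id", "read_id", "mate", "is_mapped",
                        "mate_mapped", "proper_pair", "is_primary", "chrom",
                        "start", "end", "strand", "qstart", "qend",
                        "matched_bases", "read_length", "seg_index", "seq")])
}

mob_alignments <- function(df) {
  needed <- c("rec_id", "read_id", "mate", "is_mapped", "mate_mapped",
              "proper_pair", "is_primary", "chrom", "start", "end", "strand",
              "qstart", "qend", "matched_bases", "read_length", "seg_index",
              "seq")
  stopifnot(all(needed %in% names(df)))
  class(df) <- c("mob_alignments", "data.frame")
  df
}

empty_alignments <- function() {
  mob_alignments(data.frame(
    rec_id = character(0), read_id = character(0), mate = integer(0),
    is_mapped = logical(0), mate_mapped = logical(0),
    proper_pair = logical(0), is_primary = logical(0),
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), qstart = integer(0), qend = integer(0),
    matched_bases = integer(0), read_length = integer(0),
    seg_index = integer(0), seq = character(0), stringsAsFactors = FALSE))
}

# GRanges of the mapped segment rows (names = row indices into `records`).
segments_granges <- function(records) {
  m <- records[records$is_mapped & !is.na(records$chrom), , drop = FALSE]
  if (!nrow(m)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(m$chrom,
                               IRanges::IRanges(start = m$start + 1L, end = m$end),
                               strand = "*")
  S4Vectors::mcols(gr)$rec_id <- m$rec_id
  S4Vectors::mcols(gr)$row <- as.integer(rownames(m) %||% seq_len(nrow(m)))
  gr
}

# Number of distinct mapped primary records (the rpm denominator).
count_mapped_records <- function(records) {
  length(unique(records$rec_id[records$is_mapped & records$is_primary]))
}

#' Idealized alignments for a simulated library
#'
#' Places every simulated read at its true origin, bypassing an external
#' aligner: genomic pairs are placed at their sampled locus as proper pairs;
#' circle reads are placed on the source TE locus, with junction-wrapping
#' reads emitted as two split segments (element 3' end, element 5' start)
#' and their pair flagged not-proper so the split-read classifier accepts
#' them; organelle reads map to a planted nuclear organelle insert when
#' their span lies within the inserted substring, and are unmapped to the
#' nucleus otherwise.
#'
#' @param bundle the [build_reference()] bundle the library was simulated from.
#' @param sim a [simulate_reads()] result for that bundle.
#' @return A `mob_alignments` segment table.
#' @export
idealized_alignments <- function(bundle, sim) {
  stopifnot(inherits(bundle, "ReferenceBundle"), inherits(sim, "MobilomeSim"))
  if (!identical(sim$bundle_seed, bundle$seed))
    stop("simulation was produced from a different reference bundle")
  truth <- sim$truth
  R <- sim$params$read_len
  circ_by_te <- stats::setNames(sim$circles,
                                vapply(sim$circles, `[[`, character(1), "source_te"))

  seg <- list()
  add <- function(read_id, mate, mapped, chrom, start, end, strand, qstart, qend,
                  seg_index) {
    seg[[length(seg) + 1L]] <<- data.frame(
      read_id = read_id, mate = mate, is_mapped = mapped,
      chrom = chrom, start = start, end = end, strand = strand,
      qstart = qstart, qend = qend, seg_index = seg_index,
      stringsAsFactors = FALSE)
  }

  # --- genome pairs: single segments, proper ---
  g <- truth[truth$origin == "genome", , drop = FALSE]
  if (nrow(g)) {
    add(g$read_id, 1L, TRUE, g$template, g$start, g$start + R, "+", 0L, R, 1L)
    add(g$read_id, 2L, TRUE, g$template, g$start + g$frag_len - R,
        g$start + g$frag_len, "-", 0L, R, 1L)
  }

  # --- organelle pairs: mapped only through planted nuclear inserts ---
  o <- truth[truth$origin == "organelle", , drop = FALSE]
  if (nrow(o)) {
    ins <- bundle$nuclear_organelle_inserts
    place <- function(a) {
      # a = organelle-space start of a mate span [a, a+R)
      chrom <- rep(NA_character_, length(a))
      gs <- rep(NA_integer_, length(a))
      if (nrow(ins)) for (j in seq_len(nrow(ins))) {
        hit <- is.na(chrom) & ins$organelle[j] == "organelle" &
          a >= ins$org_start[j] & (a + R) <= ins$org_end[j]
        chrom[hit] <- ins$chrom[j]
        gs[hit] <- ins$start[j] + (a[hit] - ins$org_start[j])
      }
      list(chrom = chrom, start = gs)
    }
    p1 <- place(o$start)
    p2 <- place(o$start + o$frag_len - R)
    add(o$read_id, 1L, !is.na(p1$chrom), p1$chrom, p1$start, p1$start + R,
        "+", 0L, R, 1L)
    add(o$read_id, 2L, !is.na(p2$chrom), p2$chrom, p2$start, p2$start + R,
        "-", 0L, R, 1L)
  }

  # --- circle pairs: wrap-aware placement on the source TE locus ---
  cc <- truth[truth$origin == "circle", , drop = FALSE]
  if (nrow(cc)) {
    for (te_id in unique(cc$template)) {
      tpl <- circ_by_te[[te_id]]
      C <- tpl$length; J <- tpl$junction_offset
      locus <- bundle$te_loci[match_circle_locus(bundle$te_loci, te_id), , drop = FALSE]
      if (nrow(locus) != 1L)
        stop("no unique TE locus for circle source '", te_id, "'")
      ls <- locus$start
      rows <- cc[cc$template == te_id, , drop = FALSE]
      for (m in 1:2) {
        a <- if (m == 1) rows$start %% C else
          (rows$start + rows$frag_len - R) %% C
        str <- if (m == 1) "+" else "-"
        # segment 1: [a, a+R) ∩ [0, J)   (element part, first period)
        s1a <- a; s1b <- pmin(a + R, J)
        has1 <- s1a < J & s1b > s1a
        # segment 2: [a, a+R) ∩ [C, C+J) (element part after wrapping origin)
        s2a <- pmax(a, C); s2b <- pmin(a + R, C + J)
        has2 <- (a + R) > C & s2b > s2a
        i1 <- which(has1)
        if (length(i1))
          add(rows$read_id[i1], m, TRUE, locus$chrom,
              ls + s1a[i1], ls + s1b[i1], str, 0L, s1b[i1] - s1a[i1], 1L)
        i2 <- which(has2)
        if (length(i2))
          add(rows$read_id[i2], m, TRUE, locus$chrom,
              ls + s2a[i2] - C, ls + s2b[i2] - C, str,
              s2a[i2] - a[i2], s2b[i2] - a[i2],
              ifelse(has1[i2], 2L, 1L))
        i0 <- which(!has1 & !has2)
        if (length(i0))
          add(rows$read_id[i0], m, FALSE, NA_character_, NA_integer_,
              NA_integer_, "+", NA_integer_, NA_integer_, 1L)
      }
    }
  }

  if (!length(seg)) return(empty_alignments())
  df <- do.call(rbind, seg)

  # pair-level flags
  key <- paste(df$read_id, df$mate, sep = ":")
  df$rec_id <- key
  nseg <- tapply(df$seg_index, key, max)
  mapped_by_key <- tapply(df$is_mapped, key, any)
  other_key <- paste(df$read_id, 3L - df$mate, sep = ":")
  df$mate_mapped <- as.logical(mapped_by_key[other_key])
  df$mate_mapped[is.na(df$mate_mapped)] <- FALSE
  split_by_read <- tapply(nseg >= 2L, sub(":[12]$", "", names(nseg)), any)
  rd <- sub(":[12]$", "", key)
  df$proper_pair <- df$is_mapped & df$mate_mapped & !as.logical(split_by_read[rd])
  df$is_primary <- TRUE
  df$read_length <- R
  df$matched_bases <- ifelse(df$is_mapped, df$qend - df$qstart, 0L)
  # canonical representation of unmapped records: no placement fields
  un <- !df$is_mapped
  df$chrom[un] <- NA_character_
  df$start[un] <- NA_integer_
  df$end[un] <- NA_integer_
  df$strand[un] <- "+"
  df$qstart[un] <- NA_integer_
  df$qend[un] <- NA_integer_

  # SEQ in alignment orientation: reverse-strand mates store the reverse
  # complement of the sequenced read (i.e. the forward-template substring).
  seq1 <- sim$reads1; seq2 <- revcomp(sim$reads2)
  names(seq2) <- names(sim$reads2)
  df$seq <- ifelse(df$mate == 1L, seq1[df$read_id], seq2[df$read_id])

  df <- df[order(df$read_id, df$mate, df$seg_index), ]
  rownames(df) <- NULL
  mob_alignments(df[, c("rec_id", "read_id", "mate", "is_mapped", "mate_mapped",
                        "proper_pair", "is_primary", "chrom", "start", "end",
                        "strand", "qstart", "qend", "matched_bases",
                        "read_length", "seg_index", "seq")])
}

# A circle named after an element id may sit at a locus named "<id>_c<k>";
# prefer an exact te_id match, then the element id with a unique copy.
match_circle_locus <- function(te_loci, te_id) {
  hit <- which(te_loci$te_id == te_id)
  if (length(hit) == 1L) return(hit)
  hit <- which(te_loci$element_id == te_id)
  if (length(hit) == 1L) return(hit)
  integer(0)
}

#' Write alignment records as SAM
#'
#' Emits one line per segment: the first segment of a record as the primary
#' line, further segments as supplementary (flag 0x800) lines with
#' soft-clipped CIGARs.  Internal 0-based half-open coordinates are
#' converted to SAM's 1-based.
#'
#' @param records a `mob_alignments` table.
#' @param path output SAM path.
#' @param seqlengths named integer vector of reference sequence lengths for
#'   the `@SQ` header.
#' @return invisibly, `path`.
#' @export
write_sam <- function(records, path, seqlengths) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), as.integer(seqlengths)))
  if (!nrow(records)) { writeLines(hdr, path); return(invisible(path)) }
  df <- records
  # mate-first-segment lookup for RNEXT/PNEXT and the mate-reverse flag
  first <- df[df$seg_index == 1L, ]
  mk <- paste(first$read_id, first$mate, sep = ":")
  mate_chrom <- stats::setNames(first$chrom, mk)
  mate_pos <- stats::setNames(first$start, mk)
  mate_strand <- stats::setNames(first$strand, mk)
  ok <- paste(df$read_id, 3L - df$mate, sep = ":")

  flag <- 1L +
    ifelse(df$proper_pair, 2L, 0L) +
    ifelse(df$is_mapped, 0L, 4L) +
    ifelse(df$mate_mapped, 0L, 8L) +
    ifelse(df$is_mapped & df$strand == "-", 16L, 0L) +
    ifelse(df$mate_mapped & !is.na(mate_strand[ok]) & mate_strand[ok] == "-", 32L, 0L) +
    ifelse(df$mate == 1L, 64L, 128L) +
    ifelse(df$is_primary, 0L, 256L) +
    ifelse(df$seg_index > 1L, 2048L, 0L)

  lead <- df$qstart
  alen <- df$qend - df$qstart
  trail <- df$read_length - df$qend
  cigar <- ifelse(df$is_mapped,
                  paste0(ifelse(lead > 0, paste0(lead, "S"), ""),
                         alen, "M",
                         ifelse(trail > 0, paste0(trail, "S"), "")),
                  "*")
  rname <- ifelse(df$is_mapped, df$chrom, "*")
  pos <- ifelse(df$is_mapped, df$start + 1L, 0L)
  mc <- mate_chrom[ok]
  rnext <- ifelse(!df$mate_mapped | is.na(mc), "*",
                  ifelse(df$is_mapped & mc == df$chrom, "=", mc))
  pnext <- ifelse(df$mate_mapped & !is.na(mc), mate_pos[ok] + 1L, 0L)
  mapq <- ifelse(df$is_mapped, 60L, 0L)
  seqf <- ifelse(is.na(df$seq), "*", df$seq)
  qual <- ifelse(is.na(df$seq), "*", strrep("I", nchar(df$seq)))

  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                   df$read_id, flag, rname, pos, mapq, cigar, rnext,
                   as.integer(pnext), seqf, qual)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SAM file into alignment records
#'
#' Parses SAM (via Rsamtools) into the flat segment representation:
#' 1-based closed SAM coordinates become 0-based half-open; supplementary
#' lines are merged into their primary record's segment list (ordered by
#' query offset); each secondary line becomes its own record with
#' `is_primary = FALSE`.
#'
#' @param path SAM file path; the header must declare all reference
#'   sequences.
#' @return A `mob_alignments` table.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  bam <- tryCatch(
    Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE),
    error = function(e) stop("failed to parse SAM (unknown reference name ",
                             "or malformed record?): ", conditionMessage(e)))
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar", "seq", "qwidth"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (!n) return(empty_alignments())

  flag <- x$flag
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L)
  is_mapped <- bitwAnd(flag, 4L) == 0L
  mate_mapped <- bitwAnd(flag, 8L) == 0L
  proper <- bitwAnd(flag, 2L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  supp <- bitwAnd(flag, 2048L) > 0L
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")

  cigar <- x$cigar
  refw <- rep(NA_integer_, n)
  qstart <- rep(NA_integer_, n)
  qalen <- rep(NA_integer_, n)
  mlen <- rep(0L, n)
  ci <- which(is_mapped & !is.na(cigar))
  if (length(ci)) {
    cg <- cigar[ci]
    refw[ci] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cg)
    qr <- GenomicAlignments::cigarRangesAlongQuerySpace(
      cg, ops = c("M", "I", "=", "X"))
    rg <- unlist(range(qr))
    qstart[ci] <- IRanges::start(rg) - 1L
    qalen[ci] <- IRanges::end(rg) - IRanges::start(rg) + 1L
    opt <- GenomicAlignments::cigarOpTable(cg)
    mlen[ci] <- as.integer(opt[, "M"] + opt[, "="] + opt[, "X"])
  }

  chrom <- as.character(x$rname)
  start <- ifelse(is_mapped, x$pos - 1L, NA_integer_)
  end <- ifelse(is_mapped, start + refw, NA_integer_)
  bad <- which(is_mapped & end > hdr[chrom])
  if (length(bad))
    stop("alignment extends beyond declared length of '", chrom[bad[1]], "'")

  rec_id <- paste(x$qname, mate, sep = ":")
  sec_idx <- which(secondary)
  if (length(sec_idx))
    rec_id[sec_idx] <- paste(rec_id[sec_idx], "sec", sec_idx, sep = ":")

  df <- data.frame(
    rec_id = rec_id, read_id = x$qname, mate = mate,
    is_mapped = is_mapped, mate_mapped = mate_mapped, proper_pair = proper,
    is_primary = !secondary,
    chrom = chrom, start = start, end = end, strand = strand,
    qstart = ifelse(is_mapped, qstart, NA_integer_),
    qend = ifelse(is_mapped, qstart + qalen, NA_integer_),
    matched_bases = mlen,
    read_length = ifelse(is.na(x$qwidth), nchar(as.character(x$seq)),
                         x$qwidth),
    seq = as.character(x$seq),
    stringsAsFactors = FALSE)

  # order segments within a record by query offset, drop duplicated
  # unmapped placeholders, index segments
  df <- df[order(df$rec_id, df$qstart, df$start, na.last = TRUE), ]
  df$seg_index <- stats::ave(seq_len(nrow(df)), df$rec_id,
                             FUN = seq_along)
  rownames(df) <- NULL
  mob_alignments(df[, c("rec_id", "read_id", "mate", "is_mapped", "mate_mapped",
                        "proper_pair", "is_primary", "chrom", "start", "end",
                        "strand", "qstart", "qend", "matched_bases",
                        "read_length", "seg_index", "seq")])
}
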