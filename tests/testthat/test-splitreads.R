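# Split-read detection: the seed-and-extend split aligner, FLAG-based SR
# classification, SR coverage and 2-LTR junction calls.

test_that("a read built from the element's two ends splits into two segments", {
  te <- small_te()
  ref <- with_seed(21, c(chr1 = paste0(mobscan:::random_dna(300),
                                       te_sequence(te),
                                       mobscan:::random_dna(300))))
  L <- te_length(te)
  # 80-bp flanks reach into the internal region on both sides, so the
  # placement is unambiguous (a pure-LTR flank would match both LTR copies
  # and resolve to the leftmost by the deterministic tie-break)
  read <- paste0(substr(te_sequence(te), L - 79, L),
                 substr(te_sequence(te), 1, 80))
  idx <- seed_index(ref, seed_len = 15)
  hit <- split_align(read, idx)
  expect_false(is.null(hit))
  expect_equal(nrow(hit$segments), 2)
  expect_equal(hit$segments$qend - hit$segments$qstart, c(80, 80))
  # TE occupies [300, 300 + L); segments sit at its 3' end and 5' start
  expect_equal(hit$segments$start, c(300 + L - 80, 300))
  expect_equal(hit$segments$end, c(300 + L, 380))
  expect_equal(hit$inserted, "")
})

test_that("segments shorter than the minimum length are rejected", {
  te <- small_te()
  ref <- with_seed(22, c(chr1 = paste0(mobscan:::random_dna(200),
                                       te_sequence(te),
                                       mobscan:::random_dna(200))))
  L <- te_length(te)
  read <- paste0(substr(te_sequence(te), L - 79, L),   # 80 bp
                 substr(te_sequence(te), 1, 20))       # 20 bp < 25
  idx <- seed_index(ref, seed_len = 15)
  hit <- split_align(read, idx)
  # no qualifying split: the 20-bp part is under min_segment_len and the
  # 80-bp part alone cannot reach 95% read coverage
  expect_null(hit)
})

test_that("contiguously mappable reads are not reported as splits", {
  ref <- with_seed(23, c(chr1 = mobscan:::random_dna(2000)))
  idx <- seed_index(ref, seed_len = 15)
  read <- substr(ref[[1]], 501, 600)
  expect_null(split_align(read, idx))
})

test_that("split_align matches the exhaustive two-breakpoint oracle", {
  with_seed(31, {
    ref <- c(refA = mobscan:::random_dna(2000))
    params <- split_align_params(seed_len = 8)
    idx <- seed_index(ref, seed_len = 8)
    mutate1 <- function(s) {
      p <- sample.int(nchar(s), 1)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
      s
    }
    n_checked <- 0
    for (i in 1:60) {
      cls <- sample(c("exact", "junction", "gap", "random", "mut"), 1)
      R <- sample(c(50, 56, 60), 1)
      read <- switch(cls,
        exact = { a <- sample(1800, 1); substr(ref, a, a + R - 1) },
        junction = {
          h <- R %/% 2
          a <- sample(900, 1); b <- sample(900, 1) + 1000
          paste0(substr(ref, a, a + h - 1), substr(ref, b, b + R - h - 1))
        },
        gap = {
          g <- sample(0:(R - as.integer(ceiling(0.95 * R))), 1)
          h <- (R - g) %/% 2
          a <- sample(900, 1); b <- sample(900, 1) + 1000
          paste0(substr(ref, a, a + h - 1),
                 mobscan:::random_dna(g),
                 substr(ref, b, b + (R - g - h) - 1))
        },
        random = mobscan:::random_dna(R),
        mut = {
          a <- sample(1800, 1)
          mutate1(substr(ref, a, a + R - 1))
        })
      got <- split_align(read, idx, params)
      want <- brute_split_align(read, ref, params)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_false(is.null(got))
        expect_equal(got$segments, want$segments)
        expect_equal(got$inserted, want$inserted)
        expect_equal(got$score, want$score)
      }
      n_checked <- n_checked + 1
    }
    expect_equal(n_checked, 60)
  })
})

test_that("SR classification follows the primary / not-proper / multi-segment rule", {
  rec <- alignment_records(data.frame(
    read_id = c("proper", "sr", "sr", "secondary", "secondary",
                "oneseg"),
    chrom = "c1",
    start = c(0, 100, 400, 100, 400, 700),
    end = c(50, 125, 425, 125, 425, 750),
    proper_pair = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    is_primary = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    seg_index = c(1, 1, 2, 1, 2, 1)))
  rec$rec_id <- paste(rec$read_id, rec$mate, sep = ":")
  sr <- classify_sr(rec)
  expect_identical(unique(sr$read_id), "sr")
  expect_equal(nrow(sr), 2)
})

test_that("SR coverage concentrates at the element ends and stays below the total track", {
  lib <- study_library(seed = 4, circle_depth = 200, error_rate = 0)
  aln <- idealized_alignments(lib$bundle, lib$sim)
  sl <- stats::setNames(nchar(lib$bundle$chromosomes),
                        names(lib$bundle$chromosomes))
  grid <- window_grid(sl)
  total <- window_counts(aln, grid)
  sr <- classify_sr(aln)
  srt <- sr_window_coverage(sr, grid, attr(total, "total_mapped"))
  expect_true(all(srt$raw <= total$raw))
  loc <- lib$bundle$te_loci[lib$bundle$te_loci$te_id == lib$active_te, ]
  first_w <- srt$raw[srt$start >= loc$start & srt$end <= loc$start + 300]
  last_w <- srt$raw[srt$start >= loc$end - 300 & srt$end <= loc$end]
  mid_w <- srt$raw[srt$start >= loc$start + 1000 & srt$end <= loc$end - 1000]
  expect_gt(sum(first_w), 0)
  expect_gt(sum(last_w), 0)
  # oracle: junction mates counted per window from the truth table
  tr <- lib$sim$truth
  n_junction_mates <- sum(tr$m1_wraps, na.rm = TRUE) +
    sum(tr$m2_wraps, na.rm = TRUE)
  expect_equal(sum(srt$raw > 0 & (srt$start < loc$start + 300 |
                                    srt$end > loc$end - 300)) > 0, TRUE)
  expect_gt(n_junction_mates, 0)
  # all SR mass sits in the terminal windows, none mid-element
  expect_equal(sum(mid_w), 0)
  # no SR evidence -> all-zero track
  empty <- sr_window_coverage(classify_sr(aln[0, ]), grid, 1000)
  expect_true(all(empty$raw == 0))
})

test_that("junction calls separate perfect, imperfect and internal splits", {
  loci <- data.frame(te_id = "te1", family = "fam1", chrom = "c1",
                     start = 1000, end = 2000, strand = "+")
  mk <- function(id, s1, e1, s2, e2, gap = 0, seq = NA) {
    alignment_records(data.frame(
      read_id = id, chrom = "c1",
      start = c(s1, s2), end = c(e1, e2),
      proper_pair = FALSE,
      qstart = c(0, (e1 - s1) + gap),
      qend = c(e1 - s1, (e1 - s1) + gap + (e2 - s2)),
      read_length = (e1 - s1) + gap + (e2 - s2),
      seg_index = c(1, 2), seq = seq))
  }
  # ends exactly at TE end / starts at TE start, no insert -> perfect
  perfect <- mk("p", 1950, 2000, 1000, 1050)
  # same with 12 inserted query bases -> imperfect
  imperfect <- mk("i", 1950, 2000, 1000, 1050, gap = 12,
                  seq = paste0(strrep("A", 50), "TGGTATCAGAGC", strrep("C", 50)))
  # both segments internal to the TE -> internal
  internal <- mk("n", 1200, 1250, 1400, 1450)
  calls <- call_junctions(rbind(perfect, imperfect, internal), loci)
  expect_equal(calls$klass[match(c("p", "i", "n"), calls$read_id)],
               c("perfect", "imperfect", "internal"))
  expect_equal(calls$inserted[calls$read_id == "i"], "TGGTATCAGAGC")
  expect_equal(calls$dist_to_3prime_end[calls$read_id == "p"], 0)
  expect_equal(calls$dist_to_5prime_start[calls$read_id == "p"], 0)
})

test_that("junction reference is the element's end fused to its start", {
  te <- small_te()
  s <- te_sequence(te)
  L <- te_length(te)
  jr <- build_junction_reference(te, 30)
  expect_equal(nchar(jr), 60)
  expect_identical(jr, paste0(substr(s, L - 29, L), substr(s, 1, 30)))
  expect_identical(build_junction_reference(te, 0), "")
  expect_error(build_junction_reference(te, L + 1), "exceeds")
  # a perfect-junction read aligns to it contiguously (hence: no split)
  read <- paste0(substr(s, L - 24, L), substr(s, 1, 25))
  idx <- seed_index(c(junction = build_junction_reference(te, 40)),
                    seed_len = 10)
  expect_null(split_align(read, idx, split_align_params(seed_len = 10)))
})

test_that("no junction is called for TEs without simulated circles", {
  lib <- study_library(seed = 6, circle_depth = 150, error_rate = 0)
  aln <- idealized_alignments(lib$bundle, lib$sim)
  sr <- classify_sr(aln)
  calls <- call_junctions(sr, lib$bundle$te_loci)
  expect_true(all(calls$te_id == lib$active_te))
  inactive <- setdiff(lib$bundle$te_loci$te_id, lib$active_te)
  expect_false(any(calls$te_id %in% inactive))
})
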