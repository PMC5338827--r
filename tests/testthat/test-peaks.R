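# Window grid, counting semantics, and the Poisson / negative-binomial
# two-stage peak caller.

test_that("windows tile chromosomes exactly, keeping a short trailing window", {
  g <- window_grid(c(c1 = 1000))
  expect_equal(nrow(g), 10)
  g2 <- window_grid(c(c1 = 250))
  expect_equal(g2$start, c(0, 100, 200))
  expect_equal(g2$end, c(100, 200, 250))
  expect_equal(nrow(window_grid(c(c1 = 0))), 0)
  # tiling invariant: disjoint, union = [0, len)
  expect_equal(sum(g2$end - g2$start), 250)
})

test_that("a boundary-spanning record increments both windows", {
  rec <- alignment_records(data.frame(read_id = "r", chrom = "c1",
                                      start = 95, end = 155))
  trk <- window_counts(rec, window_grid(c(c1 = 1000)))
  expect_equal(trk$raw[1:3], c(1, 1, 0))
})

test_that("rpm normalization divides by total mapped records", {
  rec <- alignment_records(data.frame(read_id = sprintf("r%d", 1:7),
                                      chrom = "c1", start = 10, end = 60))
  trk <- window_counts(rec, window_grid(c(c1 = 1000)), total_mapped = 2e6)
  expect_equal(trk$raw[1], 7)
  expect_equal(trk$rpm[1], 3.5)
})

test_that("summed window counts bound the record count", {
  # sum_w raw >= n records, equality iff no record crosses a boundary
  with_seed(42, {
    for (i in 1:5) {
      n <- 50
      starts <- sample(0:950, n, replace = TRUE)
      rec <- alignment_records(data.frame(
        read_id = sprintf("r%d", seq_len(n)), chrom = "c1",
        start = starts, end = starts + 40))
      trk <- window_counts(rec, window_grid(c(c1 = 1000)))
      crossers <- sum((starts %/% 100) != ((starts + 39) %/% 100))
      expect_equal(sum(trk$raw), n + crossers)
    }
  })
})

test_that("records on undeclared chromosomes are rejected", {
  rec <- alignment_records(data.frame(read_id = "r", chrom = "cX",
                                      start = 0, end = 50))
  expect_error(window_counts(rec, window_grid(c(c1 = 1000))),
               "unknown chromosome")
})

test_that("Poisson fit and covered-window calls follow the exact tail", {
  # 999 zeros and one 50: lambda 0.05, only the spike is covered
  raw <- c(rep(0, 999), 50)
  rec <- alignment_records(data.frame(
    read_id = sprintf("r%d", 1:50), chrom = "c1",
    start = 99950, end = 99999))
  trk <- window_counts(rec, window_grid(c(c1 = 100000)))
  m <- fit_poisson(trk)
  expect_equal(m$lambda, 0.05)
  cw <- covered_windows(trk, m)
  expect_equal(cw, 1000L)
  expect_lt(brute_pois_tail(50, 0.05), 1e-5)
})

test_that("the covered threshold at lambda 1 matches brute-force summation", {
  model <- structure(list(lambda = 1, alpha_covered = 1e-5),
                     class = "PoissonModel")
  smallest_impl <- min(which(vapply(1:50, function(k)
    poisson_upper_tail(k, 1) < 1e-5, logical(1))))
  smallest_brute <- min(which(vapply(1:50, function(k)
    brute_pois_tail(k, 1) < 1e-5, logical(1))))
  expect_equal(smallest_impl, smallest_brute)
  expect_equal(smallest_impl, 9L)
})

test_that("homogeneous counts yield no covered windows", {
  starts <- rep(seq(0, 950, by = 100) + 10, each = 10)
  rec <- alignment_records(data.frame(
    read_id = sprintf("r%d", 1:100), chrom = "c1",
    start = starts, end = starts + 50))
  trk <- window_counts(rec, window_grid(c(c1 = 1000)))
  expect_true(all(trk$raw == 10))
  expect_length(covered_windows(trk, fit_poisson(trk)), 0)
})

test_that("negative-binomial moment fit matches the closed form", {
  nb <- fit_negbin(c(2, 6))        # mean 4, var 8
  expect_equal(nb$p, 0.5)
  expect_equal(nb$r, 4)
  # under-dispersion falls back to Poisson
  nb2 <- fit_negbin(c(4, 4, 4))
  expect_true(nb2$poisson_fallback)
  # fewer than two covered windows: model unavailable
  expect_null(fit_negbin(c(5)))
})

test_that("moment fit recovers NB parameters from simulated draws", {
  x <- with_seed(7, stats::rnbinom(10000, size = 5, prob = 0.3))
  nb <- fit_negbin(x)
  expect_lt(abs(nb$r - 5) / 5, 0.10)
  expect_lt(abs(nb$p - 0.3) / 0.3, 0.05)
})

test_that("reported tail p-values match brute-force pmf summation", {
  nb <- fit_negbin(c(2, 6, 9, 1, 0, 14, 3, 3))
  for (x in c(1, 5, 10, 30)) {
    expect_equal(negbin_upper_tail(x, nb),
                 brute_nb_tail(x, nb$r, nb$p), tolerance = 1e-12)
    expect_equal(poisson_upper_tail(x, 4.75),
                 brute_pois_tail(x, 4.75), tolerance = 1e-12)
  }
})

test_that("peak calling merges adjacent significant windows and stays within covered", {
  # counts: background 2s, one block of three hot windows, a gap, one more
  raw <- rep(2, 100)
  raw[40:42] <- c(60, 80, 70)
  raw[50] <- 90
  grid <- window_grid(c(c1 = 10000))
  trk <- grid
  trk$raw <- raw
  trk$rpm <- raw
  trk$excluded <- FALSE
  attr(trk, "total_mapped") <- 1e6
  class(trk) <- c("WindowTrack", "data.frame")
  pois <- fit_poisson(trk)
  cw <- covered_windows(trk, pois)
  expect_setequal(cw, c(40, 41, 42, 50))
  # fixed NB background model (mean 4): all four hot windows are extreme
  nb <- structure(list(r = 4, p = 0.5, fitted_mean = 4, fitted_var = 8,
                       poisson_fallback = FALSE, alpha_peak = 1e-3),
                  class = "NegBinModel")
  peaks <- call_peaks(trk, cw, nb)
  expect_equal(nrow(peaks), 2)
  expect_equal(peaks$start, c(3900, 4900))
  expect_equal(peaks$end, c(4200, 5000))
  expect_equal(peaks$n_windows, c(3, 1))
  expect_equal(peaks$max_raw, c(80, 90))
  # only covered windows are eligible: a hot count outside `covered` is
  # never reported
  peaks2 <- call_peaks(trk, setdiff(cw, 50), nb)
  expect_equal(nrow(peaks2), 1)
  # no covered windows -> no peaks; no model -> no peaks
  expect_equal(nrow(call_peaks(trk, integer(0), nb)), 0)
  expect_equal(nrow(call_peaks(trk, cw, NULL)), 0)
})

test_that("raising a window count never removes it from a peak", {
  raw <- rep(2, 100); raw[40] <- 60
  grid <- window_grid(c(c1 = 10000))
  mk <- function(raw) {
    trk <- grid; trk$raw <- raw; trk$rpm <- raw; trk$excluded <- FALSE
    attr(trk, "total_mapped") <- 1e6
    class(trk) <- c("WindowTrack", "data.frame")
    trk
  }
  t1 <- mk(raw)
  nb <- structure(list(r = 4, p = 0.5, fitted_mean = 4, fitted_var = 8,
                       poisson_fallback = FALSE, alpha_peak = 1e-3),
                  class = "NegBinModel")
  p1 <- call_peaks(t1, covered_windows(t1, fit_poisson(t1)), nb)
  expect_equal(nrow(p1), 1)
  # raise the peak window's count, keep the same fitted models
  raw2 <- raw; raw2[40] <- 120
  t2 <- mk(raw2)
  p2 <- call_peaks(t2, covered_windows(t2, fit_poisson(t1)), nb)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$start, p1$start)
})

test_that("rpm tracks are invariant under joint scaling of counts and depth", {
  rec <- alignment_records(data.frame(
    read_id = sprintf("r%d", 1:20), chrom = "c1",
    start = rep(c(10, 210), each = 10), end = rep(c(60, 260), each = 10)))
  t1 <- window_counts(rec, window_grid(c(c1 = 1000)), total_mapped = 20)
  rec3 <- alignment_records(data.frame(
    read_id = sprintf("r%d", 1:60), chrom = "c1",
    start = rep(c(10, 210), each = 30), end = rep(c(60, 260), each = 30)))
  t3 <- window_counts(rec3, window_grid(c(c1 = 1000)), total_mapped = 60)
  expect_equal(t1$rpm, t3$rpm)
})

test_that("peaks are annotated with every overlapping feature", {
  peaks <- data.frame(chrom = "c1", start = c(150, 500, 900),
                      end = c(260, 600, 950), n_windows = 1,
                      max_raw = 10, min_p = 1e-5)
  loci <- data.frame(te_id = c("teA", "teB"), family = c("f", "f"),
                     chrom = "c1", start = c(100, 250), end = c(250, 400),
                     strand = "+")
  ann <- annotate_peaks(peaks, loci)
  expect_equal(ann$labels, c("teA,teB", "unannotated", "unannotated"))
})

test_that("malformed GFF lines are reported with their line number", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tTE\t100\t200\t.\t+\t.\tID=te1",
               "c1\tbroken line"), gff)
  expect_error(read_te_gff(gff), "line 3")
})

test_that("TE GFF written by the simulator reads back losslessly", {
  b <- small_bundle()
  gff <- tempfile(fileext = ".gff3")
  write_te_gff(b, gff)
  loci <- read_te_gff(gff)
  expect_equal(loci$te_id, b$te_loci$te_id)
  expect_equal(loci$start, b$te_loci$start)
  expect_equal(loci$end, b$te_loci$end)
  expect_equal(loci$ltr5_end - loci$ltr5_start,
               b$te_loci$ltr5_end - b$te_loci$ltr5_start)
})
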