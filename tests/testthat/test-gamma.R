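# minimal gamma table for unit tests of the null/cutoff/peak machinery
fake_gamma <- function(layout, chrom, mid, gamma_det, mask = TRUE,
                       window = 20000, step = 10000,
                       gamma_norm = NULL, sharp = NULL) {
  L <- chrom_length(layout, chrom)
  if (is.null(gamma_norm)) gamma_norm <- gamma_det * (L - mid)
  df <- data.frame(chrom = chrom, start = mid - window / 2,
                   end = mid + window / 2, mid = mid,
                   smoothed = 0, gamma_raw = gamma_det,
                   gamma_det = gamma_det, gamma_norm = gamma_norm,
                   gamma_norm_sharp = sharp %||% gamma_norm,
                   mask = mask, stringsAsFactors = FALSE)
  structure(df, layout = layout, window = window, step = step,
            class = c("micseq_gamma", "data.frame"))
}

test_that("isotonic engine matches a hand-written PAVA oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    x <- seq(0, 2e6, length.out = n)
    y <- 5 + 4 * (x / 2e6) + c(rep(0, 80), rep(3, 120)) + rnorm(n, 0, 1)
    got <- monotone_smooth(y, x, engine = "pava")$smoothed
    expect_equal(got, pava_oracle(y), tolerance = 1e-10)
    expect_true(all(diff(got) >= -1e-12))
  }
})

test_that("spline engine stays within its stated bound of the isotonic fit", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    x <- seq(0, 4e6, length.out = n)
    sdn <- 1.5
    y <- 10 + 8 * (x / 4e6)^2 + rnorm(n, 0, sdn)
    sm <- monotone_smooth(y, x, engine = "spline")$smoothed
    expect_lt(max(abs(sm - pava_oracle(y))), 5 * sdn)
    expect_true(all(diff(sm) >= -1e-8))
  }
})

test_that("already-monotone input passes through nearly unchanged", {
  x <- seq(0, 2e6, length.out = 100)
  y <- cumsum(runif(100, 0, 0.5))
  got <- monotone_smooth(y, x, engine = "pava")$smoothed
  expect_equal(got, y)
})

test_that("V-shaped profiles split at the vertex with both arms reproduced", {
  n <- 201
  x <- seq(0, 2e6, length.out = n)
  v <- abs(seq(-100, 100)) / 10 + 5       # vertex at index 101
  got <- monotone_smooth(v, x, has_rho = TRUE, median_window = 21,
                         engine = "pava")
  expect_equal(got$split, 101L)
  expect_equal(got$smoothed, v, tolerance = 1e-10)
  expect_true(all(diff(got$smoothed[1:101]) <= 1e-12))
  expect_true(all(diff(got$smoothed[101:n]) >= -1e-12))
})

test_that("gamma is the per-window slope of the smoothed profile", {
  lay <- genome_layout("chr1", 1e6)
  g <- window_grid(lay, 20000, 10000)
  mids <- g$mid
  # constant -> zero slope
  expect_equal(compute_gamma(rep(5, nrow(g)), mids, g$start, g$end),
               rep(0, nrow(g)))
  # linear ramp of slope m -> m on all interior windows (the profile is
  # constant-extrapolated past the terminal midpoints)
  m <- 3e-5
  interior <- 3:(nrow(g) - 3)
  expect_equal(compute_gamma(m * mids, mids, g$start, g$end)[interior],
               rep(m, length(interior)), tolerance = 1e-12)
  # a single step of height h confined to one window
  h <- 8
  stepped <- ifelse(mids >= 500000, h, 0)
  gr <- compute_gamma(stepped, mids, g$start, g$end)
  w <- 20000
  hit <- which(gr > 0)
  expect_equal(max(gr), h / w, tolerance = 0.5 / w)
  expect_true(all(abs(mids[hit] - 500000) <= w))
  expect_equal(sum(gr) * 10000, h, tolerance = 1e-9)  # total rise conserved
})

test_that("distance normalization turns steps into (h/w)(L - x) peaks", {
  lay <- genome_layout(c("chr1", "chr7", "chr11"), c(80e6, 60e6, 60e6))
  g <- window_grid(lay, 20000, 10000)
  w <- 20000
  h <- 6; x0 <- 48e6
  vals <- ifelse(g$chrom == "chr1" & g$mid >= x0, 10 + h, 10)
  trk <- new_track(g, vals)
  fit <- fit_trend(trk)                    # null chroms flat: beta = rho = 0
  gt <- gamma_track(trk, fit, has_rho = FALSE, engine = "pava",
                    edge_windows = 0)
  g1 <- gt[gt$chrom == "chr1", ]
  expect_equal(max(g1$gamma_norm), (h / w) * (80e6 - x0),
               tolerance = 0.01)

  # two equal-height steps: after normalization the proximal peak is
  # larger by (L - x1)/(L - x2)
  x1 <- 20e6; x2 <- 60e6
  vals2 <- 10 + 3 * (g$chrom == "chr1" & g$mid >= x1) +
    3 * (g$chrom == "chr1" & g$mid >= x2)
  gt2 <- gamma_track(new_track(g, vals2), fit, has_rho = FALSE,
                     engine = "pava", edge_windows = 0)
  g2 <- gt2[gt2$chrom == "chr1", ]
  p1 <- max(g2$gamma_norm[abs(g2$mid - x1) < 1e6])
  p2 <- max(g2$gamma_norm[abs(g2$mid - x2) < 1e6])
  expect_equal(p1 / p2, (80e6 - x1) / (80e6 - x2), tolerance = 0.01)
})

test_that("pure trend data detrends to near-zero gamma", {
  lay <- genome_layout(c("chr1", "chr7", "chr11"), c(80e6, 60e6, 60e6))
  g <- window_grid(lay, 20000, 10000)
  vals <- model_values(g, c(chr1 = 10, chr7 = 10, chr11 = 10), 2e-15, 0)
  trk <- new_track(g, vals)
  fit <- fit_trend(trk)
  gt <- gamma_track(trk, fit, has_rho = FALSE, engine = "pava",
                    edge_windows = 20)
  keep <- gt$mask
  expect_lt(max(abs(gt$gamma_det[keep])), 1e-10)
})

test_that("the null sigma is the trimmed sd, conservatively maximized", {
  lay <- genome_layout(c("chr7", "chr11"), c(60e6, 60e6))
  set.seed(8)
  n <- 500
  v7 <- rnorm(n, 0, 1e-8)
  v11 <- rnorm(n, 0, 2e-8)
  mids <- seq(1e4, by = 1e5, length.out = n)
  gt <- rbind(fake_gamma(lay, "chr7", mids, v7),
              fake_gamma(lay, "chr11", mids, v11))
  attr(gt, "layout") <- lay
  class(gt) <- c("micseq_gamma", "data.frame")

  nc <- null_cutoff(gt, trim = Inf)
  expect_equal(nc$sigma["chr7"], c(chr7 = sd(v7)))
  expect_equal(nc$sigma_null, max(sd(v7), sd(v11)))
  expect_equal(cutoff_at(nc, "chr7", 10e6), 3 * nc$sigma_null * 50e6)

  # trimming excludes exactly the values above the threshold
  v7t <- v7; v7t[1:5] <- 1e-6
  gtt <- rbind(fake_gamma(lay, "chr7", mids, v7t),
               fake_gamma(lay, "chr11", mids, v11))
  attr(gtt, "layout") <- lay
  class(gtt) <- c("micseq_gamma", "data.frame")
  nct <- null_cutoff(gtt, trim = 1e-7)
  expect_equal(unname(nct$sigma["chr7"]), sd(v7t[v7t <= 1e-7]))
  expect_equal(unname(nct$n_trimmed["chr7"]), 5)
  expect_error(null_cutoff(gtt, trim = -1), "trimmed")
})

test_that("peaks are supra-cutoff runs with gap merging and leftmost ties", {
  lay <- genome_layout(c("chr1", "chr7", "chr11"), c(80e6, 60e6, 60e6))
  n <- 100
  mids <- seq(5e3, by = 1e4, length.out = n)
  base <- rep(0, n)
  nc <- structure(list(sigma_null = 1e-9, sigma = c(chr7 = 1e-9),
                       n_trimmed = 0, trim = Inf, k = 3, layout = lay,
                       null_chroms = "chr7"), class = "micseq_null")

  # everything below cutoff: no peaks
  gt0 <- fake_gamma(lay, "chr1", mids, base)
  expect_equal(nrow(call_peaks(gt0, nc, min_windows = 1)), 0L)

  # two supra-cutoff runs separated by 3 sub-cutoff windows stay separate
  # at gap 1 and merge at gap 5
  gd <- base; gd[c(20:22, 26:28)] <- 1e-6
  gt1 <- fake_gamma(lay, "chr1", mids, gd)
  expect_equal(nrow(call_peaks(gt1, nc, gap = 1, min_windows = 1)), 2L)
  expect_equal(nrow(call_peaks(gt1, nc, gap = 5, min_windows = 1)), 1L)

  # masked windows cannot seed peaks
  gt2 <- fake_gamma(lay, "chr1", mids, gd, mask = seq_len(n) > 30)
  expect_equal(nrow(call_peaks(gt2, nc, min_windows = 1)), 0L)

  # leftmost apex on ties
  pk <- call_peaks(gt1, nc, gap = 5, min_windows = 1)
  expect_equal(pk$apex, mids[20])
})

test_that("peak comparison matches by overlap and reports fold changes", {
  a <- data.frame(chrom = "chr1", start = c(1e6, 30e6), end = c(2e6, 31e6),
                  apex = c(1.5e6, 30.5e6), gamma_norm = c(10, 20),
                  cutoff = c(1, 1), n_windows = c(5, 5), significant = TRUE)
  cmp <- compare_peaks(a, a)
  expect_equal(nrow(cmp$common), 2L)
  expect_equal(cmp$common$fold_change, c(1, 1))
  expect_equal(cmp$mean_fold, 1)
  expect_equal(nrow(cmp$unique_a), 0L)

  b <- a; b$gamma_norm <- a$gamma_norm / 2
  expect_equal(compare_peaks(a, b)$mean_fold, 2)

  # an extra peak in A is unique to A
  a2 <- rbind(a, data.frame(chrom = "chr1", start = 60e6, end = 61e6,
                            apex = 60.5e6, gamma_norm = 5, cutoff = 1,
                            n_windows = 3, significant = TRUE))
  cmp2 <- compare_peaks(a2, b)
  expect_equal(nrow(cmp2$common), 2L)
  expect_equal(nrow(cmp2$unique_a), 1L)
  expect_equal(cmp2$unique_a$apex, 60.5e6)
})

test_that("injected hotspots on separate chromosomes give separate peaks", {
  lay <- genome_layout(c("chr1", "chr2", "chr7", "chr11"),
                       c(60e6, 60e6, 50e6, 50e6))
  hs <- data.frame(chrom = c("chr1", "chr2"), pos = c(30e6, 40e6),
                   step = c(8, 8))
  sim <- simulate_mn(simulation_config(lay, hotspots = hs, rho = 0),
                     seed = 77)
  nt <- sim_normalized(sim)
  fit <- fit_trend(nt)
  gt <- gamma_track(nt, fit, has_rho = FALSE)
  nc <- null_cutoff(gt, trim = Inf)
  pk <- call_peaks(gt, nc)
  expect_setequal(unique(pk$chrom), c("chr1", "chr2"))
  for (i in seq_len(nrow(hs))) {
    p <- pk[pk$chrom == hs$chrom[i], ]
    expect_equal(nrow(p), 1L)
    expect_true(p$start <= hs$pos[i] && hs$pos[i] <= p$end)
  }
})
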