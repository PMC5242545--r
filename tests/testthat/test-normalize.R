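test_that("uniform GRN leaves MN values unchanged", {
  lay <- toy_layout()
  g <- window_grid(lay, 20000, 10000)
  set.seed(3)
  mn_vals <- rpois(nrow(g), 30)
  mn <- new_track(g, mn_vals, fraction = "MN")
  grn <- new_track(g, rep(50, nrow(g)), fraction = "GRN")
  out <- grn_normalize(mn, grn)
  expect_equal(out$value, as.numeric(mn_vals))
})

test_that("a shared multiplicative bias cancels", {
  lay <- genome_layout("chr1", 2e6)
  g <- window_grid(lay, 20000, 10000)
  n <- nrow(g)
  set.seed(5)
  mu_mn <- 20 + 10 * (g$mid / 2e6)^2
  mu_grn <- rep(100, n)
  bias <- rlnorm(n, 0, 0.2)
  bias <- bias / mean(bias)          # a bias field is relative: unit mean
  plain <- grn_normalize(new_track(g, mu_mn), new_track(g, mu_grn, "GRN"))
  biased <- grn_normalize(new_track(g, mu_mn * bias),
                          new_track(g, mu_grn * bias, "GRN"))
  both <- plain$mask & biased$mask
  expect_gt(mean(both), 0.95)
  expect_lt(max(abs(biased$value[both] - plain$value[both]) /
                  plain$value[both]), 1e-6)
})

test_that("GRN outlier windows and zero windows are masked", {
  lay <- genome_layout("chr1", 2e6)
  g <- window_grid(lay, 20000, 10000)
  n <- nrow(g)
  gv <- rep(100, n)
  gv[3] <- 500                       # far beyond mean + 3 sd
  gv[5] <- 0
  out <- grn_normalize(new_track(g, rep(10, n)), new_track(g, gv, "GRN"))
  expect_false(out$mask[3])
  expect_false(out$mask[5])
  expect_true(all(out$mask[-c(3, 5)]))

  g2 <- window_grid(lay, 40000, 20000)
  expect_error(grn_normalize(new_track(g, rep(1, n)),
                             new_track(g2, rep(1, nrow(g2)), "GRN")),
               "different grids")
})

test_that("alpha is the minimum sliding median", {
  lay <- genome_layout("chr1", 2e6)
  g <- window_grid(lay, 20000, 10000)
  n <- nrow(g)

  # constant track
  a <- estimate_alpha(new_track(g, rep(7, n)), m = 50)
  expect_equal(a$alpha, 7)

  # a dip wide enough to hold a full run
  v <- rep(5, n)
  v[60:180] <- 1
  expect_equal(estimate_alpha(new_track(g, v), m = 100)$alpha, 1)

  # fuzzed tracks vs brute force
  for (seed in 1:10) {
    set.seed(seed)
    v <- rpois(n, 20) + runif(n)
    m <- sample(c(5, 17, 50, 101), 1)
    expect_equal(estimate_alpha(new_track(g, v), m = m)$alpha,
                 brute_alpha(v, m))
  }
})

test_that("alpha shifts with an additive constant and over-estimates under trends", {
  lay <- genome_layout("chr1", 2e6)
  g <- window_grid(lay, 20000, 10000)
  set.seed(9)
  v <- rpois(nrow(g), 20)
  a0 <- estimate_alpha(new_track(g, v), m = 50)$alpha
  a1 <- estimate_alpha(new_track(g, v + 3.5), m = 50)$alpha
  expect_equal(a1, a0 + 3.5)

  # with beta/rho trends the sliding-median minimum sits above alpha0
  lay2 <- genome_layout("chr1", 60e6)
  sim <- simulate_mn(simulation_config(lay2, alpha0 = 20, beta = 2e-15,
                                       rho = 5e-16, bias_sd = 0),
                     seed = 21)
  grid <- window_grid(lay2, 20000, 10000)
  tr <- count_windows(read_fragments(sim$fragments_mn, lay2), grid)
  ah <- estimate_alpha(tr, m = 1000)$alpha
  expect_gte(ah, 20 - 3 * sqrt(20 / 1000))   # not below alpha0 (noise slack)
  # over-estimate is bounded by the trend's rise across the chromosome
  expect_lt(ah - 20, 2e-15 * 60e6^2)
})

test_that("alpha run shrinks with a warning on short chromosomes", {
  lay <- toy_layout()
  g <- window_grid(lay, 20000, 10000)
  expect_warning(a <- estimate_alpha(new_track(g, rep(4, nrow(g))), m = 1000),
                 "shrinking")
  expect_equal(a$alpha, 4)
  expect_equal(a$m, nrow(g))
})

test_that("depth scaling recovers median alpha ratios", {
  lay <- genome_layout(c("chr1", "chr2", "chr3"), c(2e6, 2e6, 2e6))
  g <- window_grid(lay, 20000, 10000)
  n <- nrow(g)
  a <- new_track(g, rep(10, n))
  b <- new_track(g, rep(5, n))
  ds <- depth_scale(list(A = a, B = b), reference = "A",
                    exclude_chroms = character(), m = 20)
  expect_equal(unname(ds$factors), c(1, 2))
  expect_equal(ds$tracks$B$value, rep(10, n))

  # identical samples scale by 1
  ds2 <- depth_scale(list(A = a, B = a), reference = "A",
                     exclude_chroms = character(), m = 20)
  expect_equal(unname(ds2$factors), c(1, 1))

  # scaling is idempotent
  ds3 <- depth_scale(ds$tracks, reference = "A",
                     exclude_chroms = character(), m = 20)
  expect_equal(unname(ds3$factors), c(1, 1))

  expect_error(depth_scale(list(A = a, B = b), reference = "A",
                           exclude_chroms = c("chr1", "chr2", "chr3")),
               "excluded")
})

test_that("simulated depth multipliers are recovered within 5%", {
  lay <- genome_layout(c("chr1", "chr2"), c(40e6, 40e6))
  depths <- c(1, 0.5, 2)
  tracks <- lapply(seq_along(depths), function(i) {
    sim <- simulate_mn(simulation_config(lay, alpha0 = 30, beta = 0, rho = 0,
                                         depth_mn = depths[i], bias_sd = 0),
                       seed = 100 + i)
    grid <- window_grid(lay, 20000, 10000)
    count_windows(read_fragments(sim$fragments_mn, lay), grid)
  })
  names(tracks) <- c("s1", "s2", "s3")
  ds <- depth_scale(tracks, reference = "s1", exclude_chroms = character(),
                    m = 500)
  expect_equal(unname(ds$factors), depths[1] / depths, tolerance = 0.05)
})
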