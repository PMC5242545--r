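# shared fixtures: layouts, fragment fixtures, and small simulated bundles

toy_layout <- function() genome_layout("chr1", 1e5)

mini_layout <- function() {
  genome_layout(c("chr1", "chr7", "chr11"), c(80e6, 60e6, 60e6))
}

# a deterministic fragment table passing all filters
make_fragments <- function(chrom, mids, len = 200, mapq = 60) {
  if (!length(mids)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), left_read_mid = numeric(0),
                      mapq = numeric(0), proper_pair = logical(0),
                      duplicate = logical(0), stringsAsFactors = FALSE))
  }
  data.frame(chrom = chrom, start = mids - len %/% 2,
             end = mids - len %/% 2 + len, left_read_mid = mids,
             mapq = mapq, proper_pair = TRUE, duplicate = FALSE,
             stringsAsFactors = FALSE)
}

# brute-force window membership count (the oracle for count_windows)
brute_count <- function(mids, grid_df) {
  vapply(seq_len(nrow(grid_df)), function(i) {
    sum(mids >= grid_df$start[i] & mids < grid_df$end[i])
  }, numeric(1))
}

# brute-force sliding-median alpha (the oracle for estimate_alpha)
brute_alpha <- function(v, m) {
  m <- min(m, length(v))
  min(vapply(seq_len(length(v) - m + 1L), function(i) {
    stats::median(v[i:(i + m - 1L)])
  }, numeric(1)))
}

# hand-written pool-adjacent-violators (the oracle for monotone fits)
pava_oracle <- function(y) {
  n <- length(y)
  vals <- as.numeric(y)
  wts <- rep(1, n)
  i <- 1L
  while (i < length(vals)) {
    if (vals[i] > vals[i + 1L] + 1e-15) {
      new_val <- (vals[i] * wts[i] + vals[i + 1L] * wts[i + 1L]) /
        (wts[i] + wts[i + 1L])
      vals <- c(vals[seq_len(i - 1L)], new_val,
                vals[-seq_len(i + 1L)])
      wts <- c(wts[seq_len(i - 1L)], wts[i] + wts[i + 1L],
               wts[-seq_len(i + 1L)])
      i <- max(1L, i - 1L)
    } else i <- i + 1L
  }
  rep(vals, wts)
}

# build a normalized-style track directly from per-window values
value_track <- function(layout, values, window = 20000, step = 10000,
                        fraction = "MN") {
  g <- window_grid(layout, window, step)
  stopifnot(length(values) == nrow(g))
  new_track(g, values, fraction = fraction)
}

# expected value of the representation model on a grid
model_values <- function(grid, alpha, beta, rho) {
  layout <- attr(grid, "layout")
  L <- unname(layout[grid$chrom])
  a <- alpha[grid$chrom]
  a + beta * grid$mid^2 + rho * (L - grid$mid)^2
}

# simulate `reps` replicate samples, pool each fraction, and normalize —
# the pooled-replicate design under which the 20 kb / 10 kb grid is used
sim_pooled <- function(cfg, seed, reps = 3, window = 20000, step = 10000) {
  layout <- cfg$layout
  grid <- window_grid(layout, window, step)
  mns <- list()
  grs <- list()
  for (i in seq_len(reps)) {
    sim <- simulate_mn(cfg, seed = seed * 10 + i)
    mns[[i]] <- count_windows(read_fragments(sim$fragments_mn, layout),
                              grid, fraction = "MN")
    grs[[i]] <- count_windows(read_fragments(sim$fragments_grn, layout),
                              grid, fraction = "GRN")
  }
  grn_normalize(pool_tracks(mns), pool_tracks(grs))
}

# run count -> normalize on a simulated dataset
sim_normalized <- function(sim, window = 20000, step = 10000) {
  layout <- sim$config$layout
  grid <- window_grid(layout, window, step)
  mn <- count_windows(read_fragments(sim$fragments_mn, layout), grid,
                      fraction = "MN")
  grn <- count_windows(read_fragments(sim$fragments_grn, layout), grid,
                       fraction = "GRN")
  grn_normalize(mn, grn)
}
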