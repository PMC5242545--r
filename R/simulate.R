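#' Configuration of the micronuclear coverage forward model
#'
#' The simulator draws fragment midpoints from the positional density the
#' MN representation model predicts: a per-chromosome baseline `alpha0`
#' (whole-chromosome loss plus contamination), a quadratic gain `beta*x^2`
#' toward the distal telomere (retention of acentromeric fragments from
#' breaks near the distal end), the converse proximal gain
#' `rho*(L - x)^2`, and step-like hot spots that add constant expected
#' coverage distal to the break position. The GRN control is uniform
#' before bias. A shared multiplicative window bias (log-normal,
#' normalized to unit mean — a bias field is relative by convention)
#' multiplies the expected counts of both fractions, emulating GC/strain
#' bias. Counts are Poisson by default or negative binomial for
#' over-dispersion.
#'
#' All rate parameters are expressed on the count-per-window scale of the
#' stated `window` size, so the ground truth aligns directly with what
#' [fit_trend()] estimates on tracks counted at that window size.
#'
#' @param layout a [genome_layout()].
#' @param window reference window size in bp the rates refer to
#'   (default 20000).
#' @param alpha0 expected baseline MN count per window (single value or
#'   named per chromosome).
#' @param beta,rho quadratic trend coefficients, counts per window per
#'   bp^2. Defaults (2e-15, 5e-16) put the distal gain on the same order
#'   as the baseline over a 100 Mb chromosome, as observed in wild-type
#'   MN fractions.
#' @param hotspots data.frame with columns `chrom`, `pos` (bp) and `step`
#'   (added expected counts per window distal to `pos`); `NULL` for none.
#' @param grn_level expected GRN count per window.
#' @param bias_sd log-sd of the shared log-normal window bias (0 disables).
#' @param bias_bin bias-field bin size in bp (default `window`).
#' @param depth_mn,depth_grn depth multipliers applied to all expected
#'   counts of the fraction.
#' @param noise `"poisson"` or `"nb"`; `nb_dispersion` is the NB
#'   dispersion (1/size) used when `noise = "nb"`.
#' @param bias_seed seed of the bias field, separate from the
#'   fragment-sampling seed: GC/strain bias is a property of the genome
#'   and protocol, so simulated samples sharing a `bias_seed` share the
#'   field — which is what GRN normalization and replicate pooling
#'   assume.
#' @param insert_mean,insert_sd fragment insert-size distribution (bp).
#' @param sim_bin internal sampling resolution in bp.
#' @param compartments named proportions of repeat-compartment fragments
#'   (rDNA45S, MaSat, MiSat) for [simulate_repeats()]; the remainder is
#'   genomic.
#' @return list of class `micseq_sim_config`.
#' @export
simulation_config <- function(layout,
                              window = 20000,
                              alpha0 = 20,
                              beta = 2e-15,
                              rho = 5e-16,
                              hotspots = NULL,
                              grn_level = 200,
                              bias_sd = 0.15,
                              bias_bin = window,
                              depth_mn = 1,
                              depth_grn = 1,
                              noise = c("poisson", "nb"),
                              nb_dispersion = 0.05,
                              bias_seed = 1848,
                              insert_mean = 300,
                              insert_sd = 60,
                              sim_bin = 5000,
                              compartments = c(rDNA45S = 0.01, MaSat = 0.02,
                                               MiSat = 0.005)) {
  stopifnot(inherits(layout, "micseq_layout"))
  noise <- match.arg(noise)
  if (length(alpha0) == 1L && is.null(names(alpha0))) {
    alpha0 <- stats::setNames(rep(alpha0, length(layout)), names(layout))
  }
  stopifnot(all(names(layout) %in% names(alpha0)),
            all(alpha0 >= 0), beta >= 0, rho >= 0,
            depth_mn > 0, depth_grn > 0, grn_level >= 0,
            sum(compartments) < 1, all(compartments >= 0))
  if (!is.null(hotspots)) {
    stopifnot(all(c("chrom", "pos", "step") %in% names(hotspots)))
    stopifnot(all(hotspots$chrom %in% names(layout)),
              all(hotspots$pos >= 0),
              all(hotspots$pos < chrom_length(layout, hotspots$chrom)),
              all(hotspots$step >= 0))
  }
  structure(list(layout = layout, window = window, alpha0 = alpha0,
                 beta = beta, rho = rho, hotspots = hotspots,
                 grn_level = grn_level, bias_sd = bias_sd,
                 bias_bin = bias_bin, bias_seed = bias_seed,
                 depth_mn = depth_mn,
                 depth_grn = depth_grn, noise = noise,
                 nb_dispersion = nb_dispersion, insert_mean = insert_mean,
                 insert_sd = insert_sd, sim_bin = sim_bin,
                 compartments = compartments),
            class = "micseq_sim_config")
}

# expected MN coverage density (counts per bp) at positions x on chrom
mn_density <- function(config, chrom, x) {
  L <- chrom_length(config$layout, chrom)
  w <- config$window
  d <- config$alpha0[[chrom]] / w + config$beta * x^2 / w +
    config$rho * (L - x)^2 / w
  hs <- config$hotspots
  if (!is.null(hs)) {
    for (i in which(hs$chrom == chrom)) {
      d <- d + (hs$step[i] / w) * (x >= hs$pos[i])
    }
  }
  config$depth_mn * d
}

draw_counts <- function(lambda, config) {
  if (config$noise == "poisson") stats::rpois(length(lambda), lambda)
  else stats::rnbinom(length(lambda), mu = lambda,
                      size = 1 / config$nb_dispersion)
}

#' Simulate MN and GRN fragment tables with ground truth
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; identical config + seed gives identical
#'   fragment tables.
#' @return list of class `micseq_sim` with `fragments_mn`,
#'   `fragments_grn` (fragment tables consumable by [read_fragments()]),
#'   `bias` (the shared window-bias field), and `truth`: implied `alpha`
#'   (per chromosome, counts per window), `beta`, `rho` (counts per
#'   window per bp^2), and the hot-spot table augmented with the expected
#'   normalized-gamma apex `gamma_norm_expected`.
#' @export
simulate_mn <- function(config, seed = 1) {
  stopifnot(inherits(config, "micseq_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  layout <- config$layout

  # shared bias field on bias_bin bins, unit mean genome-wide; drawn from
  # its own seed so samples in one study share it
  set.seed(config$bias_seed)
  bias <- lapply(names(layout), function(ch) {
    nb <- ceiling(unname(layout[ch]) / config$bias_bin)
    if (config$bias_sd > 0) stats::rlnorm(nb, 0, config$bias_sd) else rep(1, nb)
  })
  names(bias) <- names(layout)
  bmean <- mean(unlist(bias))
  bias <- lapply(bias, function(b) b / bmean)
  set.seed(seed)

  sample_fraction <- function(density_fun) {
    frames <- lapply(names(layout), function(ch) {
      L <- unname(layout[ch])
      starts <- seq(0, L - 1, by = config$sim_bin)
      ends <- pmin(starts + config$sim_bin, L)
      mids <- (starts + ends) / 2
      b <- bias[[ch]][pmin(floor(mids / config$bias_bin) + 1L,
                           length(bias[[ch]]))]
      lam <- density_fun(ch, mids) * (ends - starts) * b
      cnt <- draw_counts(lam, config)
      n <- sum(cnt)
      if (n == 0) return(NULL)
      binidx <- rep.int(seq_along(cnt), cnt)
      mid <- floor(starts[binidx] +
                     stats::runif(n) * (ends[binidx] - starts[binidx]))
      len <- pmax(100, round(stats::rnorm(n, config$insert_mean,
                                          config$insert_sd)))
      start <- pmax(0, mid - len %/% 2)
      end <- pmin(L, start + len)
      start <- pmin(start, mid)          # keep mid in [start, end)
      end <- pmax(end, mid + 1)
      data.frame(chrom = ch, start = start, end = end, left_read_mid = mid,
                 mapq = 60L, proper_pair = TRUE, duplicate = FALSE,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, frames[!vapply(frames, is.null, TRUE)])
    rownames(out) <- NULL
    out
  }

  mean_win <- mean(unlist(lapply(names(layout), function(ch) {
    x <- seq(0, unname(layout[ch]), length.out = 50)
    mn_density(config, ch, x) * config$window
  })))
  if (mean_win < 1) {
    warning(sprintf("infeasible depth: expected MN coverage %.2g < 1 per window",
                    mean_win))
  }
  frags_mn <- sample_fraction(function(ch, x) mn_density(config, ch, x))
  grn_density <- function(ch, x) {
    rep(config$depth_grn * config$grn_level / config$window, length(x))
  }
  frags_grn <- sample_fraction(grn_density)

  truth_hs <- config$hotspots
  if (!is.null(truth_hs)) {
    L <- chrom_length(layout, truth_hs$chrom)
    truth_hs$gamma_norm_expected <-
      config$depth_mn * truth_hs$step * (L - truth_hs$pos) / config$window
  }
  structure(list(
    fragments_mn = frags_mn,
    fragments_grn = frags_grn,
    bias = bias,
    truth = list(alpha = config$alpha0 * config$depth_mn,
                 beta = config$beta * config$depth_mn,
                 rho = config$rho * config$depth_mn,
                 hotspots = truth_hs),
    config = config, seed = seed),
    class = "micseq_sim")
}

#' Simulate repeat-compartment fragment counts
#'
#' Multinomial draw of fragments over the repeat compartments (45S rDNA,
#' major satellite, minor satellite) and the standard genome, with an
#' optional per-compartment enrichment multiplier (e.g. 3-fold rDNA
#' over-representation in MN of replication-licensing deficient animals).
#' Compartment fragments carry MAPQ 0, as multi-mapping reads within
#' concatenated repeat arrays do; genomic fragments carry MAPQ 60.
#'
#' @param config a [simulation_config()] (supplies `compartments` and the
#'   layout used to place genomic fragments).
#' @param n total number of fragments.
#' @param enrichment named multipliers on compartment proportions
#'   (probabilities renormalized afterwards).
#' @param seed integer seed.
#' @return a fragment data.frame whose `chrom` is the compartment contig
#'   name for repeat fragments.
#' @export
simulate_repeats <- function(config, n = 1e5, enrichment = NULL, seed = 1) {
  stopifnot(inherits(config, "micseq_sim_config"), n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- config$compartments
  if (!is.null(enrichment)) {
    stopifnot(all(names(enrichment) %in% names(p)))
    p[names(enrichment)] <- p[names(enrichment)] * enrichment
  }
  p_all <- c(p, genome = 1 - sum(config$compartments))
  p_all <- p_all / sum(p_all)
  cnt <- stats::rmultinom(1, n, p_all)[, 1]
  layout <- config$layout
  frames <- lapply(names(cnt), function(nm) {
    k <- cnt[[nm]]
    if (k == 0) return(NULL)
    if (nm == "genome") {
      ch <- sample(names(layout), k, replace = TRUE,
                   prob = unname(layout) / sum(layout))
      L <- chrom_length(layout, ch)
      mid <- floor(stats::runif(k) * (L - 400)) + 200
      mapq <- 60L
    } else {
      ch <- rep(nm, k)
      mid <- floor(stats::runif(k, 200, 10000))
      mapq <- 0L
    }
    data.frame(chrom = ch, start = mid - 150, end = mid + 150,
               left_read_mid = mid, mapq = mapq, proper_pair = TRUE,
               duplicate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, frames[!vapply(frames, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
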