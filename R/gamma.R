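#' Shape-constrained monotone smoothing of a coverage profile
#'
#' Localized instability (gamma) appears as cumulative step increases in
#' MN coverage distal to a breakpoint, while GC and other local biases
#' produce non-cumulative wiggles. Fitting a monotone curve suppresses the
#' latter. For chromosomes with a significant centromere-proximal (rho)
#' effect the profile is V-shaped: a monotone non-increasing fit is used
#' before the minimum-median point and a non-decreasing fit after it,
#' continuous at the split. Otherwise a single non-decreasing fit is used.
#'
#' Two engines are provided:
#' \describe{
#'   \item{`"spline"`}{a penalized cubic regression spline fitted under
#'     monotonicity constraints (mgcv's `pcls` with `mono.con`), knots
#'     every `knot_spacing` bp. The smoothing parameter is chosen by REML
#'     on the unconstrained fit unless supplied via `sp`. This is the
#'     default: its slope field is continuous, which the empirical-null
#'     significance machinery requires.}
#'   \item{`"pava"`}{exact isotonic regression
#'     (pool-adjacent-violators), the least-squares projection onto the
#'     monotone cone. Its fit is piecewise constant — razor-sharp at
#'     breakpoints but with a spiky slope distribution; it is used
#'     internally to localize peak apexes.}
#' }
#' The spline engine tracks the isotonic solution closely: on noisy
#' monotone inputs its maximum deviation from the isotonic regression is
#' bounded by a few times the local noise scale (the package tests hold
#' it under 5 standard deviations of the observation noise).
#'
#' @param values numeric coverage values for one chromosome, ordered by
#'   position; `NA`s (masked windows) are interpolated over.
#' @param mids window midpoints in bp, same length.
#' @param has_rho does this chromosome carry a rho (proximal) arm?
#' @param median_window run length (windows) of the running median used to
#'   locate the split point (default 1000, as in the alpha estimate);
#'   shrunk to the available length when necessary.
#' @param engine `"spline"` or `"pava"`.
#' @param sp smoothing parameter for the spline engine (`NULL` = chosen
#'   from the target degrees of freedom).
#' @param knot_spacing spline knot spacing in bp.
#' @param df_base,df_per_mb target effective degrees of freedom of the
#'   spline: `df_base + df_per_mb * span/1e6`, capped by the basis size.
#' @return list with `smoothed` (same length as `values`), `split`
#'   (index of the split window, `NA` when `has_rho = FALSE`), `engine`
#'   and `sp` (the smoothing parameter used, `NA` for pava).
#' @export
monotone_smooth <- function(values, mids, has_rho = FALSE,
                            median_window = 1000,
                            engine = c("spline", "pava"), sp = NULL,
                            knot_spacing = 2e6, df_base = 6,
                            df_per_mb = 0.05) {
  engine <- match.arg(engine)
  n <- length(values)
  stopifnot(length(mids) == n)
  if (sum(!is.na(values)) < 10L) stop("too few unmasked windows to smooth")
  y <- interp_na(mids, values, mids)

  fit_arm <- function(x, v, up) {
    if (engine == "pava" || length(v) < 15L || diff(range(v)) == 0) {
      if (up) stats::isoreg(seq_along(v), v)$yf
      else -stats::isoreg(seq_along(v), -v)$yf
    } else {
      mono_spline_fit(x, v, up = up, sp = sp, knot_spacing = knot_spacing,
                      df_base = df_base, df_per_mb = df_per_mb)
    }
  }

  if (!has_rho) {
    sm <- fit_arm(mids, y, TRUE)
    return(list(smoothed = sm, split = NA_integer_, engine = engine,
                sp = attr(sm, "sp") %||% NA_real_))
  }
  m <- min(median_window, n)
  med <- running_median(y, m)
  run <- which.min(med)                       # minimizing run of m windows
  split <- (run:(run + m - 1L))[which.min(y[run:(run + m - 1L)])]
  split <- min(max(split, 1L), n)
  left <- fit_arm(mids[seq_len(split)], y[seq_len(split)], FALSE)
  right <- fit_arm(mids[split:n], y[split:n], TRUE)
  junction <- min(left[split], right[1])
  left[split] <- junction
  right[1] <- junction
  list(smoothed = c(left, right[-1]), split = split, engine = engine,
       sp = attr(right, "sp") %||% NA_real_)
}

# penalized monotone cubic regression spline (mgcv pcls + mono.con);
# positions handled in Mb internally for conditioning
mono_spline_fit <- function(x, y, up = TRUE, sp = NULL, knot_spacing = 2e6,
                            df_base = 6, df_per_mb = 0.05) {
  k <- max(5L, min(length(x) - 1L, ceiling(diff(range(x)) / knot_spacing)))
  xs <- x / 1e6
  dat <- data.frame(x = xs, y = y)
  smc <- mgcv::smoothCon(mgcv::s(x, k = k, bs = "cr"), data = dat,
                         knots = NULL)[[1]]
  if (is.null(sp)) {
    df_target <- df_base + df_per_mb * diff(range(xs))
    sp <- sp_for_df(smc, df_target)
  }
  mc <- mgcv::mono.con(smc$xp, up = up)
  ramp <- if (up) seq(min(y), max(y), length.out = length(y))
  else seq(max(y), min(y), length.out = length(y))
  p0 <- qr.coef(qr(smc$X), ramp)
  fit <- tryCatch({
    G <- list(X = smc$X, C = matrix(0, 0, 0), sp = sp, p = p0, y = y,
              w = rep(1, length(y)), Ain = mc$A, bin = mc$b, S = smc$S,
              off = 0)
    drop(smc$X %*% mgcv::pcls(G))
  }, error = function(e) {
    warning("monotone spline failed (", conditionMessage(e),
            "); falling back to isotonic regression")
    if (up) stats::isoreg(seq_along(y), y)$yf
    else -stats::isoreg(seq_along(y), -y)$yf
  })
  attr(fit, "sp") <- unname(sp)
  fit
}

# smoothing parameter giving the unconstrained smooth a target effective
# df; depends only on the design (window grid), never on the data, so the
# bandwidth is identical across samples and seeds
sp_for_df <- function(smc, df_target) {
  XtX <- crossprod(smc$X)
  S <- smc$S[[1]]
  R <- chol(XtX + diag(1e-8 * mean(diag(XtX)), ncol(XtX)))
  Ri <- backsolve(R, diag(ncol(R)))
  M <- t(Ri) %*% S %*% Ri
  ev <- pmax(0, eigen((M + t(M)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values)
  nullsp <- sum(ev < 1e-10 * max(ev, 1))
  df_target <- max(min(df_target, ncol(XtX) - 0.5), nullsp + 0.5)
  f <- function(lsp) sum(1 / (1 + exp(lsp) * ev)) - df_target
  if (f(-20) < 0) return(exp(-20))
  if (f(60) > 0) return(exp(60))
  exp(stats::uniroot(f, c(-20, 60))$root)
}

#' Per-window slope of the smoothed profile (raw gamma)
#'
#' gamma for a window is the slope of the monotonically smoothed coverage
#' over that window: the smoothed profile (defined at window midpoints) is
#' linearly interpolated to the window edges and differenced, in units of
#' coverage value per bp. On non-decreasing segments gamma is nonnegative.
#'
#' @param smoothed smoothed values at the window midpoints (one
#'   chromosome).
#' @param mids,starts,ends window coordinates for the same chromosome.
#' @return numeric vector of per-window slopes.
#' @export
compute_gamma <- function(smoothed, mids, starts, ends) {
  stopifnot(length(smoothed) == length(mids))
  s_at <- function(x) interp_na(mids, smoothed, x)
  (s_at(ends) - s_at(starts)) / (ends - starts)
}

#' Full gamma decomposition of a normalized track
#'
#' Runs [monotone_smooth()] and [compute_gamma()] per chromosome, removes
#' the fitted beta/rho trend slope, and applies the distance
#' normalization: `gamma_det = gamma_raw - max(0, trend slope)` and
#' `gamma_norm = gamma_det * (L - x)`, the distance to the distal
#' telomere. The trend slope is clipped at zero before subtraction so
#' detrending cannot manufacture negative-gamma artifacts on the
#' decreasing (rho) arm. Multiplying by `L - x` removes the positional
#' bias of raw gamma: a breakpoint at `x` elevates all windows distal to
#' `x`, so raw step heights scale like `1 / (L - x)` for hot spots of
#' equal breakage intensity.
#'
#' With the default spline engine the smoothing bandwidth is structural:
#' the penalty is set so every chromosome's smooth carries
#' `df_base + df_per_mb * L/1e6` effective degrees of freedom — slightly
#' above the quadratic trend's three — independent of the data. A
#' data-driven choice (GCV or REML) was rejected because a strong hot
#' spot drags its own chromosome toward undersmoothing, inflating that
#' chromosome's gamma noise relative to the null and breaking the 3 s.d.
#' calibration. A second, sharp slope field (from the isotonic engine) is
#' carried along to localize peak apexes, since the penalized spline
#' smears step positions over its bandwidth.
#'
#' Slope estimates within `edge_windows` of a chromosome end are
#' one-sided and unstable (and maximally amplified by the `L - x` factor
#' at the centromeric end), so those windows are masked; in real data the
#' pericentromeric satellite is unmappable and carries no windows anyway.
#'
#' @param track normalized, depth-scaled `micseq_track`.
#' @param trend a fitted `micseq_trend`.
#' @param has_rho logical: either one value for all chromosomes, a named
#'   logical vector per chromosome, or `NULL` for automatic choice
#'   (enabled when the bootstrap 95% CI of rho excludes zero; falls back
#'   to `rho > 0` when no bootstrap has been run).
#' @param median_window see [monotone_smooth()].
#' @param engine smoothing engine, see [monotone_smooth()].
#' @param knot_spacing spline knot spacing in bp.
#' @param sp spline smoothing parameter override (`NULL` = structural
#'   target-df choice).
#' @param df_base,df_per_mb see [monotone_smooth()].
#' @param edge_windows number of windows masked at each chromosome end.
#' @return A data.frame of class `micseq_gamma` with columns `chrom`,
#'   `start`, `end`, `mid`, `smoothed`, `gamma_raw`, `gamma_det`,
#'   `gamma_norm`, `gamma_det_sharp`, `gamma_norm_sharp`, `mask`; layout and grid attributes
#'   are carried over, plus `sp` (smoothing parameter used).
#' @export
gamma_track <- function(track, trend, has_rho = NULL, median_window = 1000,
                        engine = c("spline", "pava"), knot_spacing = 2e6,
                        sp = NULL, df_base = 6, df_per_mb = 0.05,
                        edge_windows = 20) {
  engine <- match.arg(engine)
  layout <- track_layout(track)
  chroms <- names(layout)
  if (is.null(has_rho)) {
    has_rho_global <- if (!is.null(trend$bootstrap)) {
      trend$bootstrap$ci["rho", 1] > 0
    } else trend$rho > 0
    has_rho <- stats::setNames(rep(has_rho_global, length(chroms)), chroms)
  } else if (length(has_rho) == 1L && is.null(names(has_rho))) {
    has_rho <- stats::setNames(rep(has_rho, length(chroms)), chroms)
  }
  out <- lapply(chroms, function(ch) {
    sel <- track$chrom == ch
    mids <- track$mid[sel]
    rho_ch <- isTRUE(has_rho[[ch]])
    sm <- monotone_smooth(track$value[sel], mids, has_rho = rho_ch,
                          median_window = median_window, engine = engine,
                          sp = sp, knot_spacing = knot_spacing,
                          df_base = df_base, df_per_mb = df_per_mb)
    sharp <- monotone_smooth(track$value[sel], mids, has_rho = rho_ch,
                             median_window = median_window, engine = "pava")
    g_raw <- compute_gamma(sm$smoothed, mids, track$start[sel],
                           track$end[sel])
    g_sharp <- compute_gamma(sharp$smoothed, mids, track$start[sel],
                             track$end[sel])
    slope <- pmax(0, trend_slope(trend, ch, mids))
    L <- unname(layout[ch])
    n <- length(mids)
    mask <- track$mask[sel]
    if (edge_windows > 0 && n > 2 * edge_windows) {
      mask[c(seq_len(edge_windows), (n - edge_windows + 1L):n)] <- FALSE
    }
    data.frame(chrom = ch, start = track$start[sel], end = track$end[sel],
               mid = mids, smoothed = sm$smoothed, gamma_raw = g_raw,
               gamma_det = g_raw - slope,
               gamma_norm = (g_raw - slope) * (L - mids),
               gamma_det_sharp = g_sharp - slope,
               gamma_norm_sharp = (g_sharp - slope) * (L - mids),
               resid = track$value[sel] - trend$beta * mids^2 -
                 trend$rho * (L - mids)^2,
               mask = mask, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # per-chromosome smoothing bandwidth in windows: L / df over the step
  step <- attr(track, "step")
  bw <- vapply(chroms, function(ch) {
    L <- unname(layout[ch])
    (L / (df_base + df_per_mb * L / 1e6)) / step
  }, numeric(1))
  structure(res, layout = layout, window = attr(track, "window"),
            step = step, engine = engine,
            bandwidth_windows = bw,
            class = c("micseq_gamma", "data.frame"))
}

#' Empirical null for gamma and the positional significance cutoff
#'
#' The detrended gamma values on the designated null chromosomes (chr7
#' and chr11, assumed to carry no significant localized instability)
#' estimate the null spread. Extremely large values (greater than `trim`)
#' are removed before taking the standard deviation; the larger
#' per-chromosome sigma is kept as the conservative choice. The
#' significance cutoff at position `x` is then `k * sigma_null * (L - x)`
#' — linear in the distance to the distal telomere, mirroring the
#' distance normalization of gamma itself.
#'
#' @param gamma a `micseq_gamma` table.
#' @param null_chroms chromosomes defining the null (default chr7, chr11).
#' @param trim upper trim threshold on detrended gamma, in its own units
#'   (value per bp); default 1e-7, appropriate for per-bp tag densities.
#'   Use `Inf` to disable trimming.
#' @param k cutoff multiplier in standard deviations (default 3).
#' @return list of class `micseq_null` with `sigma_null`, per-chromosome
#'   `sigma`, `n_trimmed`, `trim`, `k`, `layout`.
#' @export
null_cutoff <- function(gamma, null_chroms = c("chr7", "chr11"),
                        trim = 1e-7, k = 3) {
  layout <- attr(gamma, "layout")
  miss <- setdiff(null_chroms, unique(gamma$chrom))
  if (length(miss)) stop("null chromosome(s) absent from gamma table: ",
                         paste(miss, collapse = ", "))
  sig <- vapply(null_chroms, function(ch) {
    v <- gamma$gamma_det[gamma$chrom == ch & gamma$mask]
    v <- v[!is.na(v)]
    kept <- v[v <= trim]
    if (length(kept) < 2L) stop("all gamma values trimmed on ", ch)
    stats::sd(kept)
  }, numeric(1))
  n_trim <- vapply(null_chroms, function(ch) {
    v <- gamma$gamma_det[gamma$chrom == ch & gamma$mask]
    sum(v > trim, na.rm = TRUE)
  }, numeric(1))
  structure(list(sigma_null = max(sig), sigma = sig, n_trimmed = n_trim,
                 trim = trim, k = k, layout = layout,
                 null_chroms = null_chroms),
            class = "micseq_null")
}

#' @export
print.micseq_null <- function(x, ...) {
  cat(sprintf("<micseq_null> sigma_null = %.4g (%s; trim > %g removed %s), cutoff = %g sd\n",
              x$sigma_null, paste(sprintf("%s: %.3g", names(x$sigma), x$sigma),
                                  collapse = ", "),
              x$trim, paste(x$n_trimmed, collapse = "/"), x$k))
  invisible(x)
}

#' Cutoff value at given positions
#'
#' @param null a `micseq_null`.
#' @param chrom chromosome name.
#' @param x positions in bp.
#' @return `k * sigma_null * (L - x)`.
#' @export
cutoff_at <- function(null, chrom, x) {
  L <- chrom_length(null$layout, chrom)
  null$k * null$sigma_null * (L - x)
}

#' Call significant gamma peaks
#'
#' Windows whose normalized gamma exceeds the positional cutoff are
#' merged into peaks; runs separated by at most `gap` sub-cutoff windows
#' are joined. The peak height (`gamma_norm`) and its cutoff are taken at
#' the window maximizing the smooth normalized gamma (leftmost on ties).
#' The apex position is refined on the sharp (isotonic) slope field
#' within the peak: the penalized spline locates significance but smears
#' step positions, while the isotonic fit jumps at the breakpoint itself.
#'
#' @param gamma a `micseq_gamma` table.
#' @param null a `micseq_null` from [null_cutoff()].
#' @param gap number of sub-cutoff windows tolerated inside a peak.
#'   Default (`NULL`): one smoothing bandwidth — where the declining
#'   signal of a hot spot crosses the cutoff, noise wiggles produce
#'   repeated crossings over a bandwidth-scale region that belongs to the
#'   same spot.
#' @param min_windows minimum number of supra-cutoff windows for a peak.
#'   Default (`NULL`): 1.2 smoothing bandwidths — a resolved hot spot
#'   elevates the slope over at least the smoother's bandwidth, while
#'   marginal null exceedances span less than one.
#' @return data.frame with columns `chrom`, `start`, `end`, `apex`,
#'   `gamma_norm`, `cutoff`, `n_windows`, `significant` (all `TRUE`: every
#'   reported peak exceeds its cutoff).
#' @export
call_peaks <- function(gamma, null, gap = NULL, min_windows = NULL) {
  has_resid <- "resid" %in% names(gamma)
  has_sharp <- "gamma_det_sharp" %in% names(gamma)
  bw <- attr(gamma, "bandwidth_windows")
  res <- list()
  for (ch in unique(gamma$chrom)) {
    bw_ch <- if (!is.null(bw) && ch %in% names(bw)) bw[[ch]] else 1
    gap_ch <- gap %||% ceiling(bw_ch)
    min_ch <- min_windows %||% ceiling(1.2 * bw_ch)
    sel <- which(gamma$chrom == ch)
    cut <- cutoff_at(null, ch, gamma$mid[sel])
    above <- !is.na(gamma$gamma_norm[sel]) & gamma$mask[sel] &
      gamma$gamma_norm[sel] > cut
    if (!any(above)) next
    idx <- which(above)
    brk <- c(TRUE, diff(idx) > gap_ch + 1L)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      ii <- idx[grp == g]
      if (length(ii) < min_ch) next
      vals <- gamma$gamma_norm[sel][ii]
      top_i <- ii[which.max(vals)]
      # localization: the breakpoint is the least-squares change point of
      # the detrended coverage inside the significant region (the smooth
      # field smears the step over its bandwidth; the step itself carries
      # the position information)
      span <- ii[1]:ii[length(ii)]
      apex_i <- if (has_resid) {
        t <- ls_changepoint(gamma$resid[sel][span])
        if (is.na(t)) top_i else span[t]
      } else if (has_sharp) {
        sharp <- gamma$gamma_det_sharp[sel][ii]
        if (all(is.na(sharp))) top_i else ii[which.max(sharp)]
      } else top_i
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch,
        start = gamma$start[sel][ii[1]],
        end = gamma$end[sel][ii[length(ii)]],
        apex = gamma$mid[sel][apex_i],
        gamma_norm = gamma$gamma_norm[sel][top_i],
        cutoff = cutoff_at(null, ch, gamma$mid[sel][top_i]),
        n_windows = length(ii),
        significant = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), apex = numeric(),
                      gamma_norm = numeric(), cutoff = numeric(),
                      n_windows = integer(), significant = logical()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), ]
}

# least-squares single change-point: index of the first element of the
# right segment minimizing total within-segment SSE; NAs tolerated
ls_changepoint <- function(r) {
  keep <- which(!is.na(r))
  v <- r[keep]
  n <- length(v)
  if (n < 5L) return(NA_integer_)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  tt <- 2:(n - 1L)
  nl <- tt - 1
  nr <- n - tt + 1
  sl <- cs[tt - 1L]
  sr <- cs[n] - sl
  sse <- (cs2[tt - 1L] - sl^2 / nl) + (cs2[n] - cs2[tt - 1L] - sr^2 / nr)
  keep[tt[which.min(sse)]]
}

#' Compare peak sets between two conditions
#'
#' Peaks are matched when their intervals overlap or their apexes lie
#' within `match_dist` bp. Matched pairs get a fold change
#' (`gamma_norm_A / gamma_norm_B`); unmatched peaks are reported as
#' condition-unique.
#'
#' @param peaks_a,peaks_b peak tables from [call_peaks()].
#' @param match_dist maximum apex distance for a match in bp (default one
#'   window, 20 kb).
#' @return list with `common` (paired table incl. `fold_change`),
#'   `unique_a`, `unique_b`, and `mean_fold` over common peaks.
#' @export
compare_peaks <- function(peaks_a, peaks_b, match_dist = 20000) {
  empty_common <- data.frame(chrom = character(), apex_a = numeric(),
                             apex_b = numeric(), gamma_norm_a = numeric(),
                             gamma_norm_b = numeric(),
                             fold_change = numeric())
  if (!nrow(peaks_a) || !nrow(peaks_b)) {
    return(list(common = empty_common, unique_a = peaks_a,
                unique_b = peaks_b, mean_fold = NA_real_))
  }
  used_b <- rep(FALSE, nrow(peaks_b))
  match_of <- rep(NA_integer_, nrow(peaks_a))
  for (i in seq_len(nrow(peaks_a))) {
    cand <- which(!used_b & peaks_b$chrom == peaks_a$chrom[i] &
                    (pmax(peaks_b$start, peaks_a$start[i]) <
                       pmin(peaks_b$end, peaks_a$end[i]) |
                       abs(peaks_b$apex - peaks_a$apex[i]) <= match_dist))
    if (length(cand)) {
      j <- cand[which.min(abs(peaks_b$apex[cand] - peaks_a$apex[i]))]
      match_of[i] <- j
      used_b[j] <- TRUE
    }
  }
  ok <- !is.na(match_of)
  common <- if (any(ok)) {
    data.frame(chrom = peaks_a$chrom[ok],
               apex_a = peaks_a$apex[ok],
               apex_b = peaks_b$apex[match_of[ok]],
               gamma_norm_a = peaks_a$gamma_norm[ok],
               gamma_norm_b = peaks_b$gamma_norm[match_of[ok]],
               fold_change = peaks_a$gamma_norm[ok] /
                 peaks_b$gamma_norm[match_of[ok]],
               stringsAsFactors = FALSE)
  } else empty_common
  list(common = common,
       unique_a = peaks_a[!ok, , drop = FALSE],
       unique_b = peaks_b[!used_b, , drop = FALSE],
       mean_fold = if (nrow(common)) mean(common$fold_change) else NA_real_)
}

#' Write peaks as BED6
#'
#' Score is the gamma/cutoff ratio scaled (capped at 1000).
#'
#' @param peaks peak table from [call_peaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (!nrow(peaks)) { writeLines(character(), path); return(invisible(path)) }
  score <- pmin(1000, round(100 * peaks$gamma_norm / peaks$cutoff))
  lines <- sprintf("%s\t%g\t%g\tpeak_%d\t%d\t.",
                   peaks$chrom, peaks$start, peaks$end,
                   seq_len(nrow(peaks)), score)
  writeLines(lines, path)
  invisible(path)
}
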