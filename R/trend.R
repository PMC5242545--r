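#' Fit the chromosome-wide representation trend
#'
#' Micronuclear coverage along a telocentric chromosome follows
#' `alpha_c + beta * x^2 + rho * (L - x)^2`, where `x` is the distance from
#' the centromere, `L` the chromosome length, `alpha_c` a per-chromosome
#' baseline, `beta` the quadratic gain toward the distal telomere
#' (acentromeric fragments from breaks near the distal end are
#' preferentially retained in micronuclei) and `rho` the converse,
#' centromere-proximal gain. `beta` and `rho` are shared across the fitted
#' chromosomes; `alpha` is per-chromosome. The fit is a weighted
#' least-squares with all coefficients constrained nonnegative, on
#' designated low-instability "null" chromosomes (chr7 and chr11 in mouse,
#' chosen because they show the smallest localized-gamma effects).
#'
#' The model is linear in its coefficients, so the constrained fit is
#' solved exactly by nonnegative least squares; positions are rescaled
#' internally (bp to 100 Mb units) for conditioning and coefficients are
#' converted back, making the fit invariant to the unit of `x`.
#'
#' @param track normalized, depth-scaled `micseq_track`.
#' @param null_chroms chromosomes used for fitting (default chr7, chr11).
#' @param weights `NULL` for uniform weights, or a numeric vector with one
#'   weight per window of `track` (e.g. inverse GRN counts).
#' @return An object of class `micseq_trend`: list with per-chromosome
#'   `alpha`, shared `beta` and `rho` (units: value per bp^2), `layout`,
#'   `null_chroms`, residual norm, and (after [bootstrap_trend()]) a
#'   `bootstrap` element.
#' @export
fit_trend <- function(track, null_chroms = c("chr7", "chr11"), weights = NULL) {
  layout <- track_layout(track)
  miss <- setdiff(null_chroms, names(layout))
  if (length(miss)) stop("null chromosome(s) not in layout: ",
                         paste(miss, collapse = ", "))
  sel <- which(track$chrom %in% null_chroms & track$mask)
  if (length(sel) < length(null_chroms) + 3L) {
    stop("too few unmasked windows on the null chromosomes")
  }
  w <- if (is.null(weights)) NULL else {
    stopifnot(length(weights) == nrow(track))
    weights[sel]
  }
  fit <- trend_nnls(track$chrom[sel], track$mid[sel], track$value[sel],
                    layout, null_chroms, w)
  structure(c(fit, list(layout = layout, null_chroms = null_chroms,
                        bootstrap = NULL)),
            class = "micseq_trend")
}

# position scale used internally for conditioning (100 Mb)
.XSCALE <- 1e8

trend_nnls <- function(chrom, x, y, layout, null_chroms, weights = NULL) {
  L <- unname(layout[chrom])
  xs <- x / .XSCALE
  Ls <- L / .XSCALE
  ind <- outer(chrom, null_chroms, `==`) * 1
  A <- cbind(ind, xs^2, (Ls - xs)^2)
  colnames(A) <- c(null_chroms, "beta", "rho")
  if (!is.null(weights)) {
    sw <- sqrt(weights)
    Aw <- A * sw
    yw <- y * sw
  } else {
    Aw <- A
    yw <- y
  }
  # the model is linear: try the unconstrained solution first and fall
  # back to NNLS only when a coefficient goes negative
  co <- tryCatch(stats::.lm.fit(Aw, yw)$coefficients,
                 error = function(e) rep(-1, ncol(Aw)))
  if (any(co < 0)) {
    sol <- tryCatch(pracma::lsqnonneg(Aw, yw),
                    error = function(e) {
                      stop("trend fit failed to converge: ",
                           conditionMessage(e))
                    })
    co <- sol$x
  }
  names(co) <- colnames(A)
  resid <- yw - drop(Aw %*% co)
  list(alpha = co[null_chroms],
       beta = unname(co["beta"]) / .XSCALE^2,
       rho = unname(co["rho"]) / .XSCALE^2,
       residual_norm = sqrt(sum(resid^2)),
       n = length(y))
}

#' @export
print.micseq_trend <- function(x, ...) {
  cat(sprintf("<micseq_trend> beta = %.4g /bp^2, rho = %.4g /bp^2 (fit on %s, n = %d)\n",
              x$beta, x$rho, paste(x$null_chroms, collapse = ", "), x$n))
  for (ch in names(x$alpha)) cat(sprintf("  alpha[%s] = %.4g\n", ch, x$alpha[ch]))
  if (!is.null(x$bootstrap)) {
    b <- x$bootstrap
    cat(sprintf("  bootstrap (%d reps, frac %.2f): beta sd %.3g CI [%.3g, %.3g]; rho sd %.3g CI [%.3g, %.3g]\n",
                b$reps_used, b$frac, b$sd["beta"], b$ci["beta", 1],
                b$ci["beta", 2], b$sd["rho"], b$ci["rho", 1], b$ci["rho", 2]))
  }
  invisible(x)
}

#' Subsample bootstrap for the trend fit
#'
#' Each replicate refits the trend on a uniform random subsample of
#' `floor(frac * n)` windows drawn without replacement; the standard
#' deviation over replicates and the empirical 2.5/97.5 percentiles give
#' the uncertainty of `beta` and `rho`. Fully reproducible given `seed`.
#'
#' @param track,null_chroms,weights as in [fit_trend()].
#' @param frac subsample fraction (default 0.5).
#' @param reps number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return The `micseq_trend` fit with a `bootstrap` element: `sd`, `ci`
#'   (2.5/97.5 percentiles), `draws` matrix, replicate counts and settings.
#' @export
bootstrap_trend <- function(track, null_chroms = c("chr7", "chr11"),
                            weights = NULL, frac = 0.5, reps = 1000,
                            seed = 1) {
  stopifnot(reps >= 2, frac > 0, frac < 1)
  fit <- fit_trend(track, null_chroms, weights)
  layout <- track_layout(track)
  sel <- which(track$chrom %in% null_chroms & track$mask)
  chrom <- track$chrom[sel]
  x <- track$mid[sel]
  y <- track$value[sel]
  w <- if (is.null(weights)) NULL else weights[sel]
  n <- length(sel)
  k <- floor(frac * n)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = reps, ncol = 2,
                  dimnames = list(NULL, c("beta", "rho")))
  dropped <- 0L
  for (r in seq_len(reps)) {
    idx <- sample.int(n, k, replace = FALSE)
    rep_fit <- tryCatch(
      trend_nnls(chrom[idx], x[idx], y[idx], layout, null_chroms,
                 if (is.null(w)) NULL else w[idx]),
      error = function(e) NULL)
    if (is.null(rep_fit)) dropped <- dropped + 1L
    else draws[r, ] <- c(rep_fit$beta, rep_fit$rho)
  }
  if (dropped > 0.1 * reps) {
    warning(sprintf("bootstrap_trend: %d/%d replicates dropped", dropped, reps))
  }
  ok <- stats::complete.cases(draws)
  fit$bootstrap <- list(
    sd = apply(draws[ok, , drop = FALSE], 2, stats::sd),
    ci = t(apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                 probs = c(0.025, 0.975))),
    draws = draws[ok, , drop = FALSE],
    reps = reps, reps_used = sum(ok), frac = frac, seed = seed)
  fit
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Evaluate the fitted trend and its slope
#'
#' `trend_value` returns `alpha_c + beta x^2 + rho (L - x)^2`;
#' `trend_slope` its derivative `2 beta x - 2 rho (L - x)`. The slope does
#' not involve `alpha`, so it is defined for any chromosome in the layout;
#' the value requires a chromosome with a fitted (or supplied) alpha.
#'
#' @param fit a `micseq_trend`.
#' @param chrom chromosome name.
#' @param x position(s) in bp, `0 <= x <= L`.
#' @param alpha optional baseline overriding the fitted per-chromosome
#'   value (needed for chromosomes outside the fitting set).
#' @return numeric vector.
#' @export
trend_value <- function(fit, chrom, x, alpha = NULL) {
  L <- chrom_length(fit$layout, chrom)
  if (any(x < 0 | x > L)) stop("position outside [0, L] on ", chrom)
  a <- alpha %||% unname(fit$alpha[chrom])
  if (is.na(a)) stop("no alpha available for ", chrom,
                     "; supply one via the 'alpha' argument")
  a + fit$beta * x^2 + fit$rho * (L - x)^2
}

#' @rdname trend_value
#' @export
trend_slope <- function(fit, chrom, x) {
  L <- chrom_length(fit$layout, chrom)
  if (any(x < 0 | x > L)) stop("position outside [0, L] on ", chrom)
  2 * fit$beta * x - 2 * fit$rho * (L - x)
}
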