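#' Normalize MN window counts against the GRN bias control
#'
#' The granulocyte (GRN) fraction carries the same GC, library and
#' strain-mapping biases as the micronuclear (MN) fraction but none of the
#' micronucleation biology, so the window-wise MN/GRN ratio cancels shared
#' multiplicative bias. Windows whose GRN count lies outside
#' `mean +/- sd_k` standard deviations of the genome-wide GRN counts, or
#' equals zero, are masked. Ratios are rescaled by the genome-wide mean GRN
#' count so normalized values stay on the MN count scale.
#'
#' @param mn,grn raw-count `micseq_track`s on identical grids; `grn` should
#'   come from the designated reference GRN sample.
#' @param sd_k outlier cutoff in standard deviations (default 3).
#' @return A normalized `micseq_track` (fraction label preserved from
#'   `mn`), masked at GRN outlier windows.
#' @export
grn_normalize <- function(mn, grn, sd_k = 3) {
  if (!same_grid(track_grid(mn), track_grid(grn))) {
    stop("MN and GRN tracks are on different grids")
  }
  g <- grn$value
  mu <- mean(g, na.rm = TRUE)
  sdv <- stats::sd(g, na.rm = TRUE)
  mask <- !is.na(g) & !is.na(mn$value) &
    g > 0 & abs(g - mu) <= sd_k * sdv
  if (mean(!mask) > 0.5) {
    warning(sprintf("grn_normalize: %.0f%% of windows masked", 100 * mean(!mask)))
  }
  value <- ifelse(mask, mn$value / g * mu, NA_real_)
  out <- new_track(track_grid(mn), value, fraction = attr(mn, "fraction"),
                   mask = mask,
                   total_fragments = attr(mn, "total_fragments"))
  attr(out, "grn_mean") <- mu
  out
}

#' Estimate the per-chromosome baseline alpha
#'
#' `alpha` is the baseline representation of a whole chromosome in the MN
#' fraction: whole-chromosome loss plus genomic contamination. It is
#' estimated as the minimum, over all runs of `m` consecutive unmasked
#' windows, of the run median. Because the quadratic beta/rho trends raise
#' coverage away from the minimum-coverage point, this estimate ignores
#' them and is a slight over-estimate of the true baseline.
#'
#' @param track a normalized `micseq_track` (a raw track works too).
#' @param m run length in windows (default 1000, matched to 40 kb / 20 kb
#'   grids on full-size chromosomes). Shrunk with a warning on chromosomes
#'   with fewer unmasked windows.
#' @param chroms chromosomes to estimate; default all in the layout.
#' @return A data.frame with columns `chrom`, `alpha`, `m` (run length
#'   actually used) and `argmin` (bp midpoint of the minimizing run).
#' @export
estimate_alpha <- function(track, m = 1000, chroms = NULL) {
  layout <- track_layout(track)
  chroms <- chroms %||% names(layout)
  res <- lapply(chroms, function(ch) {
    v <- track$value[track$chrom == ch & track$mask]
    x <- track$mid[track$chrom == ch & track$mask]
    if (!length(v)) stop("no unmasked windows on ", ch)
    m_use <- m
    if (m_use > length(v)) {
      warning(sprintf("estimate_alpha: %s has %d unmasked windows < m = %d; shrinking run",
                      ch, length(v), m))
      m_use <- length(v)
    }
    med <- running_median(v, m_use)
    i <- which.min(med)
    data.frame(chrom = ch, alpha = med[i], m = m_use,
               argmin = mean(x[i:(i + m_use - 1L)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Depth-scale a set of normalized tracks using alpha ratios
#'
#' Sequencing-depth differences between samples are removed by a
#' median-ratio factor computed from per-chromosome alpha estimates:
#' for each sample the factor is the median, over chromosomes not excluded
#' for strong alpha changes, of (reference alpha / sample alpha). The
#' reference sample keeps factor 1.
#'
#' @param tracks named list of normalized `micseq_track`s.
#' @param reference name (or index) of the reference sample.
#' @param exclude_chroms chromosomes with strong condition-specific alpha
#'   changes, excluded from the median ratio. The default matches the set
#'   used for mouse Mic-Seq: chr6, 12, 15, 16, 18, 19 and X.
#' @param m run length passed to [estimate_alpha()].
#' @return A list with `tracks` (scaled, with `scale_factor` attribute
#'   set) and `factors` (named numeric vector).
#' @export
depth_scale <- function(tracks, reference = 1,
                        exclude_chroms = c("chr6", "chr12", "chr15", "chr16",
                                           "chr18", "chr19", "chrX"),
                        m = 1000) {
  stopifnot(length(tracks) >= 2)
  if (is.null(names(tracks))) names(tracks) <- paste0("sample", seq_along(tracks))
  ref_name <- if (is.numeric(reference)) names(tracks)[reference] else reference
  stopifnot(ref_name %in% names(tracks))
  layout <- track_layout(tracks[[1]])
  use_chroms <- setdiff(names(layout), exclude_chroms)
  if (!length(use_chroms)) stop("all chromosomes excluded from depth scaling")
  alphas <- lapply(tracks, estimate_alpha, m = m, chroms = use_chroms)
  ref_alpha <- alphas[[ref_name]]$alpha
  factors <- vapply(names(tracks), function(nm) {
    stats::median(ref_alpha / alphas[[nm]]$alpha)
  }, numeric(1))
  factors[ref_name] <- 1
  scaled <- lapply(names(tracks), function(nm) {
    t <- tracks[[nm]]
    t$value <- t$value * factors[[nm]]
    attr(t, "scale_factor") <- attr(t, "scale_factor") * factors[[nm]]
    t
  })
  names(scaled) <- names(tracks)
  list(tracks = scaled, factors = factors)
}
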