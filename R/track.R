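#' Coverage track container
#'
#' A `micseq_track` is a window grid plus one value per window. Raw tracks
#' produced by [count_windows()] carry integer counts and an all-`TRUE`
#' mask; normalized tracks ([grn_normalize()]) carry real values and mask
#' out windows excluded by the GRN outlier filter. Masked windows hold
#' `NA`.
#'
#' @param grid a [window_grid()].
#' @param value numeric vector, one per window.
#' @param fraction blood-fraction label (`"MN"`, `"GRN"`, `"WBC"`, ...).
#' @param mask logical vector, `TRUE` where the window is valid.
#' @param total_fragments number of fragments assigned (raw tracks).
#' @param scale_factor depth-scaling factor applied to the values.
#' @return A data.frame of class `micseq_track` with the grid columns and
#'   `value`, `mask`.
#' @export
new_track <- function(grid, value, fraction = "MN", mask = NULL,
                      total_fragments = NA_real_, scale_factor = 1) {
  stopifnot(inherits(grid, "micseq_grid"), length(value) == nrow(grid))
  if (is.null(mask)) mask <- !is.na(value)
  stopifnot(length(mask) == nrow(grid))
  value[!mask] <- NA_real_
  tr <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                   mid = grid$mid, value = as.numeric(value), mask = mask,
                   stringsAsFactors = FALSE)
  structure(tr,
            window = grid_window(grid), step = grid_step(grid),
            layout = grid_layout(grid), fraction = fraction,
            total_fragments = total_fragments, scale_factor = scale_factor,
            class = c("micseq_track", "data.frame"))
}

#' @export
print.micseq_track <- function(x, ...) {
  cat(sprintf("<micseq_track> %s: %d windows (w = %g, s = %g), %d masked\n",
              attr(x, "fraction"), nrow(x), attr(x, "window"),
              attr(x, "step"), sum(!x$mask)))
  invisible(x)
}

track_grid <- function(track) {
  g <- data.frame(chrom = track$chrom, start = track$start, end = track$end,
                  mid = track$mid, stringsAsFactors = FALSE)
  structure(g, window = attr(track, "window"), step = attr(track, "step"),
            layout = attr(track, "layout"),
            class = c("micseq_grid", "data.frame"))
}

track_layout <- function(track) attr(track, "layout")

with_values <- function(track, value, mask = track$mask) {
  value[!mask] <- NA_real_
  track$value <- value
  track$mask <- mask
  track
}

#' Count fragment midpoints in overlapping windows
#'
#' Each fragment is assigned to every window whose half-open interval
#' contains the midpoint of its left-end read; with 50% overlap an
#' interior midpoint therefore increments exactly two windows. Counting is
#' deterministic and independent of input order. Midpoints outside the
#' chromosome are rejected and counted.
#'
#' @param frags filtered fragment data.frame (see [read_fragments()]).
#' @param grid a [window_grid()].
#' @param fraction blood-fraction label carried on the track.
#' @return A `micseq_track` of raw counts; attribute `n_rejected_mid`
#'   counts fragments whose midpoint fell outside the chromosome.
#' @examples
#' lay <- genome_layout("chr1", 1e5)
#' g <- window_grid(lay, 4e4, 2e4)
#' fr <- data.frame(chrom = "chr1", start = 24000, end = 26000,
#'                  left_read_mid = 25000, mapq = 60,
#'                  proper_pair = TRUE, duplicate = FALSE)
#' count_windows(fr, g)$value
#' @export
count_windows <- function(frags, grid, fraction = "MN") {
  stopifnot(inherits(grid, "micseq_grid"))
  w <- grid_window(grid)
  s <- grid_step(grid)
  layout <- grid_layout(grid)
  counts <- numeric(nrow(grid))
  # row offset of each chromosome's first window in the grid
  chroms <- names(layout)
  n_win <- vapply(chroms, function(ch) sum(grid$chrom == ch), 0)
  offset <- stats::setNames(cumsum(c(0, n_win[-length(n_win)])), chroms)

  n_rej <- 0L
  n_assigned <- 0L
  max_j <- ceiling(w / s) - 1L
  for (ch in unique(frags$chrom)) {
    if (!ch %in% chroms) { n_rej <- n_rej + sum(frags$chrom == ch); next }
    L <- unname(layout[ch])
    mid <- frags$left_read_mid[frags$chrom == ch]
    ok <- mid >= 0 & mid < L
    n_rej <- n_rej + sum(!ok)
    mid <- mid[ok]
    n_assigned <- n_assigned + length(mid)
    if (!length(mid)) next
    k0 <- floor(mid / s)
    nw <- n_win[[ch]]
    for (j in 0:max_j) {
      k <- k0 - j
      valid <- k >= 0 & mid < k * s + w & k < nw
      if (any(valid)) {
        tab <- tabulate(k[valid] + 1L, nbins = nw)
        idx <- offset[[ch]] + seq_len(nw)
        counts[idx] <- counts[idx] + tab
      }
    }
  }
  if (n_rej > 0) {
    message(sprintf("count_windows: rejected %d fragment(s) with midpoint outside chromosome",
                    n_rej))
  }
  tr <- new_track(grid, counts, fraction = fraction,
                  total_fragments = n_assigned)
  attr(tr, "n_rejected_mid") <- n_rej
  tr
}

#' Pool replicate tracks by summing window counts
#'
#' @param tracks list of raw-count `micseq_track`s on the same grid.
#' @return a pooled `micseq_track`.
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  g0 <- track_grid(tracks[[1]])
  for (t in tracks[-1]) {
    if (!same_grid(track_grid(t), g0)) stop("tracks are on different grids")
  }
  vals <- Reduce(`+`, lapply(tracks, function(t) t$value))
  new_track(g0, vals, fraction = attr(tracks[[1]], "fraction"),
            total_fragments = sum(vapply(tracks, attr, 0,
                                         which = "total_fragments")))
}

#' Inter-replicate Pearson correlation (QC before pooling)
#'
#' Computed on window counts, excluding the sex chromosomes since
#' replicate animals may differ in gender.
#'
#' @param a,b raw-count `micseq_track`s on the same grid.
#' @param exclude_chroms chromosomes dropped from the computation.
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(a, b, exclude_chroms = c("chrX", "chrY")) {
  if (!same_grid(track_grid(a), track_grid(b))) stop("tracks on different grids")
  keep <- !(a$chrom %in% exclude_chroms) & a$mask & b$mask
  stats::cor(a$value[keep], b$value[keep], method = "pearson")
}
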