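#' Overlapping window grid
#'
#' Builds the tiling of each chromosome into half-open windows
#' `[k*step, k*step + window)` clipped at the chromosome length. With the
#' default 40 kb windows and 20 kb step, adjacent windows overlap by 20 kb;
#' pooled data conventionally uses 20 kb windows with a 10 kb step.
#'
#' @param layout a [genome_layout()].
#' @param window window size `w` in bp.
#' @param step step `s` in bp; must satisfy `0 < s <= w`. The overlap
#'   between adjacent windows is `w - s`.
#'
#' @return A data.frame of class `micseq_grid` with columns `chrom`,
#'   `start`, `end`, `mid` (window midpoint in bp, the position `x` used by
#'   the trend model) and attributes `window`, `step`, `layout`.
#' @examples
#' g <- window_grid(genome_layout("chr1", 1e5), window = 4e4, step = 2e4)
#' head(g)
#' @export
window_grid <- function(layout, window = 40000, step = 20000) {
  stopifnot(inherits(layout, "micseq_layout"))
  if (!(step > 0 && step <= window)) stop("require 0 < step <= window")
  pieces <- lapply(names(layout), function(ch) {
    L <- unname(layout[ch])
    starts <- seq(0, L - 1, by = step)
    ends <- pmin(starts + window, L)
    data.frame(chrom = ch, start = starts, end = ends,
               mid = (starts + ends) / 2, stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  structure(grid, window = window, step = step, layout = layout,
            class = c("micseq_grid", "data.frame"))
}

grid_window <- function(grid) attr(grid, "window")
grid_step <- function(grid) attr(grid, "step")
grid_layout <- function(grid) attr(grid, "layout")

#' @export
print.micseq_grid <- function(x, ...) {
  cat(sprintf("<micseq_grid> %d windows (w = %g bp, s = %g bp, %d chromosomes)\n",
              nrow(x), grid_window(x), grid_step(x), length(grid_layout(x))))
  invisible(x)
}

same_grid <- function(a, b) {
  nrow(a) == nrow(b) &&
    identical(grid_window(a), grid_window(b)) &&
    identical(grid_step(a), grid_step(b)) &&
    identical(a$chrom, b$chrom) && identical(a$start, b$start)
}
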