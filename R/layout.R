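#' Telocentric genome layout
#'
#' A `micseq_layout` holds the chromosome coordinate system used throughout
#' the package. Mouse chromosomes are telocentric, so coordinate 0 is taken
#' to be the centromeric end of every chromosome and coordinate `L`
#' (the chromosome length) the distal telomere. A position `x` is therefore
#' literally the distance from the centromere, and `L - x` the distance to
#' the distal telomere.
#'
#' @param chroms character vector of unique chromosome names.
#' @param lengths integer-ish vector of chromosome lengths in bp, same
#'   length as `chroms`; all strictly positive.
#'
#' @return An object of class `micseq_layout`: a named numeric vector of
#'   lengths with the chromosome order preserved.
#' @examples
#' layout <- genome_layout(c("chr1", "chr2"), c(50e6, 30e6))
#' chrom_length(layout, "chr2")
#' @export
genome_layout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) == 0L) stop("layout must contain at least one chromosome")
  if (length(chroms) != length(lengths)) {
    stop("'chroms' and 'lengths' must have the same length")
  }
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("all chromosome lengths must be finite and > 0")
  }
  structure(stats::setNames(lengths, chroms), class = "micseq_layout")
}

#' @export
print.micseq_layout <- function(x, ...) {
  cat(sprintf("<micseq_layout> %d chromosomes, %.1f Mb total\n",
              length(x), sum(x) / 1e6))
  invisible(x)
}

#' Chromosome length lookup
#'
#' @param layout a [genome_layout()].
#' @param chrom chromosome name(s).
#' @return numeric length(s) in bp.
#' @export
chrom_length <- function(layout, chrom) {
  stopifnot(inherits(layout, "micseq_layout"))
  miss <- setdiff(unique(chrom), names(layout))
  if (length(miss)) stop("unknown chromosome(s): ", paste(miss, collapse = ", "))
  unname(layout[chrom])
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab- or space-separated columns: chromosome name and length in bp.
#' Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("no records in chrom.sizes file: ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed chrom.sizes line %d in %s", bad[1], path))
  }
  chroms <- vapply(parts, `[[`, "", 1L)
  lens <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(lens)) {
    stop(sprintf("non-numeric length on line %d of %s", which(is.na(lens))[1], path))
  }
  genome_layout(chroms, lens)
}

#' Write a chrom.sizes file
#'
#' @param layout a [genome_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "micseq_layout"))
  writeLines(sprintf("%s\t%d", names(layout), as.integer(round(unname(layout)))),
             path)
  invisible(path)
}
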