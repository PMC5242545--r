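#' Read paired-end fragments and apply representation filters
#'
#' Fragments are the genomic spans bridged by a read pair. Records are kept
#' only if the pair is proper, the mapping quality is strictly greater than
#' `min_mapq` (default 20), the record is not flagged as a PCR duplicate,
#' and the span is at most `max_insert`. Fragments on chromosomes absent
#' from `layout`, or with coordinates outside the chromosome, are rejected
#' at the record level and counted (see the `rejected` attribute).
#'
#' Two sources are supported:
#' \describe{
#'   \item{fragment table}{a tab-delimited file (or in-memory data.frame)
#'     with columns `chrom`, `start`, `end`, `left_read_mid`, `mapq`,
#'     `proper_pair`, `duplicate`. Coordinates are 0-based half-open.
#'     This alignment-free mode is what the simulator emits.}
#'   \item{BAM}{a coordinate-sorted paired-end BAM file (requires the
#'     Rsamtools package). The fragment span is reconstructed from the
#'     leftmost mate and the template length; duplicate marking is taken
#'     from the input flags, never recomputed.}
#' }
#'
#' @param source path to a fragment TSV or BAM file, or a data.frame in
#'   fragment-table layout.
#' @param layout a [genome_layout()] used to validate coordinates.
#' @param max_insert maximum fragment span in bp (see
#'   [insert_size_histogram()] for how it is chosen from data).
#' @param min_mapq mapping-quality floor; the filter is strictly greater
#'   than this value.
#'
#' @return A data.frame of retained fragments with columns `chrom`,
#'   `start`, `end`, `left_read_mid`, `mapq`, and attribute `rejected`, a
#'   named integer vector of rejection counts by reason.
#' @export
read_fragments <- function(source, layout, max_insert = Inf, min_mapq = 20) {
  stopifnot(inherits(layout, "micseq_layout"))
  if (is.data.frame(source)) {
    frags <- source
  } else if (grepl("\\.bam$", source, ignore.case = TRUE)) {
    frags <- read_fragments_bam(source)
  } else {
    frags <- utils::read.table(source, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  }
  filter_fragments(frags, layout, max_insert = max_insert, min_mapq = min_mapq)
}

required_fragment_cols <- c("chrom", "start", "end", "left_read_mid",
                            "mapq", "proper_pair", "duplicate")

filter_fragments <- function(frags, layout, max_insert = Inf, min_mapq = 20) {
  miss <- setdiff(required_fragment_cols, names(frags))
  if (length(miss)) {
    stop("fragment table missing column(s): ", paste(miss, collapse = ", "))
  }
  frags$chrom <- as.character(frags$chrom)
  frags$proper_pair <- as.logical(frags$proper_pair)
  frags$duplicate <- as.logical(frags$duplicate)

  known <- frags$chrom %in% names(layout)
  n_unknown <- sum(!known)
  f <- frags[known, , drop = FALSE]
  L <- unname(layout[f$chrom])
  in_bounds <- f$start >= 0 & f$end <= L & f$start < f$end &
    f$left_read_mid >= f$start & f$left_read_mid < f$end
  n_bounds <- sum(!in_bounds)
  f <- f[in_bounds, , drop = FALSE]

  keep_pp <- f$proper_pair
  keep_dup <- !f$duplicate
  keep_mq <- f$mapq > min_mapq
  keep_ins <- (f$end - f$start) <= max_insert
  keep <- keep_pp & keep_dup & keep_mq & keep_ins
  rejected <- c(
    unknown_chrom = n_unknown,
    out_of_bounds = n_bounds,
    not_proper    = sum(!keep_pp),
    duplicate     = sum(keep_pp & !keep_dup),
    low_mapq      = sum(keep_pp & keep_dup & !keep_mq),
    over_insert   = sum(keep_pp & keep_dup & keep_mq & !keep_ins)
  )
  if (n_unknown > 0) {
    message(sprintf("read_fragments: rejected %d fragment(s) on unknown chromosomes",
                    n_unknown))
  }
  out <- f[keep, c("chrom", "start", "end", "left_read_mid", "mapq",
                   "proper_pair", "duplicate"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

read_fragments_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading BAM requires the Rsamtools package; ",
         "use the fragment-table mode otherwise")
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1]]
  so <- sub(".*SO:", "", grep("^SO:|SO:", unlist(hdr$text["@HD"]), value = TRUE))
  if (length(so) && !any(so == "coordinate")) {
    stop("BAM file is not coordinate-sorted (SO:", so[1], "): ", path)
  }
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("rname", "pos", "qwidth", "mapq", "isize", "flag"))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  # keep the leftmost mate of each pair: template length positive
  left <- !is.na(rec$isize) & rec$isize > 0 & !is.na(rec$pos)
  pos0 <- rec$pos[left] - 1L                      # to 0-based
  qw <- rec$qwidth[left]
  fl <- rec$flag[left]
  data.frame(
    chrom = as.character(rec$rname[left]),
    start = pos0,
    end = pos0 + rec$isize[left],
    left_read_mid = floor((pos0 + (pos0 + qw)) / 2),
    mapq = rec$mapq[left],
    proper_pair = bitwAnd(fl, 2L) > 0L,
    duplicate = bitwAnd(fl, 1024L) > 0L,
    stringsAsFactors = FALSE
  )
}

#' Write a fragment table
#'
#' @param frags fragment data.frame (see [read_fragments()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  utils::write.table(frags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Insert-size histogram and maximum-insert choice
#'
#' Builds the integer-binned histogram of fragment spans (`end - start`)
#' and selects the maximum insert size as the smallest span covering a
#' given quantile of fragments (type-1 empirical quantile). The resulting
#' `max_insert` is the cutoff applied when regenerating coverage.
#'
#' @param frags fragment data.frame with `start` and `end` columns.
#' @param quantile fraction of fragments the chosen insert must cover
#'   (default 0.999; 1.0 gives the maximum observed span).
#'
#' @return A list with `histogram` (a named integer table of spans),
#'   `max_insert` (numeric) and `quantile`.
#' @export
insert_size_histogram <- function(frags, quantile = 0.999) {
  if (!nrow(frags)) stop("no fragments supplied")
  stopifnot(quantile > 0, quantile <= 1)
  len <- frags$end - frags$start
  list(histogram = table(len),
       max_insert = unname(stats::quantile(len, quantile, type = 1)),
       quantile = quantile)
}
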