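#' Count fragments in repeat compartments and compute enrichment ratios
#'
#' Tallies fragments whose target contig is one of the appended repeat
#' compartments (45S rDNA, major satellite MaSat, minor satellite MiSat)
#' versus the standard chromosomes, and computes the standard ratios:
#' rDNA/MaSat, MaSat/MiSat and rDNA/total. Reads inside concatenated
#' repeat arrays are typically multi-mapping (MAPQ 0), so compartments
#' use no MAPQ filter by default while genomic fragments keep the usual
#' strictly-greater-than-20 filter; proper-pair and duplicate filters
#' apply to both.
#'
#' @param frags fragment data.frame (fragment-table layout); `chrom` is
#'   the target contig name.
#' @param layout a [genome_layout()] listing the standard chromosomes.
#' @param compartments compartment contig names
#'   (default `rDNA45S`, `MaSat`, `MiSat`).
#' @param mapq_gt_genome MAPQ filter for genomic fragments (strictly
#'   greater; default 20).
#' @param mapq_gt_compartment MAPQ filter for compartment fragments
#'   (default -1, i.e. no filter).
#' @param sample sample label carried into the output.
#' @param fraction blood-fraction label.
#' @return data.frame of class `micseq_repeats` with one row per
#'   compartment plus `genome` and `total`, and attribute `ratios`
#'   (named: `rDNA_MaSat`, `MaSat_MiSat`, `rDNA_total`; `NA` where the
#'   denominator is zero).
#' @export
count_repeats <- function(frags, layout,
                          compartments = c("rDNA45S", "MaSat", "MiSat"),
                          mapq_gt_genome = 20, mapq_gt_compartment = -1,
                          sample = "sample", fraction = "MN") {
  if (!any(frags$chrom %in% compartments)) {
    stop("no fragments on compartment contigs (",
         paste(compartments, collapse = ", "),
         "); fragments must be aligned to the repeat-augmented reference")
  }
  base_keep <- as.logical(frags$proper_pair) & !as.logical(frags$duplicate)
  is_comp <- frags$chrom %in% compartments
  is_gen <- frags$chrom %in% names(layout)
  keep <- base_keep &
    ((is_comp & frags$mapq > mapq_gt_compartment) |
       (is_gen & frags$mapq > mapq_gt_genome))
  f <- frags[keep, , drop = FALSE]
  counts <- c(vapply(compartments, function(cp) sum(f$chrom == cp), 0),
              genome = sum(f$chrom %in% names(layout)))
  total <- sum(counts)
  ratios <- c(
    rDNA_MaSat = if (counts[["MaSat"]] > 0)
      counts[["rDNA45S"]] / counts[["MaSat"]] else NA_real_,
    MaSat_MiSat = if (counts[["MiSat"]] > 0)
      counts[["MaSat"]] / counts[["MiSat"]] else NA_real_,
    rDNA_total = if (total > 0)
      counts[["rDNA45S"]] / total else NA_real_)
  out <- data.frame(sample = sample, fraction = fraction,
                    compartment = c(names(counts), "total"),
                    count = c(unname(counts), total),
                    stringsAsFactors = FALSE)
  structure(out, ratios = ratios, class = c("micseq_repeats", "data.frame"))
}

#' Regression-based flagging of repeat enrichment across samples
#'
#' Samples sharing normal repeat representation fall on a line when rDNA
#' tag counts are plotted against MaSat tag counts; samples with rDNA
#' over-representation (e.g. a 2-3 fold excess in MN of replication-
#' licensing deficient animals) fall above the 95% band. The line is
#' least squares through the included samples; the band is the pointwise
#' 95% prediction band, and any sample outside it is flagged as enriched.
#'
#' @param points data.frame with columns `sample`, `masat`, `rdna`.
#' @param exclude sample names excluded from the fit (they are still
#'   assessed against the band).
#' @param level band coverage level (default 0.95).
#' @return list with `fit` (the `lm`), `table` (input plus `fitted`,
#'   `lower`, `upper`, `included`, `flagged`), and `n_included`.
#' @export
ratio_regression <- function(points, exclude = character(), level = 0.95) {
  stopifnot(all(c("sample", "masat", "rdna") %in% names(points)))
  inc <- !(points$sample %in% exclude)
  if (sum(inc) < 3) stop("need at least 3 included points")
  if (stats::var(points$masat[inc]) == 0) {
    stop("degenerate regression: no variance in MaSat counts")
  }
  fit <- stats::lm(rdna ~ masat, data = points[inc, , drop = FALSE])
  pred <- suppressWarnings(
    stats::predict(fit, newdata = points, interval = "prediction",
                   level = level))
  tab <- points
  tab$fitted <- pred[, "fit"]
  tab$lower <- pred[, "lwr"]
  tab$upper <- pred[, "upr"]
  tab$included <- inc
  tab$flagged <- points$rdna > tab$upper | points$rdna < tab$lower
  tab$flagged[is.na(tab$flagged)] <- FALSE
  list(fit = fit, table = tab, n_included = sum(inc))
}
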