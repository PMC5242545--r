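#' Assemble a run configuration
#'
#' @param samples data.frame with columns `sample`, `fraction`
#'   (`MN`/`GRN`/`WBC`), `condition`, `path` (fragment table or BAM).
#' @param layout a [genome_layout()] or path to a chrom.sizes file.
#' @param window,step analysis window grid in bp.
#' @param reference_grn sample name of the designated GRN bias control
#'   (default: the first GRN sample).
#' @param reference_condition condition whose depth factor is fixed at 1
#'   (default: condition of the reference GRN).
#' @param null_chroms low-instability chromosomes used for the trend fit
#'   and the gamma null.
#' @param exclude_chroms chromosomes excluded from depth scaling.
#' @param alpha_m run length for the alpha estimate.
#' @param trim,k,gap gamma null trim, cutoff multiplier and peak gap
#'   (`NULL` = one smoothing bandwidth, see [call_peaks()]).
#' @param has_rho per-chromosome rho flags for the smoother (`NULL` =
#'   automatic from the trend fit).
#' @param boot_reps,boot_frac trend bootstrap settings.
#' @param min_mapq,max_insert_quantile fragment filters.
#' @param qc_floor minimum inter-replicate Pearson r before pooling
#'   warns.
#' @param seed run seed; all randomness (the bootstrap) derives from it.
#' @return list of class `micseq_run_config`.
#' @export
run_config <- function(samples, layout, window = 20000, step = 10000,
                       reference_grn = NULL, reference_condition = NULL,
                       null_chroms = c("chr7", "chr11"),
                       exclude_chroms = c("chr6", "chr12", "chr15", "chr16",
                                          "chr18", "chr19", "chrX"),
                       alpha_m = 1000, trim = 1e-7, k = 3, gap = NULL,
                       has_rho = NULL, boot_reps = 1000, boot_frac = 0.5,
                       min_mapq = 20, max_insert_quantile = 0.999,
                       qc_floor = 0.9, seed = 1) {
  stopifnot(all(c("sample", "fraction", "condition", "path") %in%
                  names(samples)))
  if (is.character(layout)) layout <- read_chrom_sizes(layout)
  grn <- samples$sample[samples$fraction == "GRN"]
  if (is.null(reference_grn)) {
    if (!length(grn)) stop("no GRN sample in the sample sheet")
    reference_grn <- grn[1]
  }
  stopifnot(reference_grn %in% grn)
  if (is.null(reference_condition)) {
    reference_condition <-
      samples$condition[samples$sample == reference_grn][1]
  }
  stopifnot(all(null_chroms %in% names(layout)))
  structure(list(samples = samples, layout = layout, window = window,
                 step = step, reference_grn = reference_grn,
                 reference_condition = reference_condition,
                 null_chroms = null_chroms, exclude_chroms = exclude_chroms,
                 alpha_m = alpha_m, trim = trim, k = k, gap = gap,
                 has_rho = has_rho, boot_reps = boot_reps,
                 boot_frac = boot_frac, min_mapq = min_mapq,
                 max_insert_quantile = max_insert_quantile,
                 qc_floor = qc_floor, seed = seed),
            class = "micseq_run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the [run_config()] arguments; `samples` is a list of
#' records and `layout` a chrom.sizes path.
#'
#' @param path YAML file.
#' @return a `micseq_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$samples <- do.call(rbind, lapply(y$samples, as.data.frame))
  do.call(run_config, y)
}

#' Run the Mic-Seq pipeline end to end
#'
#' Stages: fragment reading and filtering, window counting, replicate QC
#' (inter-replicate Pearson r excluding sex chromosomes), pooling by
#' condition, GRN normalization, depth scaling across conditions, trend
#' fitting with bootstrap, gamma extraction, peak calling against the
#' empirical null, peak comparison between conditions, and repeat
#' ratios where compartment contigs are present. All artifacts are
#' written under `outdir` with the seed recorded; re-running with the
#' same config and seed reproduces them byte-identically.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created).
#' @param force pool replicates even when QC falls below the floor.
#' @return list with the per-condition results (`tracks`, `normalized`,
#'   `trend`, `gamma`, `null`, `peaks`), the `qc` table, depth `factors`,
#'   peak `comparisons`, and `repeats` (or `NULL`).
#' @export
run_all <- function(config, outdir, force = FALSE) {
  stopifnot(inherits(config, "micseq_run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  layout <- config$layout
  grid <- window_grid(layout, config$window, config$step)
  smp <- config$samples

  # --- count ---------------------------------------------------------
  tracks <- list()
  for (i in seq_len(nrow(smp))) {
    fr <- read_fragments(smp$path[i], layout, min_mapq = config$min_mapq)
    mi <- insert_size_histogram(fr, config$max_insert_quantile)$max_insert
    fr <- fr[(fr$end - fr$start) <= mi, , drop = FALSE]
    tracks[[smp$sample[i]]] <- count_windows(fr, grid,
                                             fraction = smp$fraction[i])
  }

  # --- replicate QC and pooling per (condition, fraction) -----------
  qc <- list()
  pooled <- list()
  for (cond in unique(smp$condition)) {
    for (frac in unique(smp$fraction[smp$condition == cond])) {
      ids <- smp$sample[smp$condition == cond & smp$fraction == frac]
      if (length(ids) >= 2) {
        for (a in seq_along(ids)) for (b in seq_along(ids)) if (a < b) {
          r <- replicate_correlation(tracks[[ids[a]]], tracks[[ids[b]]])
          qc[[length(qc) + 1L]] <- data.frame(
            condition = cond, fraction = frac,
            sample_a = ids[a], sample_b = ids[b], pearson_r = r)
          if (r < config$qc_floor && !force) {
            warning(sprintf("replicate correlation %.3f below floor %.2f for %s/%s",
                            r, config$qc_floor, cond, frac))
          }
        }
      } else {
        message(sprintf("run_all: single %s sample for %s; QC skipped",
                        frac, cond))
      }
      pooled[[paste(cond, frac, sep = ".")]] <-
        pool_tracks(tracks[ids])
    }
  }
  qc <- if (length(qc)) do.call(rbind, qc) else NULL

  # --- GRN normalization --------------------------------------------
  ref_cond <- config$reference_condition
  grn_ref <- pooled[[paste(ref_cond, "GRN", sep = ".")]]
  if (is.null(grn_ref)) stop("no pooled GRN track for reference condition ",
                             ref_cond)
  conds <- unique(smp$condition[smp$fraction == "MN"])
  normalized <- lapply(conds, function(cond) {
    grn_normalize(pooled[[paste(cond, "MN", sep = ".")]], grn_ref)
  })
  names(normalized) <- conds

  # --- depth scaling -------------------------------------------------
  factors <- stats::setNames(rep(1, length(conds)), conds)
  if (length(conds) >= 2) {
    ds <- depth_scale(normalized, reference = ref_cond,
                      exclude_chroms = config$exclude_chroms,
                      m = config$alpha_m)
    normalized <- ds$tracks
    factors <- ds$factors
  }

  # --- trend, gamma, peaks per condition -----------------------------
  results <- list()
  for (cond in conds) {
    tr <- bootstrap_trend(normalized[[cond]],
                          null_chroms = config$null_chroms,
                          frac = config$boot_frac, reps = config$boot_reps,
                          seed = config$seed + match(cond, conds))
    g <- gamma_track(normalized[[cond]], tr, has_rho = config$has_rho,
                     median_window = config$alpha_m)
    nc <- null_cutoff(g, config$null_chroms, trim = config$trim,
                      k = config$k)
    pk <- call_peaks(g, nc, gap = config$gap)
    results[[cond]] <- list(trend = tr, gamma = g, null = nc, peaks = pk)
  }

  # --- peak comparison (first condition as A) ------------------------
  comparisons <- list()
  if (length(conds) >= 2) {
    for (cond in conds[-1]) {
      comparisons[[paste(conds[1], "vs", cond)]] <-
        compare_peaks(results[[conds[1]]]$peaks, results[[cond]]$peaks,
                      match_dist = config$window)
    }
  }

  write_run_outputs(outdir, config, tracks, normalized, results, qc,
                    factors, comparisons)
  list(tracks = tracks, pooled = pooled, normalized = normalized,
       results = results, qc = qc, factors = factors,
       comparisons = comparisons)
}

write_run_outputs <- function(outdir, config, tracks, normalized, results,
                              qc, factors, comparisons) {
  for (nm in names(tracks)) {
    write_track(tracks[[nm]], file.path(outdir, paste0("counts_", nm, ".tsv")))
  }
  for (nm in names(normalized)) {
    write_track(normalized[[nm]], file.path(outdir, paste0("norm_", nm, ".tsv")))
  }
  if (!is.null(qc)) {
    utils::write.table(qc, file.path(outdir, "qc_replicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (cond in names(results)) {
    r <- results[[cond]]
    jsonlite::write_json(
      list(condition = cond,
           alpha = as.list(r$trend$alpha),
           beta = r$trend$beta, rho = r$trend$rho,
           beta_sd = r$trend$bootstrap$sd[["beta"]],
           rho_sd = r$trend$bootstrap$sd[["rho"]],
           beta_ci = unname(r$trend$bootstrap$ci["beta", ]),
           rho_ci = unname(r$trend$bootstrap$ci["rho", ]),
           sigma_null = r$null$sigma_null,
           seed = config$seed, depth_factor = factors[[cond]]),
      file.path(outdir, paste0("trend_", cond, ".json")),
      auto_unbox = TRUE, digits = NA)
    write_peaks_bed(r$peaks, file.path(outdir, paste0("peaks_", cond, ".bed")))
    gdf <- r$gamma
    utils::write.table(
      data.frame(chrom = gdf$chrom, start = gdf$start, end = gdf$end,
                 gamma_raw = sprintf("%.8e", gdf$gamma_raw),
                 gamma_norm = sprintf("%.8e", gdf$gamma_norm)),
      file.path(outdir, paste0("gamma_", cond, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    utils::write.table(cmp$common,
                       file.path(outdir, paste0("common_peaks_",
                                                gsub(" ", "_", nm), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(seed = config$seed, factors = as.list(factors)),
                       file.path(outdir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
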