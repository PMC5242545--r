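#' Write a coverage track to bedGraph, wiggle, or TSV
#'
#' bedGraph lines are `chrom start end value` with 0-based half-open
#' coordinates. Overlapping-window tracks cannot be written as their raw
#' (overlapping) intervals, so each window is serialized as the step-sized
#' interval starting at its left edge (`[k*s, k*s + s)`); the representation
#' and the grid parameters are documented in `#`-comment header lines so the
#' file can be read back losslessly. Wiggle output uses `fixedStep` blocks.
#' The TSV format is self-contained: it embeds the chromosome sizes in the
#' header and round-trips mask and attributes exactly.
#'
#' Masked (`NA`) windows are omitted from bedGraph/wiggle records and
#' restored as masked on re-read.
#'
#' @param track a `micseq_track`.
#' @param path output path.
#' @param format one of `"bedGraph"`, `"wiggle"`, `"tsv"`; default guessed
#'   from the file extension, falling back to TSV.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("auto", "bedGraph", "wiggle", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     bedgraph = , bg = "bedGraph",
                     wig = , wiggle = "wiggle",
                     "tsv")
  }
  w <- attr(track, "window"); s <- attr(track, "step")
  layout <- track_layout(track)
  hdr <- c(
    sprintf("# micseq_track format=%s fraction=%s window=%g step=%g representation=%s",
            format, attr(track, "fraction"), w, s,
            if (s < w) "step-interval" else "window"),
    sprintf("# chrom_sizes %s",
            paste(sprintf("%s=%g", names(layout), unname(layout)), collapse = ","))
  )
  keep <- track$mask & !is.na(track$value)
  if (format == "bedGraph") {
    t2 <- track[keep, , drop = FALSE]
    rep_end <- pmin(t2$start + s, unname(layout[t2$chrom]))
    lines <- c(hdr, sprintf("%s\t%g\t%g\t%s", t2$chrom, t2$start, rep_end,
                            format(t2$value, digits = 15, trim = TRUE,
                                   scientific = FALSE)))
    writeLines(lines, path)
  } else if (format == "wiggle") {
    lines <- hdr
    for (ch in unique(track$chrom)) {
      sel <- track$chrom == ch
      lines <- c(lines,
                 sprintf("fixedStep chrom=%s start=1 step=%g span=%g", ch, s, s),
                 ifelse(track$mask[sel] & !is.na(track$value[sel]),
                        format(track$value[sel], digits = 15, trim = TRUE,
                               scientific = FALSE),
                        "NA"))
    }
    writeLines(lines, path)
  } else {
    hdr <- c(hdr, sprintf("# total_fragments=%g scale_factor=%.15g",
                          attr(track, "total_fragments"),
                          attr(track, "scale_factor")))
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(track[, c("chrom", "start", "end", "mid", "value", "mask")],
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(path)
}

parse_track_header <- function(lines, path) {
  h1 <- grep("^# micseq_track ", lines, value = TRUE)
  if (!length(h1)) stop("not a micseq track file (missing header): ", path)
  get <- function(key, line) {
    m <- regmatches(line, regexec(paste0(key, "=([^ ]+)"), line))[[1]]
    if (length(m) < 2) stop("malformed track header in ", path) else m[2]
  }
  hs <- grep("^# chrom_sizes ", lines, value = TRUE)
  layout <- NULL
  if (length(hs)) {
    spec <- strsplit(sub("^# chrom_sizes ", "", hs[1]), ",")[[1]]
    kv <- strsplit(spec, "=")
    layout <- genome_layout(vapply(kv, `[[`, "", 1),
                            as.numeric(vapply(kv, `[[`, "", 2)))
  }
  list(fraction = get("fraction", h1[1]),
       window = as.numeric(get("window", h1[1])),
       step = as.numeric(get("step", h1[1])),
       layout = layout)
}

#' Read a coverage track written by [write_track()]
#'
#' @param path input path.
#' @param layout optional [genome_layout()]; defaults to the one embedded
#'   in the file header.
#' @return a `micseq_track`.
#' @export
read_track <- function(path, layout = NULL) {
  lines <- readLines(path, warn = FALSE)
  info <- parse_track_header(lines, path)
  if (is.null(layout)) layout <- info$layout
  if (is.null(layout)) stop("no layout in file header; pass 'layout': ", path)
  grid <- window_grid(layout, info$window, info$step)
  body <- lines[!startsWith(lines, "#")]
  value <- rep(NA_real_, nrow(grid))
  key <- paste(grid$chrom, grid$start)
  if (any(startsWith(body, "fixedStep"))) {
    blocks <- which(startsWith(body, "fixedStep"))
    bounds <- c(blocks, length(body) + 1L)
    for (i in seq_along(blocks)) {
      hd <- body[blocks[i]]
      ch <- sub(".*chrom=([^ ]+).*", "\\1", hd)
      st <- as.numeric(sub(".*start=([0-9]+).*", "\\1", hd)) - 1
      vals <- suppressWarnings(as.numeric(body[(blocks[i] + 1L):(bounds[i + 1L] - 1L)]))
      starts <- st + info$step * (seq_along(vals) - 1)
      value[match(paste(ch, starts), key)] <- vals
    }
  } else if (length(body) && grepl("\t", body[1]) &&
             startsWith(body[1], "chrom\t")) {
    df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    value[match(paste(df$chrom, df$start), key)] <- df$value
    tr <- new_track(grid, value, fraction = info$fraction)
    tr$mask <- df$mask[match(key, paste(df$chrom, df$start))]
    tr$value[!tr$mask] <- NA_real_
    h <- grep("^# total_fragments", lines, value = TRUE)
    if (length(h)) {
      attr(tr, "total_fragments") <- suppressWarnings(
        as.numeric(sub(".*total_fragments=([^ ]+).*", "\\1", h[1])))
      attr(tr, "scale_factor") <- suppressWarnings(
        as.numeric(sub(".*scale_factor=([^ ]+).*", "\\1", h[1])))
    }
    return(tr)
  } else {
    for (i in seq_along(body)) {
      f <- strsplit(body[i], "\t")[[1]]
      if (length(f) != 4L) {
        stop(sprintf("malformed bedGraph line %d in %s",
                     which(lines == body[i])[1], path))
      }
      j <- match(paste(f[1], as.numeric(f[2])), key)
      if (is.na(j)) {
        stop(sprintf("bedGraph line %d does not align to the window grid in %s",
                     which(lines == body[i])[1], path))
      }
      value[j] <- as.numeric(f[4])
    }
  }
  new_track(grid, value, fraction = info$fraction)
}
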