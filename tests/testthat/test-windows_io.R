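test_that("fragment filters keep proper, high-MAPQ, non-duplicate pairs", {
  lay <- toy_layout()
  ok <- make_fragments("chr1", 200)
  expect_equal(nrow(read_fragments(ok, lay, max_insert = 1000)), 1L)

  # the MAPQ filter is strictly greater than 20
  at20 <- make_fragments("chr1", 200, mapq = 20)
  expect_equal(nrow(read_fragments(at20, lay)), 0L)
  at21 <- make_fragments("chr1", 200, mapq = 21)
  expect_equal(nrow(read_fragments(at21, lay)), 1L)

  # mixed fixture: 10 fragments, 3 duplicates, 2 low MAPQ, 1 over-insert
  fr <- make_fragments("chr1", seq(1000, 10000, by = 1000))
  fr$duplicate[1:3] <- TRUE
  fr$mapq[4:5] <- c(20L, 5L)
  fr$end[6] <- fr$start[6] + 1500
  got <- read_fragments(fr, lay, max_insert = 1000)
  expect_equal(nrow(got), 4L)
  # brute-force re-filter agrees
  keep <- !fr$duplicate & fr$mapq > 20 & (fr$end - fr$start) <= 1000
  expect_equal(got$left_read_mid, fr$left_read_mid[keep])
  rej <- attr(got, "rejected")
  expect_equal(unname(rej[c("duplicate", "low_mapq", "over_insert")]),
               c(3, 2, 1))
})

test_that("unknown chromosomes are rejected record-wise, not fatally", {
  lay <- toy_layout()
  fr <- rbind(make_fragments("chr1", 500), make_fragments("chrUn", 500))
  expect_message(got <- read_fragments(fr, lay), "unknown chromosome")
  expect_equal(nrow(got), 1L)
  expect_equal(unname(attr(got, "rejected")["unknown_chrom"]), 1)
})

test_that("filtering is idempotent", {
  lay <- toy_layout()
  set.seed(11)
  fr <- make_fragments("chr1", sample.int(9e4, 200),
                       mapq = sample(c(0, 20, 30, 60), 200, replace = TRUE))
  fr$duplicate <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  once <- read_fragments(fr, lay, max_insert = 500)
  twice <- read_fragments(once, lay, max_insert = 500)
  expect_equal(twice$left_read_mid, once$left_read_mid)
})

test_that("insert-size histogram picks the covering quantile", {
  lay <- toy_layout()
  fr <- make_fragments("chr1", seq(5000, 9000, by = 1000), len = 200)
  h <- insert_size_histogram(fr)
  expect_equal(h$max_insert, 200)
  expect_equal(unname(h$histogram["200"]), 5L)

  lens <- 100:1000
  fr2 <- make_fragments("chr1", seq(2000, by = 90, length.out = length(lens)))
  fr2$end <- fr2$start + lens
  fr2$left_read_mid <- fr2$start
  h2 <- insert_size_histogram(fr2, quantile = 0.999)
  expect_equal(h2$max_insert,
               unname(quantile(lens, 0.999, type = 1)))
  expect_equal(insert_size_histogram(fr2, quantile = 1)$max_insert, 1000)
  expect_error(insert_size_histogram(fr2[0, ]), "no fragments")
})

test_that("midpoints increment every overlapping window", {
  lay <- toy_layout()
  g <- window_grid(lay, 40000, 20000)
  # interior midpoint falls in exactly two windows at 50% overlap
  t1 <- count_windows(make_fragments("chr1", 25000), g)
  expect_equal(t1$value[t1$start %in% c(0, 20000)], c(1, 1))
  expect_equal(sum(t1$value), 2)
  # half-open boundary: mid 0 only hits the first window
  t2 <- count_windows(make_fragments("chr1", 0), g)
  expect_equal(t2$value[1], 1)
  expect_equal(sum(t2$value), 1)
})

test_that("window counting equals brute-force membership on fuzzed input", {
  lay <- genome_layout("chr1", 1e6)
  for (seed in 1:5) {
    set.seed(seed)
    w <- sample(c(20000, 40000, 30000), 1)
    s <- sample(c(w, w / 2, 10000), 1)
    g <- window_grid(lay, w, s)
    mids <- sample.int(1e6, 1000, replace = TRUE) - 1L
    tr <- count_windows(make_fragments("chr1", mids), g)
    expect_equal(tr$value, brute_count(mids, g))
    # assignment conservation: each midpoint lands in the number of
    # windows that contain it
    expect_equal(sum(tr$value),
                 sum(vapply(mids, function(m) {
                   sum(m >= g$start & m < g$end)
                 }, numeric(1))))
    # order independence
    tr2 <- count_windows(make_fragments("chr1", rev(mids)), g)
    expect_identical(tr2$value, tr$value)
  }
})

test_that("chrom.sizes and track files round-trip", {
  lay <- genome_layout(c("chr1", "chr2"), c(120000, 80000))
  p <- withr::local_tempfile(fileext = ".sizes")
  write_chrom_sizes(lay, p)
  lay2 <- read_chrom_sizes(p)
  expect_equal(unname(lay2), unname(lay))
  expect_equal(names(lay2), names(lay))

  g <- window_grid(lay, 40000, 20000)
  tr <- new_track(g, seq_len(nrow(g)), fraction = "MN")
  for (ext in c(".bedgraph", ".wig", ".tsv")) {
    f <- withr::local_tempfile(fileext = ext)
    write_track(tr, f)
    back <- read_track(f)
    expect_equal(back$value, tr$value, info = ext)
    expect_equal(back$chrom, tr$chrom, info = ext)
  }
  # bedGraph line format: chrom, start, end, value (0-based half-open)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_track(tr, f)
  body <- grep("^#", readLines(f), value = TRUE, invert = TRUE)
  expect_equal(body[1], "chr1\t0\t20000\t1")

  bad <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("# micseq_track format=bedGraph fraction=MN window=40000 step=20000 representation=step-interval",
               "chr1\t0\t20000"), bad)
  expect_error(read_track(bad, lay), "malformed")
})

test_that("masked windows survive a TSV round-trip", {
  lay <- toy_layout()
  g <- window_grid(lay, 20000, 10000)
  v <- rep(5, nrow(g))
  tr <- new_track(g, v, mask = c(FALSE, rep(TRUE, nrow(g) - 1)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_track(tr, f)
  back <- read_track(f)
  expect_true(is.na(back$value[1]))
  expect_false(back$mask[1])
  expect_equal(back$value[-1], tr$value[-1])
})

test_that("BAM input reconstructs pair-bridged fragments", {
  skip_if_not_installed("Rsamtools")
  lay <- genome_layout("chr1", 100000)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:100000",
    # proper pair, mapq 60, fragment [999, 1299)
    "r1\t99\tchr1\t1000\t60\t100M\t=\t1200\t300\t*\t*",
    "r1\t147\tchr1\t1200\t60\t100M\t=\t1000\t-300\t*\t*",
    # duplicate pair
    "r2\t1123\tchr1\t2000\t60\t100M\t=\t2200\t300\t*\t*",
    "r2\t1171\tchr1\t2200\t60\t100M\t=\t2000\t-300\t*\t*",
    # low mapq
    "r3\t99\tchr1\t3000\t10\t100M\t=\t3200\t300\t*\t*",
    "r3\t147\tchr1\t3200\t10\t100M\t=\t3000\t-300\t*\t*"),
    sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  got <- read_fragments(bam, lay, max_insert = 1000)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 999)
  expect_equal(got$end, 1299)
  expect_equal(got$left_read_mid, floor((999 + 1099) / 2))
  rej <- attr(got, "rejected")
  expect_equal(unname(rej["duplicate"]), 1)
  expect_equal(unname(rej["low_mapq"]), 1)
})
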