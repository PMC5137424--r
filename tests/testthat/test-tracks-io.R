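test_that("bedGraph records expand to per-base values with zero fill", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t5\t2.0", "chr1\t5\t10\t0"), f)
  tr <- suppressMessages(read_bedgraph(f))
  expect_named(tr, "chr1")
  expect_equal(tr$chr1$values, c(rep(2, 5), rep(0, 5)))

  # unspecified gap bases are zero
  writeLines(c("chr1\t2\t4\t1.5", "chr1\t8\t9\t3"), f)
  tr <- suppressMessages(read_bedgraph(f))
  expect_equal(tr$chr1$values, c(0, 0, 1.5, 1.5, 0, 0, 0, 0, 3))
})

test_that("empty bedGraph yields empty track set with a warning", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(character(0), f)
  expect_warning(out <- read_bedgraph(f), "no records")
  expect_length(out, 0)
})

test_that("malformed bedGraph records are rejected", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t5\t2", "chr1\t3\t8\t7"), f)
  expect_error(suppressMessages(read_bedgraph(f)), "conflicting")
  writeLines("chr1\t0\t5\t-1", f)
  expect_error(suppressMessages(read_bedgraph(f)), "Negative")
  writeLines("chr1\t5\t5\t1", f)
  expect_error(suppressMessages(read_bedgraph(f)), "start < end")
})

test_that("write/read bedGraph round-trips the run-length representation", {
  withr::with_seed(11, {
    vals <- rpois(500, 1.5)
  })
  tr <- coverage_track(vals, chrom = "chr2")
  f <- withr::local_tempfile(fileext = ".bedgraph")
  suppressMessages(write_bedgraph(tr, f))
  back <- suppressMessages(read_bedgraph(f))$chr2
  expect_equal(back$values, tr$values)
  expect_equal(as_tibble(back), as_tibble(tr))
})

test_that("strand cross-correlation recovers the true fragment length", {
  withr::with_seed(7, {
    readlen <- 36L
    frag <- 150L
    p <- sort(sample(1000:40000, 400))
    reads <- tibble::tibble(
      chrom = "chrS",
      start = c(p, p + frag - readlen),
      end = c(p + readlen, p + frag),
      strand = rep(c("+", "-"), each = length(p))
    )
  })
  est <- estimate_fragment_length(reads, max_shift = 300)
  expect_lte(abs(est - 150), 5)
})

test_that("fragment-length estimation handles degenerate inputs", {
  reads <- tibble::tibble(chrom = "chrS", start = c(10, 60), end = c(46, 96),
                          strand = c("+", "-"))
  # identical + and - 5' densities after zero shift
  sym <- tibble::tibble(chrom = "chrS", start = c(10, 30, 9, 29),
                        end = c(46, 66, 11, 31),
                        strand = c("+", "+", "-", "-"))
  expect_equal(estimate_fragment_length(sym, max_shift = 50), 0L)
  expect_equal(estimate_fragment_length(reads, max_shift = 0), 0L)
  plus_only <- reads[reads$strand == "+", ]
  expect_error(estimate_fragment_length(plus_only, 100), "strand '-'")
})

test_that("read extension anchors fragments at 5' ends and clips", {
  plus <- tibble::tibble(chrom = "chrS", start = 100, end = 136, strand = "+")
  tr <- extend_reads(plus, 200, chrom_length = 500)
  expect_equal(which(tr$values == 1) - 1L, 100:299)
  expect_equal(tr$total_depth, 1)

  minus <- tibble::tibble(chrom = "chrS", start = 100, end = 136,
                          strand = "-")
  tr <- extend_reads(minus, 200, chrom_length = 500)
  # fragment [136 - 200, 136) clipped at 0
  expect_equal(which(tr$values == 1) - 1L, 0:135)

  stack <- dplyr::bind_rows(rep(list(plus), 7))
  tr <- extend_reads(stack, 200, chrom_length = 500)
  expect_equal(max(tr$values), 7)
  expect_equal(tr$total_depth, 7)
})

test_that("extended coverage mass equals reads x fragment length minus clipping", {
  withr::with_seed(21, {
    n <- 60
    reads <- tibble::tibble(
      chrom = "chrS",
      start = sample(0:3000, n),
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
    reads$end <- reads$start + 36
  })
  frag <- 180
  tr <- extend_reads(reads, frag, chrom_length = 3100)
  fs <- ifelse(reads$strand == "+", reads$start, reads$end - frag)
  fe <- fs + frag
  clipped <- sum(pmax(0 - fs, 0)) + sum(pmax(fe - 3100, 0))
  expect_equal(sum(tr$values), n * frag - clipped)
})

test_that("reflecting reads and chromosome reflects the coverage track", {
  withr::with_seed(22, {
    n <- 40
    L <- 2000
    reads <- tibble::tibble(
      chrom = "chrS",
      start = sample(0:(L - 36), n),
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
    reads$end <- reads$start + 36
  })
  tr <- extend_reads(reads, 120, chrom_length = L)
  mirrored <- tibble::tibble(
    chrom = "chrS",
    start = L - reads$end,
    end = L - reads$start,
    strand = ifelse(reads$strand == "+", "-", "+")
  )
  tr2 <- extend_reads(mirrored, 120, chrom_length = L)
  expect_equal(tr2$values, rev(tr$values))
})

test_that("BED round-trip preserves intervals", {
  bed <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(0, 250),
                        end = c(100, 1250), name = c("a", "b"),
                        score = c(1.5, 0), strand = c("+", "."))
  f <- withr::local_tempfile(fileext = ".bed")
  suppressMessages(write_bed(bed, f))
  expect_equal(suppressMessages(read_bed(f)), bed)
})
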