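rd <- function(start, end, direction, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, direction = direction)
}

test_that("read-based RFD matches hand counts in both counting modes", {
  # all rightward reads
  p <- okseq_rfd(rd(c(0, 5000), c(1000, 6000), c("R", "R")),
                 "chr1", 0, 10000, 10000)
  expect_equal(p$rfd, 1)

  # balanced read-bp gives zero
  p <- okseq_rfd(rd(c(0, 0), c(1000, 1000), c("R", "L")),
                 "chr1", 0, 10000, 10000)
  expect_equal(p$rfd, 0)

  # 3 R and 1 L of equal length in one bin: (3 - 1)/(3 + 1)
  p <- okseq_rfd(rd(c(0, 2000, 4000, 6000), c(1000, 3000, 5000, 7000),
                    c("R", "R", "R", "L")), "chr1", 0, 10000, 10000)
  expect_equal(p$rfd, 0.5)

  # midpoint counting assigns each read once
  p <- okseq_rfd(rd(c(9000, 9000), c(11000, 10100), c("R", "L")),
                 "chr1", 0, 20000, 10000, count_mode = "reads")
  expect_equal(p$r_cov, c(0, 1)) # midpoint 10000 falls in bin 2
  expect_equal(p$l_cov, c(1, 0)) # midpoint 9550 falls in bin 1
})

test_that("subsampling is deterministic, degenerate at full depth, and unbiased", {
  m <- ccser1_model()
  reads <- emit_reads(m, 6000, n_cells = 150, seed = 99)

  # degenerate subsample (all reads, one draw) equals the full profile
  full <- okseq_rfd(reads, "sim", 0, m$length)
  ens1 <- subsample_rfd(reads, "sim", 0, m$length, n = nrow(reads),
                        draws = 1, seed = 4)
  expect_equal(ens1$profiles[[1]]$rfd, full$rfd)

  # same seed, bit-identical ensemble; different seed differs
  e1 <- subsample_rfd(reads, "sim", 0, m$length, n = 500, draws = 5, seed = 7)
  e2 <- subsample_rfd(reads, "sim", 0, m$length, n = 500, draws = 5, seed = 7)
  expect_identical(e1$profiles, e2$profiles)
  e3 <- subsample_rfd(reads, "sim", 0, m$length, n = 500, draws = 5, seed = 8)
  expect_false(identical(e1$profiles, e3$profiles))

  # requesting more reads than available names the available count
  expect_error(subsample_rfd(reads, "sim", 0, m$length, n = 1e6, draws = 1,
                             seed = 1), "6000")
  expect_error(subsample_rfd(reads, "sim", 0, m$length, n = 500, draws = 2),
               "seed")

  # ensemble mean approaches the full-data profile (law of large numbers)
  ens <- subsample_rfd(reads, "sim", 0, m$length, n = 1500, draws = 60,
                       seed = 21)
  ok <- !is.na(ens$summary$mean) & !is.na(full$rfd) & ens$summary$sd > 0
  dev <- abs(ens$summary$mean - full$rfd)[ok]
  se3 <- 3 * pmax(ens$summary$se[ok], 1e-3)
  expect_gt(mean(dev <= se3), 0.9)
})

test_that("binned Spearman handles self, negation, and sparse overlap", {
  m <- ccser1_model()
  reads <- emit_reads(m, 4000, n_cells = 100, seed = 12)
  p <- okseq_rfd(reads, "sim", 0, m$length)
  expect_equal(binned_spearman(p, p), 1)
  neg <- p
  neg$rfd <- -neg$rfd
  expect_equal(binned_spearman(p, neg), -1)

  # mismatched binning is rejected
  p2 <- okseq_rfd(reads, "sim", 0, m$length, bin_size = 20000)
  expect_error(binned_spearman(p, p2), "binning")

  # fewer than 3 common defined bins is an error
  a <- p; b <- p
  a$rfd[-(1:2)] <- NA
  expect_error(binned_spearman(a, b), ">= 3")

  # independent random profiles: |rho| small (null behaviour)
  set.seed(31)
  rhos <- replicate(20, {
    a$rfd <- runif(nrow(a), -1, 1)
    b$rfd <- runif(nrow(b), -1, 1)
    binned_spearman(a, b)
  })
  expect_lt(median(abs(rhos)), 0.2)
})

test_that("oriented reads round-trip through BED under both strand conventions", {
  reads <- rd(c(100, 2000, 5500), c(250, 2150, 5650), c("R", "L", "R"))
  f <- tempfile(fileext = ".bed")
  write_reads_bed(reads, f)
  back <- read_reads_bed(f, convention = "direct")
  expect_equal(back$start, reads$start)
  expect_equal(back$end, reads$end)
  expect_equal(back$direction, reads$direction)
  # the Okazaki convention flips: forward-strand fragments = leftward forks
  flipped <- read_reads_bed(f, convention = "okseq")
  expect_equal(flipped$direction, ifelse(reads$direction == "R", "L", "R"))
})

test_that("BAM reads convert with the Okazaki strand convention", {
  skip_if_not_installed("Rsamtools")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:100000",
    paste("r1", 0, "chr1", 101, 60, "50M", "*", 0, 0,
          paste(rep("A", 50), collapse = ""), "*", sep = "\t"),
    paste("r2", 16, "chr1", 201, 60, "50M", "*", 0, 0,
          paste(rep("A", 50), collapse = ""), "*", sep = "\t")), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  reads <- read_reads_bam(bam, convention = "okseq")
  expect_equal(reads$start, c(100, 200))
  expect_equal(reads$end, c(150, 250))
  expect_equal(reads$direction, c("L", "R"))
  expect_equal(read_reads_bam(bam, convention = "direct")$direction,
               c("R", "L"))
})
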