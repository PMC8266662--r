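seg <- function(start, end, direction, chrom = "chr1", fiber_id = "F") {
  data.frame(chrom = rep(chrom, length(start)), start = start, end = end,
             direction = direction, fiber_id = rep(fiber_id, length(start)))
}

test_that("binned coverage and RFD follow (R - L)/(R + L) with NA when empty", {
  # one rightward segment covering the whole locus
  p <- rfd_profile(seg(0, 50000, "R"), "chr1", 0, 50000, 10000)
  expect_true(all(p$rfd == 1))

  # fully overlapping R and L
  p <- rfd_profile(rbind(seg(0, 50000, "R"), seg(0, 50000, "L")),
                   "chr1", 0, 50000, 10000)
  expect_true(all(p$rfd == 0))

  # R over 0-10 kb plus L over 5-10 kb, 5 kb bins
  p <- rfd_profile(rbind(seg(0, 10000, "R"), seg(5000, 10000, "L")),
                   "chr1", 0, 10000, 5000)
  expect_equal(p$rfd, c(1, 0))
  expect_equal(p$r_cov, c(5000, 5000))
  expect_equal(p$l_cov, c(0, 5000))

  # empty input: all-undefined profile, not an error and not zeros
  p <- rfd_profile(seg(numeric(0), numeric(0), character(0)),
                   "chr1", 0, 30000, 10000)
  expect_true(all(is.na(p$rfd)))
  expect_true(all(p$r_cov == 0))

  # uncovered bins are NA even when others are covered
  p <- rfd_profile(seg(0, 10000, "R"), "chr1", 0, 30000, 10000)
  expect_equal(p$rfd, c(1, NA, NA))
})

test_that("coverage conserves segment bp and RFD is scale-invariant", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    s <- sort(sample(0:90000, n))
    e <- s + sample(1000:10000, n, replace = TRUE)
    d <- sample(c("R", "L"), n, replace = TRUE)
    p <- rfd_profile(seg(s, pmin(e, 100000), d), "chr1", 0, 100000,
                     sample(c(5000, 10000, 7000), 1))
    expect_equal(sum(p$r_cov), sum(pmin(e, 100000)[d == "R"] - s[d == "R"]))
    expect_equal(sum(p$l_cov), sum(pmin(e, 100000)[d == "L"] - s[d == "L"]))
    # scaling both coverages leaves rfd unchanged
    r2 <- p$r_cov * 7; l2 <- p$l_cov * 7
    rfd2 <- ifelse(r2 + l2 > 0, (r2 - l2) / (r2 + l2), NA_real_)
    expect_equal(rfd2, p$rfd)
  }
})

test_that("OEM equals the drop in leftward fraction and (rfd(i+1) - rfd(i))/2", {
  # uniform profile: zero OEM everywhere
  p <- rfd_profile(seg(0, 60000, "R"), "chr1", 0, 60000, 10000)
  expect_true(all(oem_profile(p)$oem == 0))

  # perfect origin: -1 window then +1 window gives OEM +1 at the boundary
  p <- rfd_profile(rbind(seg(0, 10000, "L"), seg(10000, 20000, "R")),
                   "chr1", 0, 20000, 10000)
  o <- oem_profile(p)
  expect_equal(o$oem, 1)
  expect_equal(o$pos, 10000)

  # fewer than two windows: empty OEM
  p <- rfd_profile(seg(0, 9000, "R"), "chr1", 0, 9000, 10000)
  expect_equal(nrow(oem_profile(p)), 0)

  # undefined flanking window propagates
  p <- rfd_profile(seg(0, 10000, "R"), "chr1", 0, 30000, 10000)
  expect_true(all(is.na(oem_profile(p)$oem)))
})

test_that("(I - T) counts per bin and sums to total I minus total T", {
  ev <- function(kind, pos) data.frame(kind = kind, chrom = rep("chr1", length(pos)),
                                       position = pos, fiber_id = rep("F", length(pos)))
  p <- it_profile(ev(character(0), numeric(0)), "chr1", 0, 30000, 10000)
  expect_true(all(p$it == 0))

  p <- it_profile(ev(c("initiation", "initiation", "termination"),
                     c(1000, 2000, 9000)), "chr1", 0, 30000, 10000)
  expect_equal(p$it, c(1, 0, 0))

  set.seed(5)
  for (rep in 1:10) {
    n <- sample(1:200, 1)
    e <- ev(sample(c("initiation", "termination"), n, replace = TRUE),
            sample(0:99999, n))
    p <- it_profile(e, "chr1", 0, 100000, 10000)
    expect_equal(sum(p$it),
                 sum(e$kind == "initiation") - sum(e$kind == "termination"))
  }
})

test_that("zone calling reports threshold runs as genomic intervals", {
  p <- rfd_profile(rbind(seg(0, 30000, "L"), seg(30000, 60000, "R")),
                   "chr1", 0, 60000, 10000)
  z <- call_zones(oem_profile(p))
  expect_equal(z$kind, "IZ")
  expect_equal(z$center, 30000)

  # flat profile: no zones
  p <- rfd_profile(seg(0, 60000, "R"), "chr1", 0, 60000, 10000)
  expect_equal(nrow(call_zones(oem_profile(p))), 0)

  # min_run filters single-boundary runs; merge_gap bridges a dip
  o <- structure(
    data.frame(chrom = "chr1", pos = seq(10000, 70000, 10000),
               oem = c(0.2, 0.02, 0.2, 0.25, -0.3, 0, 0.0)),
    class = c("rfd_oem", "data.frame"),
    bin_size = 10000, locus_start = 0, locus_end = 80000)
  z0 <- call_zones(o)
  expect_equal(z0$kind, c("IZ", "IZ", "TZ"))
  z1 <- call_zones(o, min_run = 2)
  expect_equal(z1$kind, "IZ")
  expect_equal(z1$n_boundaries, 2)
  z2 <- call_zones(o, min_run = 2, merge_gap = 1)
  expect_equal(z2$kind, "IZ")
  expect_equal(z2$n_boundaries, 3)
  expect_equal(z2$center, mean(c(10000, 30000, 40000)))
  z3 <- call_zones(o, merge_gap = 1)
  expect_equal(z3$kind, c("IZ", "TZ"))
  expect_equal(z3$n_boundaries, c(3, 1))

  # IZ and TZ intervals never overlap
  expect_true(all(z0$end[-nrow(z0)] <= z0$start[-1]))
  expect_true(all(z3$end[-nrow(z3)] <= z3$start[-1]))
})

test_that("profiles export to bedGraph omitting undefined bins and re-import", {
  p <- rfd_profile(seg(0, 10000, "R"), "chr1", 0, 30000, 10000)
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(p, f)
  back <- read_bedgraph(f)
  expect_equal(nrow(back), 1) # NA bins omitted
  expect_equal(back$start, 0)
  expect_equal(back$end, 10000)
  expect_equal(back$value, 1)
})
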