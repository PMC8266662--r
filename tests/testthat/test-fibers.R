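test_that("fibre table parsing validates invariants and round-trips", {
  tmp <- tempfile(fileext = ".tsv")
  hdr <- paste("fiber_id", "chrom", "fiber_start", "fiber_end", "analog",
               "track_start", "track_end", "left_intact", "right_intact",
               sep = "\t")

  writeLines(hdr, tmp)
  expect_identical(parse_fibers(tmp), list())

  writeLines(c(hdr,
               "F1\tchr1\t0\t40000\tIdU\t10000\t20000\t1\t1",
               "F1\tchr1\t0\t40000\tCldU\t20000\t30000\t1\t1"), tmp)
  fbs <- parse_fibers(tmp)
  expect_length(fbs, 1)
  expect_equal(nrow(fbs[[1]]$tracks), 2)
  expect_s3_class(fbs[[1]], "rfd_fiber")

  # overlapping tracks are rejected with the fibre named
  writeLines(c(hdr,
               "F1\tchr1\t0\t40000\tIdU\t10000\t20000\t1\t1",
               "F1\tchr1\t0\t40000\tCldU\t15000\t25000\t1\t1"), tmp)
  expect_error(parse_fibers(tmp), "F1.*overlap")

  writeLines(c(hdr, "F2\tchr1\t0\t40000\tXdU\t10000\t20000\t1\t1"), tmp)
  expect_error(parse_fibers(tmp), "F2.*analog")

  writeLines(c(hdr, "F3\tchr1\t0\t40000\tIdU\t10000\t50000\t1\t1"), tmp)
  expect_error(parse_fibers(tmp), "F3.*span")

  # broken ends must abut the fibre boundary
  writeLines(c(hdr, "F4\tchr1\t0\t40000\tIdU\t10000\t20000\t0\t1"), tmp)
  expect_error(parse_fibers(tmp), "F4")

  # parse -> write -> parse is the identity
  fbs <- random_intact_fibers(25, seed = 11)
  write_fibers(fbs, tmp)
  expect_equal(parse_fibers(tmp), fbs)
})

test_that("adjacency grammar classifies forks and events with correct anchors", {
  # elongating rightward fork
  fb <- intact_fiber("F1", 0, 40000, c("IdU", "CldU"),
                     c(10000, 20000), c(20000, 30000))
  st <- classify_structures(fb)
  expect_equal(st$kind, "right_fork")

  # contiguous initiation: anchor at the centre of the shared IdU
  fb <- intact_fiber("F1", 0, 28000, c("CldU", "IdU", "CldU"),
                     c(0, 8000, 20000), c(8000, 20000, 28000))
  st <- classify_structures(fb)
  expect_equal(st$kind, "initiation")
  expect_equal(st$anchor, 14000)

  # split termination: anchor at the centre of the inter-CldU gap, which
  # may exceed the fork-gap limit
  fb <- intact_fiber("F1", 0, 40000, c("IdU", "CldU", "CldU", "IdU"),
                     c(0, 10000, 22000, 30000), c(10000, 18000, 30000, 40000))
  st <- classify_structures(fb)
  expect_equal(st$kind, "termination")
  expect_equal(st$anchor, 20000)

  # split initiation (origin fired before the first pulse)
  fb <- intact_fiber("F1", 0, 40000, c("CldU", "IdU", "IdU", "CldU"),
                     c(0, 8000, 24000, 32000), c(8000, 16000, 32000, 40000))
  st <- classify_structures(fb)
  expect_equal(st$kind, "initiation")
  expect_equal(st$anchor, 20000)

  # leftward fork, lone intact CldU, lone IdU
  fb <- intact_fiber("F1", 0, 100000,
                     c("CldU", "IdU", "CldU", "IdU"),
                     c(0, 10000, 40000, 70000),
                     c(10000, 20000, 50000, 80000))
  st <- classify_structures(fb)
  expect_equal(st$kind, c("left_fork", "initiation", "unoriented"))
  expect_equal(st$anchor[2], 45000)

  # a gap above max_fork_gap separates fork tracks into lone structures
  fb <- intact_fiber("F1", 0, 40000, c("IdU", "CldU"),
                     c(10000, 25000), c(20000, 35000))
  expect_equal(classify_structures(fb)$kind, c("unoriented", "initiation"))
  expect_equal(classify_structures(fb, max_fork_gap = 5000)$kind, "right_fork")

  # a lone CldU with a broken end is direction-ambiguous
  fb <- new_fiber("F1", "chr1", 0, 30000,
                  data.frame(analog = "CldU", start = 0, end = 12000,
                             left_intact = FALSE, right_intact = TRUE))
  expect_equal(classify_structures(fb)$kind, "unoriented")

  # consecutive events may share a track: the junction grammar reads
  # CldU-IdU-CldU-IdU as an initiation and an adjacent termination
  fb <- intact_fiber("F1", 0, 40000, c("CldU", "IdU", "CldU", "IdU"),
                     c(0, 10000, 20000, 30000), c(10000, 20000, 30000, 40000))
  st <- classify_structures(fb)
  expect_equal(st$kind, c("initiation", "termination"))
  expect_equal(st$anchor, c(15000, 25000))

  # every track belongs to at least one structure
  for (fb in random_intact_fibers(50, seed = 3)) {
    st <- classify_structures(fb)
    covered <- unlist(mapply(seq, st$first, st$last, SIMPLIFY = FALSE))
    expect_identical(sort(unique(covered)), seq_len(nrow(fb$tracks)))
  }
})

test_that("orientation follows the midpoint rule", {
  # rightward fork: R extends from the midpoint of the start gap to the
  # midpoint of the end gap
  fb <- intact_fiber("F1", 0, 40000, c("IdU", "CldU"),
                     c(10000, 20000), c(20000, 30000))
  res <- orient_fiber(fb)
  expect_equal(res$segments$start, 5000)
  expect_equal(res$segments$end, 35000)
  expect_equal(res$segments$direction, "R")
  expect_equal(nrow(res$events), 0)

  # initiation splits the fibre at the anchor
  fb <- intact_fiber("F1", 0, 28000, c("CldU", "IdU", "CldU"),
                     c(0, 8000, 20000), c(8000, 20000, 28000))
  res <- orient_fiber(fb)
  expect_equal(res$segments$direction, c("L", "R"))
  expect_equal(res$segments$start, c(0, 14000))
  expect_equal(res$segments$end, c(14000, 28000))
  expect_equal(res$events$kind, "initiation")
  expect_equal(res$events$position, 14000)

  # a lone IdU gives neither segments nor events
  fb <- intact_fiber("F1", 0, 30000, "IdU", 10000, 20000)
  res <- orient_fiber(fb)
  expect_equal(nrow(res$segments), 0)
  expect_equal(nrow(res$events), 0)

  # a broken track abuts the boundary: no midpoint extension at the break
  fb <- new_fiber("F1", "chr1", 0, 40000,
                  data.frame(analog = c("IdU", "CldU"),
                             start = c(0, 10000), end = c(10000, 20000),
                             left_intact = c(FALSE, TRUE),
                             right_intact = c(TRUE, TRUE)))
  res <- orient_fiber(fb)
  expect_equal(res$segments$start, 0)
  expect_equal(res$segments$end, 30000)
})

test_that("event anchors sit at L-to-R or R-to-L transitions of the segments", {
  fbs <- random_intact_fibers(200, seed = 7)
  for (fb in fbs) {
    res <- orient_fiber(fb)
    if (nrow(res$events) == 0) next
    seg <- res$segments[order(res$segments$start), ]
    for (j in seq_len(nrow(res$events))) {
      pos <- res$events$position[j]
      left <- seg$direction[seg$end == pos]
      right <- seg$direction[seg$start == pos]
      expect_length(left, 1)
      expect_length(right, 1)
      if (res$events$kind[j] == "initiation") {
        expect_equal(left, "L"); expect_equal(right, "R")
      } else {
        expect_equal(left, "R"); expect_equal(right, "L")
      }
    }
  }
})

test_that("fully oriented intact fibres are tiled between the end-gap midpoints", {
  fbs <- random_intact_fibers(300, seed = 13)
  n_checked <- 0
  for (fb in fbs) {
    st <- classify_structures(fb)
    if (any(st$kind == "unoriented")) next
    res <- orient_fiber(fb)
    lo <- floor((fb$start + fb$tracks$start[1]) / 2)
    hi <- floor((fb$end + fb$tracks$end[nrow(fb$tracks)]) / 2)
    expect_true(tiles_exactly(res$segments, lo, hi))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 100)
})

test_that("reflection swaps R and L and reflects event positions", {
  fbs <- random_intact_fibers(150, seed = 17)
  for (fb in fbs) {
    tot <- fb$start + fb$end
    a <- orient_fiber(fb)
    b <- orient_fiber(reflect_fiber(fb))
    sa <- a$segments[order(a$segments$start), ]
    sb <- b$segments[order(-b$segments$end), ]
    expect_equal(nrow(sa), nrow(sb))
    if (nrow(sa) > 0) {
      expect_equal(sa$start, tot - sb$end, tolerance = 1e-9)
      expect_equal(sa$direction, ifelse(sb$direction == "R", "L", "R"))
    }
    ea <- sort(a$events$position)
    eb <- sort(tot - b$events$position)
    expect_equal(ea, eb)
    expect_equal(sort(a$events$kind), sort(b$events$kind))
  }
})
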