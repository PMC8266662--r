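# fixtures are built in code; all stochastic helpers take an explicit seed

# shorthand for a fibre whose tracks are all intact
intact_fiber <- function(id, start, end, analogs, t_starts, t_ends,
                         chrom = "chr1") {
  new_fiber(id, chrom, start, end,
            data.frame(analog = analogs, start = t_starts, end = t_ends,
                       left_intact = TRUE, right_intact = TRUE))
}

# random fully-intact fibres assembled from random structure patterns;
# even coordinates keep integer midpoints exact under reflection
random_intact_fibers <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pats <- list(c("IdU", "CldU"), c("CldU", "IdU"),
                 c("CldU", "IdU", "CldU"), c("IdU", "CldU", "IdU"),
                 c("CldU", "IdU", "IdU", "CldU"),
                 c("IdU", "CldU", "CldU", "IdU"),
                 "CldU", "IdU")
    k <- sample(1:4, 1)
    analogs <- character(0); starts <- numeric(0); ends <- numeric(0)
    pos <- 2 * sample(0:5000, 1)
    first <- pos
    for (j in seq_len(k)) {
      p <- pats[[sample(length(pats), 1)]]
      for (t in seq_along(p)) {
        len <- 2 * sample(500:10000, 1)
        analogs <- c(analogs, p[t]); starts <- c(starts, pos)
        ends <- c(ends, pos + len)
        pos <- pos + len
        if (t < length(p)) {
          # internal same-analog event gaps may exceed the fork-gap limit
          gap <- if (p[t] == p[t + 1]) 2 * sample(0:5000, 1)
          else 2 * sample(0:1400, 1)
          pos <- pos + gap
        }
      }
      if (j < k) pos <- pos + 2 * sample(1600:10000, 1) # separates structures
    }
    gl <- 2 * sample(0:4000, 1)
    gr <- 2 * sample(0:4000, 1)
    intact_fiber(sprintf("R%05d", i), first - gl, pos + gr, analogs,
                 starts, ends)
  })
}

# segments tile an interval exactly once (no gaps, no overlaps)
tiles_exactly <- function(segments, lo, hi) {
  if (nrow(segments) == 0) return(lo == hi)
  o <- order(segments$start)
  s <- segments$start[o]; e <- segments$end[o]
  s[1] == lo && e[length(e)] == hi &&
    (length(s) == 1 || all(s[-1] == e[-length(e)]))
}
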