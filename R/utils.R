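#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif rlnorm rpois cor complete.cases median
#' @importFrom utils read.delim write.table packageVersion
NULL

# round half away from zero at `digits` decimals (presentation rounding for
# report tables; base round() half-to-even would drop 0.5 cases differently)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# integer midpoint, rounded down (BED convention, 0-based half-open)
midpoint <- function(a, b) floor((a + b) / 2)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# sum of bp overlap of [starts, ends) (0-based, half-open) with consecutive
# bins of `bin_size` tiling [locus_start, locus_end); returns one value per bin
binned_bp <- function(starts, ends, locus_start, locus_end, bin_size) {
  n_bins <- ceiling((locus_end - locus_start) / bin_size)
  out <- numeric(n_bins)
  if (length(starts) == 0) return(out)
  s <- pmax(starts, locus_start) - locus_start
  e <- pmin(ends, locus_end) - locus_start
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  bin_bounds <- c(seq(0, by = bin_size, length.out = n_bins),
                  locus_end - locus_start)
  for (i in seq_along(s)) {
    b1 <- floor(s[i] / bin_size) + 1
    b2 <- min(ceiling(e[i] / bin_size), n_bins)
    idx <- b1:b2
    out[idx] <- out[idx] +
      pmin(e[i], bin_bounds[idx + 1]) - pmax(s[i], bin_bounds[idx])
  }
  out
}

bin_bounds <- function(locus_start, locus_end, bin_size) {
  n_bins <- ceiling((locus_end - locus_start) / bin_size)
  start <- locus_start + seq(0, by = bin_size, length.out = n_bins)
  end <- pmin(start + bin_size, locus_end)
  list(start = start, end = end, n = n_bins)
}
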