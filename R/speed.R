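#' Per-fork velocity and position from track lengths
#'
#' For every elongating fork (right_fork / left_fork structure) on the given
#' fibres, estimates the fork's velocity from the labelled track lengths and
#' the pulse duration, and assigns the fork a position:
#' \itemize{
#'   \item both tracks intact: speed = (IdU + CldU length) / (2 x pulse),
#'     position = centre of the combined IdU+CldU span;
#'   \item intact IdU, CldU interrupted by a fibre break: speed = IdU length
#'     / pulse, position = centre of the IdU track;
#'   \item intact CldU, IdU interrupted: speed = CldU length / pulse,
#'     position = centre of the CldU track.
#' }
#' Forks whose both tracks are broken give no measurement and are counted in
#' the `n_skipped` attribute. A track is intact when neither of its ends is
#' interrupted by a physical fibre break.
#'
#' @param fibers list of `rfd_fiber` objects (or a single fibre).
#' @param pulse_min duration of each analog pulse in minutes (default 20).
#' @param max_fork_gap passed to [classify_structures()].
#' @return data.frame with columns `fiber_id, chrom, direction, position,
#'   speed_kb_min, idu_kb, cldu_kb, pattern`; attribute `n_skipped`.
#' @export
fork_speeds <- function(fibers, pulse_min = 20, max_fork_gap = 3000) {
  stopifnot(pulse_min > 0)
  if (inherits(fibers, "rfd_fiber")) fibers <- list(fibers)
  rows <- list()
  skipped <- 0L
  for (fb in fibers) {
    st <- classify_structures(fb, max_fork_gap)
    forks <- st[st$kind %in% c("right_fork", "left_fork"), , drop = FALSE]
    for (k in seq_len(nrow(forks))) {
      i1 <- forks$first[k]; i2 <- forks$last[k]
      tr <- fb$tracks
      idu_i <- if (tr$analog[i1] == "IdU") i1 else i2
      cldu_i <- if (idu_i == i1) i2 else i1
      idu_ok <- tr$left_intact[idu_i] && tr$right_intact[idu_i]
      cldu_ok <- tr$left_intact[cldu_i] && tr$right_intact[cldu_i]
      idu_kb <- (tr$end[idu_i] - tr$start[idu_i]) / 1000
      cldu_kb <- (tr$end[cldu_i] - tr$start[cldu_i]) / 1000
      if (idu_ok && cldu_ok) {
        speed <- (idu_kb + cldu_kb) / (2 * pulse_min)
        pos <- midpoint(tr$start[i1], tr$end[i2])
        pat <- "both_intact"
      } else if (idu_ok) {
        speed <- idu_kb / pulse_min
        pos <- midpoint(tr$start[idu_i], tr$end[idu_i])
        pat <- "idu_intact_cldu_broken"
        cldu_kb <- NA_real_
      } else if (cldu_ok) {
        speed <- cldu_kb / pulse_min
        pos <- midpoint(tr$start[cldu_i], tr$end[cldu_i])
        pat <- "cldu_intact_idu_broken"
        idu_kb <- NA_real_
      } else {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        fiber_id = fb$fiber_id, chrom = fb$chrom,
        direction = if (forks$kind[k] == "right_fork") "R" else "L",
        position = pos, speed_kb_min = speed,
        idu_kb = idu_kb, cldu_kb = cldu_kb, pattern = pat)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(fiber_id = character(), chrom = character(),
                  direction = character(), position = numeric(),
                  speed_kb_min = numeric(), idu_kb = numeric(),
                  cldu_kb = numeric(), pattern = character())
  attr(out, "n_skipped") <- skipped
  out
}

#' Write fork measurements to TSV
#'
#' @param speeds data.frame from [fork_speeds()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fork_speeds <- function(speeds, path) {
  write.table(speeds, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
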