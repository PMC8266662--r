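#' S-phase duration from doubling time and S fraction
#'
#' In an asynchronously cycling population the expected time a cell spends
#' in S phase is the fraction of cells in S times the doubling time.
#'
#' @param doubling_time population doubling time in minutes.
#' @param s_fraction proportion of cells in S phase, in (0, 1].
#' @return S-phase duration in minutes (unrounded).
#' @export
s_phase_duration <- function(doubling_time, s_fraction) {
  stopifnot(doubling_time > 0)
  if (!(s_fraction > 0 && s_fraction <= 1))
    stopf("s_fraction must be in (0, 1], got %s", format(s_fraction))
  doubling_time * s_fraction
}

#' Theoretical fork travel distance per S-phase quarter
#'
#' A fork born at the start of quarter q of S phase and running at constant
#' velocity to the end of S travels `d(q) = (1 - (q-1)/4) x s_duration x
#' velocity`: the whole of S for quarter 1 down to the last quarter only for
#' quarter 4.
#'
#' @param s_duration S-phase duration in minutes.
#' @param velocity fork velocity in kb/min.
#' @return numeric vector `d(1..4)` in kb (unrounded).
#' @export
quarter_distances <- function(s_duration, velocity) {
  stopifnot(s_duration > 0, velocity >= 0)
  (1 - (0:3) / 4) * s_duration * velocity
}

#' Timing-weighted mean fork travel distance
#'
#' Weights the quarter travel distances by the proportion of forks firing in
#' each quarter: `sum(d(q) * f(q))`. Computed on unrounded distances.
#'
#' @param d quarter distances from [quarter_distances()] (kb).
#' @param f quarter firing fractions, summing to ~1 (1% slack for printed
#'   percentages).
#' @return mean travel distance in kb (unrounded).
#' @export
mean_travel <- function(d, f) {
  stopifnot(length(d) == 4, length(f) == 4, all(f >= 0))
  if (abs(sum(f) - 1) > 0.01)
    stopf("quarter fractions sum to %.4f, not 1", sum(f))
  sum(d * f)
}

#' Average meeting point of converging forks
#'
#' Divides the separation between two initiation zones in proportion to the
#' timing-weighted travel distances of the forks converging from each side:
#' `dIZ1 / (dIZ1 + dIZ2) x locus_len`, measured from the left (5') zone.
#'
#' @param d_iz1 mean travel distance of rightward forks from the 5' IZ (kb).
#' @param d_iz2 mean travel distance of leftward forks from the 3' IZ (kb).
#' @param locus_len distance between the zones (kb).
#' @return meeting point in kb from the 5' IZ (unrounded).
#' @export
meeting_point <- function(d_iz1, d_iz2, locus_len) {
  stopifnot(d_iz1 > 0, d_iz2 > 0, locus_len > 0)
  d_iz1 / (d_iz1 + d_iz2) * locus_len
}

#' Fraction of forks able to reach the opposite initiation zone
#'
#' Only forks leaving the source zone in the first S quarter can cover the
#' inter-zone distance, and only if the target zone has not yet fired, i.e.
#' fires in the last quarter: the reachable fraction is the product
#' `f_source_S1 x f_target_S4 x 100` (the two firing times being
#' independent).
#'
#' @param f_source_s1 fraction of source-zone forks firing in S1, in [0, 1].
#' @param f_target_s4 fraction of target-zone firings in S4, in [0, 1].
#' @return percentage (unrounded).
#' @export
reach_fraction <- function(f_source_s1, f_target_s4) {
  stopifnot(f_source_s1 >= 0, f_source_s1 <= 1,
            f_target_s4 >= 0, f_target_s4 <= 1)
  f_source_s1 * f_target_s4 * 100
}

# accept quarter fractions given as percentages or proportions
.as_proportions <- function(f, unit = c("proportion", "percent")) {
  unit <- match.arg(unit)
  f <- as.numeric(f)
  if (unit == "percent") f <- f / 100
  f
}

#' Fork-travel kinetics of a locus
#'
#' Full closed-form chain from the measured inputs (doubling time, fraction
#' of cells in S, per-direction median fork velocities, quarter-resolved
#' firing-time fractions of each initiation zone) to the derived quantities:
#' S-phase duration, quarter travel distances, timing-weighted mean travel
#' per direction and - when both directions and a locus length are given -
#' the average meeting point of converging forks and the percentage of forks
#' from each zone able to reach the other. All intermediates are kept at
#' full precision; rounding happens only in the print method, half-up at the
#' precision of the reported unit. A distance-feasibility diagnostic flags,
#' per direction, whether an S1-born fork can cover the locus by the end of
#' the third quarter (`0.75 x s_duration x v >= locus_len`), the premise of
#' the reachability product.
#'
#' @param doubling_time_min doubling time, minutes.
#' @param s_fraction proportion of cells in S (0-1); or give `s_percent`.
#' @param s_percent percentage of cells in S (alternative to `s_fraction`).
#' @param right,left per-direction lists with `velocity_kb_min`,
#'   `timing_quarters` (length-4) and optional `timing_unit`
#'   ("percent"/"proportion"). `left` may be omitted for one-sided analyses.
#' @param locus_length_kb distance between the 5' and 3' zones, kb
#'   (optional).
#' @return object of class `rfd_kinetics`: a list with `s_duration`,
#'   per-direction sublists (`velocity`, `d`, `f`, `mean_travel`), and when
#'   applicable `meeting_point_kb`, `reach_right_pct`, `reach_left_pct`,
#'   `feasible_right`, `feasible_left`.
#' @export
fork_kinetics <- function(doubling_time_min, s_fraction = NULL,
                          s_percent = NULL, right, left = NULL,
                          locus_length_kb = NULL) {
  if (is.null(s_fraction)) {
    if (is.null(s_percent)) stopf("give s_fraction or s_percent")
    s_fraction <- s_percent / 100
  }
  s_dur <- s_phase_duration(doubling_time_min, s_fraction)
  side <- function(x) {
    f <- .as_proportions(x$timing_quarters, x$timing_unit %||% "proportion")
    d <- quarter_distances(s_dur, x$velocity_kb_min)
    list(velocity = x$velocity_kb_min, d = d, f = f,
         mean_travel = mean_travel(d, f))
  }
  res <- list(doubling_time = doubling_time_min, s_fraction = s_fraction,
              s_duration = s_dur, right = side(right),
              locus_length_kb = locus_length_kb)
  if (!is.null(left)) {
    res$left <- side(left)
    if (!is.null(locus_length_kb)) {
      res$meeting_point_kb <- meeting_point(res$right$mean_travel,
                                            res$left$mean_travel,
                                            locus_length_kb)
      # rightward reach: source (5') must fire in S1, target (3') in S4;
      # leftward reach is the mirror, with the 5' zone as the late target
      res$reach_right_pct <- reach_fraction(res$right$f[1], res$left$f[4])
      res$reach_left_pct <- reach_fraction(res$left$f[1], res$right$f[4])
      res$feasible_right <- 0.75 * s_dur * right$velocity_kb_min >= locus_length_kb
      res$feasible_left <- 0.75 * s_dur * left$velocity_kb_min >= locus_length_kb
    }
  }
  class(res) <- "rfd_kinetics"
  res
}

#' @export
print.rfd_kinetics <- function(x, ...) {
  cat("Fork-travel kinetics\n")
  cat(sprintf("  Doubling time              %6s min\n", format(x$doubling_time)))
  cat(sprintf("  %% of cells in S phase      %6s\n", format(x$s_fraction * 100)))
  cat(sprintf("  Estimated S-phase duration %6d min\n",
              round_half_up(x$s_duration)))
  show_side <- function(s, label) {
    cat(sprintf("  %s forks: v = %s kb/min\n", label, format(s$velocity)))
    for (q in 1:4)
      cat(sprintf("    dS%d %5d kb   fS%d %5.1f %%\n", q,
                  round_half_up(s$d[q]), q, s$f[q] * 100))
    cat(sprintf("    mean travel distance %5d kb\n",
                round_half_up(s$mean_travel)))
  }
  show_side(x$right, "rightward")
  if (!is.null(x$left)) show_side(x$left, "leftward")
  if (!is.null(x$meeting_point_kb)) {
    cat(sprintf("  Locus length               %6s kb\n",
                format(x$locus_length_kb)))
    cat(sprintf("  Average fork meeting point %6d kb from the 5' zone\n",
                round_half_up(x$meeting_point_kb)))
    cat(sprintf("  Rightward forks reaching the 3' zone  %s %% (feasible: %s)\n",
                format(round_half_up(x$reach_right_pct, 1)), x$feasible_right))
    cat(sprintf("  Leftward forks reaching the 5' zone   %s %% (feasible: %s)\n",
                format(round_half_up(x$reach_left_pct, 2)), x$feasible_left))
  }
  invisible(x)
}

#' Read kinetics inputs from YAML
#'
#' The YAML mirrors the [fork_kinetics()] arguments:
#' `doubling_time_min`, `s_percent` (or `s_fraction`), `right:`/`left:`
#' blocks with `velocity_kb_min`, `timing_quarters`, `timing_unit`, and
#' optionally `locus_length_kb`. Packaged examples:
#' `system.file("extdata", "table1_dmd_tet.yaml", package = "combRFD")` and
#' `"table2_ccser1_ba.yaml"`.
#'
#' @param path YAML path.
#' @return an `rfd_kinetics` object.
#' @export
kinetics_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  fork_kinetics(doubling_time_min = y$doubling_time_min,
                s_fraction = y$s_fraction, s_percent = y$s_percent,
                right = y$right, left = y$left,
                locus_length_kb = y$locus_length_kb)
}

#' Write a kinetics report as TSV
#'
#' One row per derived quantity, rounded half-up at the precision of the
#' printed unit (integer kb and minutes; reach percentages at 1-2 decimals).
#'
#' @param x an `rfd_kinetics` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_kinetics_tsv <- function(x, path) {
  rows <- data.frame(parameter = "s_duration_min",
                     value = round_half_up(x$s_duration))
  add <- function(p, v) rbind(rows, data.frame(parameter = p, value = v))
  for (lab in intersect(c("right", "left"), names(x))) {
    s <- x[[lab]]
    for (q in 1:4)
      rows <- add(sprintf("d_%s_S%d_kb", lab, q), round_half_up(s$d[q]))
    rows <- add(sprintf("mean_travel_%s_kb", lab),
                round_half_up(s$mean_travel))
  }
  if (!is.null(x$meeting_point_kb)) {
    rows <- add("meeting_point_kb", round_half_up(x$meeting_point_kb))
    rows <- add("reach_right_pct", round_half_up(x$reach_right_pct, 1))
    rows <- add("reach_left_pct", round_half_up(x$reach_left_pct, 2))
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
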