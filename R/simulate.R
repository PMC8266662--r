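#' Define a stochastic locus replication model
#'
#' The model embodies the replication program of a large locus: delimited
#' initiation zones (IZs) with a per-cell firing probability (efficiency)
#' and a quarter-resolved firing-time distribution over S phase, plus
#' uniformly dispersed low-efficiency origins elsewhere. Forks progress at
#' constant velocity (rightward and leftward velocities may differ); forks
#' converging from neighbouring origins merge into terminations, and an
#' origin overrun by a fork before its own firing time is passively
#' replicated and never fires. Forks entering from outside the modelled
#' locus guarantee full replication by the end of S.
#'
#' Firing times are drawn by quarter index from the zone's distribution,
#' then uniformly within the quarter. `timing_coupling` sets the
#' probability that a zone's firing-time quantile is the cell's shared
#' S-progression quantile rather than an independent draw: 1 (default)
#' makes zone firing order reproducible from cell to cell, as under a
#' cell-wide replication-timing program, while 0 makes zones fire
#' independently. Dispersed origins always fire at independent uniform
#' times.
#'
#' @param length_bp locus length in bp.
#' @param izs data.frame with one row per initiation zone: `center` (bp),
#'   `width` (bp; firing positions are uniform on center +- width/2),
#'   `efficiency` in [0,1], `q1..q4` firing-quarter probabilities summing
#'   to 1. May be empty for dispersed-only models.
#' @param dispersed_rate expected dispersed (licensed) origins per Mb per
#'   cell; each fires at an independent uniform time in S unless passively
#'   replicated first, so the realized initiation density is lower.
#' @param v_right,v_left fork velocities in kb/min.
#' @param s_duration_min S-phase duration in minutes.
#' @param timing_coupling probability in [0,1] that an IZ uses the cell's
#'   shared timing quantile (default 1).
#' @param velocity_sdlog lognormal sd of a per-cell velocity multiplier
#'   (default 0 = constant velocity).
#' @param chrom chromosome name for emitted coordinates.
#' @return object of class `rfd_locus_model`.
#' @export
locus_model <- function(length_bp, izs = NULL, dispersed_rate = 0,
                        v_right = 1.9, v_left = 1.8, s_duration_min = 465,
                        timing_coupling = 1, velocity_sdlog = 0,
                        chrom = "sim") {
  if (is.null(izs))
    izs <- data.frame(center = numeric(), width = numeric(),
                      efficiency = numeric(), q1 = numeric(), q2 = numeric(),
                      q3 = numeric(), q4 = numeric())
  stopifnot(length_bp > 0, dispersed_rate >= 0, v_right > 0, v_left > 0,
            s_duration_min > 0, timing_coupling >= 0, timing_coupling <= 1)
  if (nrow(izs) > 0) {
    qsum <- rowSums(izs[, c("q1", "q2", "q3", "q4")])
    if (any(abs(qsum - 1) > 0.01))
      stopf("IZ quarter distributions must sum to 1")
    if (any(izs$efficiency < 0 | izs$efficiency > 1))
      stopf("IZ efficiencies must be in [0, 1]")
  }
  structure(list(length = length_bp, izs = izs,
                 dispersed_rate = dispersed_rate,
                 v_right = v_right * 1000, v_left = v_left * 1000, # bp/min
                 s_duration = s_duration_min,
                 timing_coupling = timing_coupling,
                 velocity_sdlog = velocity_sdlog, chrom = chrom),
            class = "rfd_locus_model")
}

#' @export
print.rfd_locus_model <- function(x, ...) {
  cat(sprintf(paste0("<rfd_locus_model> %s: %.0f kb, %d IZ(s), dispersed ",
                     "%.2f/Mb, vR %.2f / vL %.2f kb/min, S %.0f min\n"),
              x$chrom, x$length / 1000, nrow(x$izs), x$dispersed_rate,
              x$v_right / 1000, x$v_left / 1000, x$s_duration))
  invisible(x)
}

#' Default two-IZ model of the overexpressed CCSER1 locus
#'
#' A 661-kb locus with efficient initiation zones at both ends, 621 kb
#' apart (the distance used in the fork-travel analysis of this allele),
#' early-firing at the 5' end and late-firing at the 3' end, with the
#' measured quarter distributions, fork velocities 1.9 (rightward) and 1.8
#' (leftward) kb/min and a 465-min S phase. No dispersed origins.
#'
#' @param ... overrides passed on to [locus_model()].
#' @return an `rfd_locus_model`.
#' @export
ccser1_model <- function(...) {
  defaults <- list(
    length_bp = 661000,
    izs = data.frame(center = c(20000, 641000), width = c(30000, 30000),
                     efficiency = c(1, 1),
                     q1 = c(0.263, 0.057), q2 = c(0.532, 0.201),
                     q3 = c(0.176, 0.410), q4 = c(0.029, 0.332)),
    dispersed_rate = 0, v_right = 1.9, v_left = 1.8, s_duration_min = 465)
  args <- utils::modifyList(defaults, list(...))
  do.call(locus_model, args)
}

#' Dispersed-only model (no initiation zones)
#'
#' Random, inefficient initiation everywhere: the regime in which individual
#' initiation events are observable on fibres while the population RFD
#' stays flat. The default licensed-origin rate is calibrated so that
#' roughly one initiation event is realized per two mean-length (95 kb)
#' fibre fragments, i.e. about 5 events per Mb per cell.
#'
#' @param dispersed_rate licensed origins per Mb per cell (default 32;
#'   passive replication brings realized initiations to ~5.3/Mb under the
#'   default velocities and S duration).
#' @param ... overrides passed on to [locus_model()].
#' @return an `rfd_locus_model`.
#' @export
dispersed_model <- function(dispersed_rate = 32, ...) {
  args <- utils::modifyList(
    list(length_bp = 661000, izs = NULL, dispersed_rate = dispersed_rate),
    list(...))
  do.call(locus_model, args)
}

# inverse CDF of a quarter-mixture firing time: quarter from the zone's
# distribution, uniform within the quarter
.quarter_time <- function(q_probs, u, s_duration) {
  cml <- cumsum(q_probs)
  q <- findInterval(u, c(0, cml[-4]), rightmost.closed = FALSE)
  q <- max(1L, min(4L, q))
  lo <- if (q == 1) 0 else cml[q - 1]
  rel <- if (q_probs[q] > 0) (u - lo) / q_probs[q] else 0.5
  ((q - 1) + rel) / 4 * s_duration
}

# one cell: fired origins after passive suppression, replication pieces
# (direction + timing) clipped to the locus, and initiation/termination
# events. Uses the current RNG stream.
.sim_cell <- function(model) {
  s <- model$s_duration
  mult <- if (model$velocity_sdlog > 0)
    rlnorm(1, -model$velocity_sdlog^2 / 2, model$velocity_sdlog) else 1
  vr <- model$v_right * mult
  vl <- model$v_left * mult
  pad <- s * max(vr, vl)
  u_cell <- runif(1)
  pos <- numeric(0); tm <- numeric(0)
  izs <- model$izs
  for (k in seq_len(nrow(izs))) {
    if (runif(1) > izs$efficiency[k]) next
    u <- if (runif(1) <= model$timing_coupling) u_cell else runif(1)
    pos <- c(pos, izs$center[k] + runif(1, -izs$width[k] / 2, izs$width[k] / 2))
    tm <- c(tm, .quarter_time(as.numeric(izs[k, c("q1", "q2", "q3", "q4")]),
                              u, s))
  }
  n_disp <- rpois(1, model$dispersed_rate * (model$length + 2 * pad) / 1e6)
  if (n_disp > 0) {
    pos <- c(pos, runif(n_disp, -pad, model$length + pad))
    tm <- c(tm, runif(n_disp, 0, s))
  }
  # boundary forks entering from outside arrive at the locus edges no later
  # than the end of S
  pos <- c(pos, -pad, model$length + pad)
  tm <- c(tm, 0, 0)
  # passive suppression: process candidates in firing order; an origin
  # reached by an active fork before its own time never fires
  ord <- order(tm)
  act_p <- numeric(0); act_t <- numeric(0)
  for (i in ord) {
    if (length(act_p)) {
      dx <- pos[i] - act_p
      arr <- act_t + ifelse(dx >= 0, dx / vr, -dx / vl)
      if (min(arr) <= tm[i]) next
    }
    act_p <- c(act_p, pos[i]); act_t <- c(act_t, tm[i])
  }
  o <- order(act_p)
  act_p <- act_p[o]; act_t <- act_t[o]
  k <- length(act_p)
  # meeting points between consecutive active origins
  if (k > 1) {
    i <- seq_len(k - 1)
    meet <- (act_t[i + 1] - act_t[i] + act_p[i] / vr + act_p[i + 1] / vl) /
      (1 / vr + 1 / vl)
    meet_t <- act_t[i] + (meet - act_p[i]) / vr
  } else {
    meet <- numeric(0); meet_t <- numeric(0)
  }
  # replication pieces: around each origin a rightward piece up to the next
  # meeting point and a leftward piece back to the previous one
  p_start <- c(-pad - 1, as.vector(rbind(act_p, c(meet, model$length + pad + 1))))
  p_start <- p_start[-length(p_start)]
  p_end <- c(p_start[-1], model$length + pad + 1)
  p_dir <- rep(c("L", "R"), k)[seq_along(p_start)]
  p_orig <- rep(seq_len(k), each = 2)[seq_along(p_start)]
  # pieces span the whole extended domain: fibre fragments may overhang the
  # locus, as combed molecules do
  pieces <- data.frame(start = p_start, end = p_end, dir = p_dir,
                       x0 = act_p[p_orig], t0 = act_t[p_orig])
  list(origins = data.frame(position = act_p, time = act_t),
       terminations = data.frame(position = meet, time = meet_t),
       pieces = pieces, v_right = vr, v_left = vl)
}

#' Simulate the replication of one cell
#'
#' Fires origins according to the model, propagates forks bidirectionally,
#' suppresses passively replicated origins, merges converging forks into
#' terminations and returns the per-position direction/timing map as
#' piecewise intervals, plus the realized initiation and termination
#' events.
#'
#' @param model an [locus_model()].
#' @param seed optional integer seed.
#' @return list with `origins` (position, time; includes the virtual
#'   boundary origins outside the locus), `terminations`, `pieces`
#'   (intervals `start,end,dir` with the source origin `x0,t0`, clipped to
#'   the locus) and the cell's velocities (bp/min).
#' @export
simulate_cell <- function(model, seed = NULL) {
  with_seed(seed, .sim_cell(model))
}

# replication time of position x on a piece
.piece_time <- function(piece, x, vr, vl) {
  ifelse(piece$dir == "R", piece$t0 + (x - piece$x0) / vr,
         piece$t0 + (piece$x0 - x) / vl)
}

#' Model RFD averaged over cells
#'
#' Estimates the model's expected RFD profile - the per-bin probability
#' balance of rightward versus leftward replication - by averaging the
#' exact per-cell direction maps of `n_cells` freshly simulated cells.
#' Within a cell every bp is replicated exactly once, so the per-bin
#' coverages sum to `n_cells x bin_size`.
#'
#' @param model an [locus_model()].
#' @param bin_size bin width in bp.
#' @param n_cells number of cells to average (default 2000).
#' @param seed integer seed.
#' @return an `rfd_profile` over `[0, model$length)`.
#' @export
analytic_rfd <- function(model, bin_size = 10000, n_cells = 2000,
                         seed = NULL) {
  bb <- bin_bounds(0, model$length, bin_size)
  r_cov <- numeric(bb$n); l_cov <- numeric(bb$n)
  with_seed(seed, {
    for (i in seq_len(n_cells)) {
      cell <- .sim_cell(model)
      p <- cell$pieces
      r <- p$dir == "R"
      r_cov <- r_cov + binned_bp(p$start[r], p$end[r], 0, model$length, bin_size)
      l_cov <- l_cov + binned_bp(p$start[!r], p$end[!r], 0, model$length, bin_size)
    }
  })
  tot <- r_cov + l_cov
  structure(
    data.frame(chrom = model$chrom, start = bb$start, end = bb$end,
               r_cov = r_cov, l_cov = l_cov,
               rfd = ifelse(tot > 0, (r_cov - l_cov) / tot, NA_real_)),
    class = c("rfd_profile", "data.frame"),
    bin_size = bin_size, locus_start = 0, locus_end = model$length,
    n_cells = n_cells)
}

# label intervals of one cell for a pulse window [w1, w2): the set of
# positions replicated during the window, as exact (unrounded) intervals
.label_intervals <- function(cell, w1, w2) {
  p <- cell$pieces
  vr <- cell$v_right; vl <- cell$v_left
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(p))) {
    if (p$dir[i] == "R") {
      # t increasing in x
      a <- p$x0[i] + (w1 - p$t0[i]) * vr
      b <- p$x0[i] + (w2 - p$t0[i]) * vr
    } else {
      # t decreasing in x
      a <- p$x0[i] - (w2 - p$t0[i]) * vl
      b <- p$x0[i] - (w1 - p$t0[i]) * vl
    }
    s <- max(a, p$start[i]); e <- min(b, p$end[i])
    if (e > s) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
  }
  o <- order(out_s)
  list(start = out_s[o], end = out_e[o])
}

# merge touching/overlapping intervals (same analog)
.merge_intervals <- function(s, e, tol = 1e-6) {
  if (length(s) <= 1) return(list(start = s, end = e))
  ms <- s[1]; me <- e[1]
  rs <- numeric(0); re <- numeric(0)
  for (i in 2:length(s)) {
    if (s[i] <= me + tol) me <- max(me, e[i])
    else { rs <- c(rs, ms); re <- c(re, me); ms <- s[i]; me <- e[i] }
  }
  list(start = c(rs, ms), end = c(re, me))
}

#' Emit pulse-labelled fibre fragments from the model
#'
#' Emulates a dual-pulse combing experiment on an asynchronous population:
#' for each fibre a fresh cell is simulated, a pulse onset is drawn
#' uniformly over S phase, IdU is laid on the DNA replicated during
#' `[t0, t0 + pulse)` and CldU during `[t0 + pulse, t0 + 2 pulse)`, and a
#' fibre fragment with lognormal length is cut out of the locus. Tracks
#' crossing a fragment end are clipped and flagged broken on that side;
#' DNA replicated before the pulses or not yet replicated at their end is
#' unlabelled. Fibres with no labelled track within the fragment are
#' returned with zero tracks. Track coordinates are rounded down to
#' integer bp.
#'
#' @param model an [locus_model()].
#' @param n_fibers number of fibre fragments.
#' @param pulse_min duration of each pulse in minutes (default 20).
#' @param fiber_mean_kb mean fragment length (default 95 kb, the scale of
#'   combed fibres in this kind of experiment).
#' @param fiber_sdlog lognormal sdlog of fragment lengths (default 0.35).
#' @param seed integer seed.
#' @param drop_empty drop fibres with no labelled track (default FALSE).
#' @return list with `fibers` (list of `rfd_fiber`) and `truth`
#'   (data.frame `fiber_id, kind, position, time` of all realized events
#'   inside each fragment, visible on the fibre or not).
#' @export
emit_fibers <- function(model, n_fibers, pulse_min = 20, fiber_mean_kb = 95,
                        fiber_sdlog = 0.35, seed = NULL, drop_empty = FALSE) {
  stopifnot(pulse_min > 0, n_fibers >= 0)
  meanlog <- log(fiber_mean_kb * 1000) - fiber_sdlog^2 / 2
  with_seed(seed, {
    fibers <- vector("list", n_fibers)
    truth <- vector("list", n_fibers)
    for (f in seq_len(n_fibers)) {
      cell <- .sim_cell(model)
      t0 <- runif(1, 0, model$s_duration)
      len <- min(max(rlnorm(1, meanlog, fiber_sdlog), 5000), model$length)
      # fragments land uniformly among those overlapping the locus and may
      # overhang its ends (combed fibres are not trimmed to the probed
      # window), so edge positions are sampled without bias
      fs <- floor(runif(1, -len, model$length))
      fe <- floor(fs + len)
      idu <- .label_intervals(cell, t0, t0 + pulse_min)
      cldu <- .label_intervals(cell, t0 + pulse_min, t0 + 2 * pulse_min)
      idu <- .merge_intervals(idu$start, idu$end)
      cldu <- .merge_intervals(cldu$start, cldu$end)
      lab <- data.frame(
        analog = c(rep("IdU", length(idu$start)),
                   rep("CldU", length(cldu$start))),
        start = c(idu$start, cldu$start), end = c(idu$end, cldu$end))
      # clip to the fragment, recording physical breaks
      lab$left_intact <- lab$start >= fs
      lab$right_intact <- lab$end <= fe
      lab$start <- floor(pmax(lab$start, fs))
      lab$end <- floor(pmin(lab$end, fe))
      lab <- lab[lab$end > lab$start, , drop = FALSE]
      lab <- lab[order(lab$start), , drop = FALSE]
      id <- sprintf("F%05d", f)
      fibers[[f]] <- new_fiber(id, model$chrom, fs, fe, lab)
      ini <- cell$origins$position >= fs & cell$origins$position < fe
      ter <- cell$terminations$position >= fs & cell$terminations$position < fe
      n_ev <- sum(ini) + sum(ter)
      if (n_ev > 0)
        truth[[f]] <- data.frame(
          fiber_id = id,
          kind = c(rep("initiation", sum(ini)), rep("termination", sum(ter))),
          position = floor(c(cell$origins$position[ini],
                             cell$terminations$position[ter])),
          time = c(cell$origins$time[ini], cell$terminations$time[ter]))
    }
    truth <- do.call(rbind, c(truth[!vapply(truth, is.null, TRUE)],
                              list(make.row.names = FALSE)))
    if (is.null(truth))
      truth <- data.frame(fiber_id = character(), kind = character(),
                          position = numeric(), time = numeric())
    if (drop_empty)
      fibers <- Filter(function(fb) nrow(fb$tracks) > 0, fibers)
    list(fibers = fibers, truth = truth)
  })
}

#' Emit strand-oriented reads from the model
#'
#' Emulates an Okazaki-fragment-style library: a pool of cells is
#' simulated, each read lands uniformly on the locus in a random cell, and
#' its direction is the direction of the fork that replicated the read's
#' midpoint in that cell.
#'
#' @param model an [locus_model()].
#' @param n_reads number of reads.
#' @param read_len read length in bp (default 150).
#' @param n_cells size of the simulated cell pool (default 500).
#' @param seed integer seed.
#' @return data.frame `chrom,start,end,direction`.
#' @export
emit_reads <- function(model, n_reads, read_len = 150, n_cells = 500,
                       seed = NULL) {
  stopifnot(n_reads >= 0, read_len > 0, n_cells > 0)
  if (n_reads == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character()))
  with_seed(seed, {
    cells <- lapply(seq_len(n_cells), function(i) .sim_cell(model))
    start <- floor(runif(n_reads, 0, model$length - read_len))
    cell_of <- sample.int(n_cells, n_reads, replace = TRUE)
    mid <- start + read_len / 2
    dir <- character(n_reads)
    for (ci in unique(cell_of)) {
      sel <- cell_of == ci
      p <- cells[[ci]]$pieces
      idx <- findInterval(mid[sel], p$start)
      idx[idx < 1] <- 1
      dir[sel] <- p$dir[idx]
    }
    data.frame(chrom = model$chrom, start = start, end = start + read_len,
               direction = dir)
  })
}
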