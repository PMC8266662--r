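#' Strand-resolved coverage and RFD over a locus
#'
#' Bins oriented replicated-DNA segments over `[locus_start, locus_end)` and
#' computes, per bin, the rightward (R) and leftward (L) replicated bp and
#' the replication fork directionality RFD = (R - L)/(R + L). RFD ranges from
#' -1 (all leftward) to +1 (all rightward); bins with zero total coverage are
#' undefined and carried as `NA`, never as 0. Binned RFD is the ratio of
#' summed coverages within the bin, not a mean of per-bp ratios.
#'
#' @param segments data.frame with columns `chrom,start,end,direction`
#'   ("R"/"L"), e.g. from [orient_fibers()].
#' @param chrom locus chromosome; segments on other chromosomes are ignored.
#' @param locus_start,locus_end locus bounds in bp (0-based, half-open).
#' @param bin_size bin width in bp (default 10 kb, the standard RFD window).
#' @return data.frame of class `rfd_profile` with columns
#'   `chrom,start,end,r_cov,l_cov,rfd` and attributes `bin_size`,
#'   `locus_start`, `locus_end`.
#' @export
rfd_profile <- function(segments, chrom, locus_start, locus_end,
                        bin_size = 10000) {
  stopifnot(bin_size > 0, locus_end > locus_start)
  seg <- segments[segments$chrom == chrom &
                    segments$end > locus_start & segments$start < locus_end, ,
                  drop = FALSE]
  r <- seg$direction == "R"
  r_cov <- binned_bp(seg$start[r], seg$end[r], locus_start, locus_end, bin_size)
  l_cov <- binned_bp(seg$start[!r], seg$end[!r], locus_start, locus_end, bin_size)
  tot <- r_cov + l_cov
  rfd <- ifelse(tot > 0, (r_cov - l_cov) / tot, NA_real_)
  bb <- bin_bounds(locus_start, locus_end, bin_size)
  structure(
    data.frame(chrom = chrom, start = bb$start, end = bb$end,
               r_cov = r_cov, l_cov = l_cov, rfd = rfd),
    class = c("rfd_profile", "data.frame"),
    bin_size = bin_size, locus_start = locus_start, locus_end = locus_end)
}

#' Origin efficiency metric from an RFD profile
#'
#' OEM at the boundary between two adjacent windows is the drop in the
#' normalised leftward coverage, Lfrac = L/(R + L), from the window on the
#' left to the window on the right: `oem(i) = Lfrac(i) - Lfrac(i+1)`.
#' Positive peaks mark efficient initiation (the leftward share falls across
#' an origin), negative troughs mark termination. Algebraically
#' `oem(i) = (rfd(i+1) - rfd(i))/2` wherever both windows are defined; a
#' boundary with an undefined flanking window is `NA`.
#'
#' @param profile an [rfd_profile()] binned at the OEM window size
#'   (10 kb in the standard analysis).
#' @return data.frame of class `rfd_oem` with columns `chrom,pos,oem`
#'   (`pos` is the inter-window boundary coordinate) and the profile's
#'   binning attributes. Fewer than two windows give an empty profile.
#' @export
oem_profile <- function(profile) {
  stopifnot(inherits(profile, "rfd_profile"))
  n <- nrow(profile)
  if (n < 2)
    return(structure(data.frame(chrom = character(), pos = numeric(),
                                oem = numeric()),
                     class = c("rfd_oem", "data.frame"),
                     bin_size = attr(profile, "bin_size"),
                     locus_start = attr(profile, "locus_start"),
                     locus_end = attr(profile, "locus_end")))
  tot <- profile$r_cov + profile$l_cov
  lfrac <- ifelse(tot > 0, profile$l_cov / tot, NA_real_)
  structure(
    data.frame(chrom = profile$chrom[-n], pos = profile$end[-n],
               oem = lfrac[-n] - lfrac[-1]),
    class = c("rfd_oem", "data.frame"),
    bin_size = attr(profile, "bin_size"),
    locus_start = attr(profile, "locus_start"),
    locus_end = attr(profile, "locus_end"))
}

#' Initiation-minus-termination density profile
#'
#' Counts initiation minus termination events in non-overlapping bins. The
#' (I - T) density is locally proportional to the RFD shift over a region,
#' so it tracks the OEM profile where events are abundant.
#'
#' @param events data.frame with columns `kind` ("initiation"/"termination"),
#'   `chrom`, `position`, e.g. from [orient_fibers()].
#' @inheritParams rfd_profile
#' @return data.frame of class `rfd_it` with columns
#'   `chrom,start,end,n_init,n_term,it`.
#' @export
it_profile <- function(events, chrom, locus_start, locus_end,
                       bin_size = 10000) {
  stopifnot(bin_size > 0, locus_end > locus_start)
  ev <- events[events$chrom == chrom & events$position >= locus_start &
                 events$position < locus_end, , drop = FALSE]
  bb <- bin_bounds(locus_start, locus_end, bin_size)
  idx <- floor((ev$position - locus_start) / bin_size) + 1
  n_init <- tabulate(idx[ev$kind == "initiation"], nbins = bb$n)
  n_term <- tabulate(idx[ev$kind == "termination"], nbins = bb$n)
  structure(
    data.frame(chrom = chrom, start = bb$start, end = bb$end,
               n_init = n_init, n_term = n_term, it = n_init - n_term),
    class = c("rfd_it", "data.frame"),
    bin_size = bin_size, locus_start = locus_start, locus_end = locus_end)
}

#' Call initiation and termination zones from an OEM profile
#'
#' Reports maximal runs of at least `min_run` consecutive window boundaries
#' whose OEM is at or above `threshold` as initiation zones (IZ: upward RFD
#' slope) and runs at or below `-threshold` as termination zones (TZ:
#' downward slope). Each zone is reported as the genomic interval from half
#' a window before its first qualifying boundary to half a window after its
#' last, clipped to the locus, so adjacent zones of opposite kind never
#' overlap; `center` is the mean of the run's boundary positions. Undefined
#' boundaries break runs.
#'
#' @param oem an [oem_profile()].
#' @param threshold minimum absolute OEM (default 0.1).
#' @param min_run minimum number of qualifying boundaries in a zone
#'   (default 1).
#' @param merge_gap maximum number of consecutive sub-threshold boundaries
#'   bridged between qualifying runs of the same kind (default 0: runs must
#'   be contiguous). Useful for sparse single-molecule OEM, where a broad
#'   zone can dip below threshold for one boundary by sampling noise.
#' @return data.frame with columns `kind` ("IZ"/"TZ"), `chrom`, `start`,
#'   `end`, `center`, `n_boundaries`, `peak_oem` (`center` is the mean of
#'   the qualifying boundary positions).
#' @export
call_zones <- function(oem, threshold = 0.1, min_run = 1, merge_gap = 0) {
  stopifnot(inherits(oem, "rfd_oem"), threshold > 0, min_run >= 1,
            merge_gap >= 0)
  bin <- attr(oem, "bin_size")
  lo <- attr(oem, "locus_start")
  hi <- attr(oem, "locus_end")
  empty <- data.frame(kind = character(), chrom = character(),
                      start = numeric(), end = numeric(), center = numeric(),
                      n_boundaries = integer(), peak_oem = numeric())
  if (nrow(oem) == 0) return(empty)
  state <- ifelse(is.na(oem$oem), 0L,
                  ifelse(oem$oem >= threshold, 1L,
                         ifelse(oem$oem <= -threshold, -1L, 0L)))
  r <- rle(state)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1
  # group qualifying runs of one sign, bridging <= merge_gap neutral
  # boundaries between runs of the same sign
  qual <- which(r$values != 0L)
  groups <- list()
  for (k in qual) {
    g <- length(groups)
    if (g > 0 && r$values[groups[[g]]$last_k] == r$values[k] &&
        starts[k] - stops[groups[[g]]$last_k] - 1 <= merge_gap) {
      groups[[g]]$runs <- c(groups[[g]]$runs, k)
      groups[[g]]$last_k <- k
    } else {
      groups[[g + 1]] <- list(runs = k, last_k = k)
    }
  }
  zones <- empty
  for (g in groups) {
    idx <- unlist(lapply(g$runs, function(k) starts[k]:stops[k]))
    if (length(idx) < min_run) next
    sgn <- r$values[g$runs[1]]
    zones <- rbind(zones, data.frame(
      kind = if (sgn > 0) "IZ" else "TZ",
      chrom = oem$chrom[idx[1]],
      start = max(lo, oem$pos[idx[1]] - bin / 2),
      end = min(hi, oem$pos[idx[length(idx)]] + bin / 2),
      center = mean(oem$pos[idx]),
      n_boundaries = length(idx),
      peak_oem = if (sgn > 0) max(oem$oem[idx]) else min(oem$oem[idx])))
  }
  rownames(zones) <- NULL
  zones
}
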