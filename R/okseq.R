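#' Population RFD from strand-oriented read intervals
#'
#' Computes the binned RFD profile of Okazaki-fragment-style data: reads
#' whose mapping strand gives the local fork direction. Under
#' `count_mode = "bp"` the rightward/leftward coverages are summed read-bp
#' per bin, consistent with the combing coverage definition; under
#' `"reads"` each read is counted once in the bin containing its midpoint.
#'
#' @param reads data.frame `chrom,start,end,direction` ("R"/"L"), e.g. from
#'   [read_reads_bed()] or [emit_reads()].
#' @inheritParams rfd_profile
#' @param count_mode `"bp"` (default) or `"reads"`.
#' @return an `rfd_profile` (see [rfd_profile()]).
#' @export
okseq_rfd <- function(reads, chrom, locus_start, locus_end, bin_size = 10000,
                      count_mode = c("bp", "reads")) {
  count_mode <- match.arg(count_mode)
  stopifnot(bin_size > 0, locus_end > locus_start)
  rd <- reads[reads$chrom == chrom & reads$end > locus_start &
                reads$start < locus_end, , drop = FALSE]
  bb <- bin_bounds(locus_start, locus_end, bin_size)
  r <- rd$direction == "R"
  if (count_mode == "bp") {
    r_cov <- binned_bp(rd$start[r], rd$end[r], locus_start, locus_end, bin_size)
    l_cov <- binned_bp(rd$start[!r], rd$end[!r], locus_start, locus_end, bin_size)
  } else {
    mid <- floor((rd$start + rd$end) / 2)
    keep <- mid >= locus_start & mid < locus_end
    idx <- floor((mid[keep] - locus_start) / bin_size) + 1
    r_cov <- tabulate(idx[r[keep]], nbins = bb$n)
    l_cov <- tabulate(idx[!r[keep]], nbins = bb$n)
  }
  tot <- r_cov + l_cov
  structure(
    data.frame(chrom = chrom, start = bb$start, end = bb$end,
               r_cov = r_cov, l_cov = l_cov,
               rfd = ifelse(tot > 0, (r_cov - l_cov) / tot, NA_real_)),
    class = c("rfd_profile", "data.frame"),
    bin_size = bin_size, locus_start = locus_start, locus_end = locus_end)
}

#' Subsample reads to single-molecule-like depth
#'
#' Draws `draws` independent subsamples of `n` reads (uniformly, without
#' replacement) from the reads overlapping the locus, and computes the
#' binned RFD profile of each draw. This emulates the sampling noise of a
#' single-molecule RFD profile assembled from a few hundred fibres, at
#' population-sequencing accuracy. All draws come from one stream seeded
#' with `seed`, taken sequentially, so a rerun with the same seed is
#' bit-identical.
#'
#' @inheritParams okseq_rfd
#' @param n reads per draw (default 2500).
#' @param draws number of draws (default 100).
#' @param seed integer seed (required).
#' @return object of class `rfd_subsample`: list with `profiles` (list of
#'   `rfd_profile`), `summary` (per-bin mean, sd, se, min, max of the draw
#'   RFDs and mean coverage) and the sampling parameters.
#' @export
subsample_rfd <- function(reads, chrom, locus_start, locus_end, n = 2500,
                          draws = 100, seed, bin_size = 10000,
                          count_mode = c("bp", "reads")) {
  count_mode <- match.arg(count_mode)
  if (missing(seed) || is.null(seed)) stopf("subsample_rfd: seed is required")
  rd <- reads[reads$chrom == chrom & reads$end > locus_start &
                reads$start < locus_end, , drop = FALSE]
  if (nrow(rd) < n)
    stopf("subsample_rfd: %d reads requested but only %d map on the locus",
          n, nrow(rd))
  profiles <- with_seed(seed, {
    lapply(seq_len(draws), function(d) {
      okseq_rfd(rd[sample.int(nrow(rd), n), , drop = FALSE],
                chrom, locus_start, locus_end, bin_size, count_mode)
    })
  })
  mat <- vapply(profiles, function(p) p$rfd, numeric(nrow(profiles[[1]])))
  mat <- matrix(mat, ncol = draws)
  cov_mat <- vapply(profiles, function(p) p$r_cov + p$l_cov,
                    numeric(nrow(profiles[[1]])))
  sd_v <- apply(mat, 1, stats::sd, na.rm = TRUE)
  smry <- data.frame(
    chrom = profiles[[1]]$chrom, start = profiles[[1]]$start,
    end = profiles[[1]]$end,
    mean = rowMeans(mat, na.rm = TRUE),
    sd = sd_v, se = sd_v / sqrt(draws),
    min = suppressWarnings(apply(mat, 1, min, na.rm = TRUE)),
    max = suppressWarnings(apply(mat, 1, max, na.rm = TRUE)),
    n_defined = rowSums(!is.na(mat)),
    mean_cov = rowMeans(matrix(cov_mat, ncol = draws)))
  smry$min[!is.finite(smry$min)] <- NA_real_
  smry$max[!is.finite(smry$max)] <- NA_real_
  structure(list(profiles = profiles, summary = smry, n = n, draws = draws,
                 seed = seed, bin_size = bin_size, count_mode = count_mode),
            class = "rfd_subsample")
}

#' @export
print.rfd_subsample <- function(x, ...) {
  cat(sprintf("<rfd_subsample> %d draws of %d reads, %d bins (seed %s)\n",
              x$draws, x$n, nrow(x$summary), format(x$seed)))
  invisible(x)
}

#' Write a subsampling ensemble to disk
#'
#' One bedGraph per draw plus a per-bin summary TSV (mean, sd, se, min,
#' max).
#'
#' @param ens an [subsample_rfd()] ensemble.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return `dir`, invisibly.
#' @export
write_subsample <- function(ens, dir, prefix = "subsample") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in seq_along(ens$profiles))
    write_bedgraph(ens$profiles[[d]],
                   file.path(dir, sprintf("%s_draw%03d.bedGraph", prefix, d)))
  write.table(ens$summary, file.path(dir, paste0(prefix, "_summary.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Spearman correlation between two binned profiles
#'
#' Rank correlation over the bins where both profiles are defined, with tied
#' ranks mid-ranked (the default of [stats::cor()] for
#' `method = "spearman"`). The two profiles must share the locus and the
#' binning.
#'
#' @param a,b `rfd_profile` objects (or anything with an `rfd` column and
#'   matching `start`).
#' @return the correlation coefficient rho.
#' @export
binned_spearman <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$start != b$start))
    stopf("binned_spearman: profiles have different loci or binning")
  ok <- !is.na(a$rfd) & !is.na(b$rfd)
  if (sum(ok) < 3)
    stopf("binned_spearman: only %d bins defined in both profiles (>= 3 needed)",
          sum(ok))
  stats::cor(a$rfd[ok], b$rfd[ok], method = "spearman")
}
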