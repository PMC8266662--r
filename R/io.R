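#' Export oriented segments as BED6
#'
#' Writes one BED record per oriented segment with the fibre id as name and
#' strand `+` for rightward, `-` for leftward replication.
#'
#' @param segments data.frame from [orient_fibers()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  gr <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(start = segments$start + 1, end = segments$end),
    strand = ifelse(segments$direction == "R", "+", "-"))
  gr$name <- segments$fiber_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export replication events as 1-bp BED
#'
#' @param events data.frame from [orient_fibers()]; `kind` becomes the BED
#'   name.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(events, path) {
  gr <- GenomicRanges::GRanges(
    events$chrom,
    IRanges::IRanges(start = events$position + 1, width = 1))
  gr$name <- events$kind
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# pull a (chrom, start, end, value) table out of the profile classes
.profile_values <- function(x) {
  if (inherits(x, "rfd_profile"))
    data.frame(chrom = x$chrom, start = x$start, end = x$end, value = x$rfd)
  else if (inherits(x, "rfd_oem"))
    data.frame(chrom = x$chrom, start = x$pos, end = x$pos + 1, value = x$oem)
  else if (inherits(x, "rfd_it"))
    data.frame(chrom = x$chrom, start = x$start, end = x$end, value = x$it)
  else stopf("cannot export object of class %s", paste(class(x), collapse = "/"))
}

#' Export a profile as bedGraph
#'
#' RFD, OEM and (I - T) profiles all export to 4-column bedGraph. Undefined
#' bins are omitted, not written as zero.
#'
#' @param x an `rfd_profile`, `rfd_oem` or `rfd_it` object.
#' @param path output bedGraph path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  v <- .profile_values(x)
  v <- v[!is.na(v$value), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    v$chrom, IRanges::IRanges(start = v$start + 1, end = v$end),
    score = v$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Export a profile as bigWig
#'
#' Requires chromosome sizes, since the bigWig container indexes against the
#' assembly.
#'
#' @inheritParams write_bedgraph
#' @param chrom_sizes named numeric vector of chromosome lengths, or path to
#'   a two-column `chrom<TAB>size` file.
#' @return `path`, invisibly.
#' @export
write_bigwig <- function(x, path, chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    cs <- read.delim(chrom_sizes, header = FALSE)
    chrom_sizes <- stats::setNames(cs[[2]], cs[[1]])
  }
  v <- .profile_values(x)
  v <- v[!is.na(v$value), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    v$chrom, IRanges::IRanges(start = v$start + 1, end = v$end),
    score = v$value,
    seqinfo = GenomeInfoDb::Seqinfo(names(chrom_sizes),
                                    as.integer(chrom_sizes)))
  rtracklayer::export(gr, path, format = "BigWig")
  invisible(path)
}

#' Read a bedGraph written by this package
#'
#' @param path bedGraph path.
#' @return data.frame `chrom,start,end,value` (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             value = gr$score)
}

#' Read strand-oriented read intervals from BED
#'
#' Each record is one read interval whose fork direction derives from the
#' mapping strand. Under `convention = "direct"` the strand is the fork
#' direction itself (`+` = rightward), which is how [write_reads_bed()]
#' stores simulated reads. Under `convention = "okseq"` the strand is the
#' Okazaki-fragment mapping strand: fragments mapping to the forward strand
#' are synthesised by leftward-moving forks, so `+` = leftward. The flag is
#' explicit because files in the wild use either.
#'
#' @param path BED path (6 columns; strand required).
#' @param convention `"direct"` or `"okseq"`.
#' @return data.frame `chrom,start,end,direction` ("R"/"L").
#' @export
read_reads_bed <- function(path, convention = c("direct", "okseq")) {
  convention <- match.arg(convention)
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stopf("%s: strand column required for oriented reads", path)
  plus_is <- if (convention == "direct") "R" else "L"
  minus_is <- if (convention == "direct") "L" else "R"
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             direction = ifelse(strand == "+", plus_is, minus_is))
}

#' Write oriented reads as BED6
#'
#' Strand records the fork direction directly (`+` = rightward); see
#' [read_reads_bed()].
#'
#' @param reads data.frame `chrom,start,end,direction`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  gr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(start = reads$start + 1, end = reads$end),
    strand = ifelse(reads$direction == "R", "+", "-"))
  gr$name <- "."
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read strand-oriented reads from BAM
#'
#' Thin converter for aligned Okazaki-fragment libraries. Mapping strand is
#' translated to fork direction under the stated convention (see
#' [read_reads_bed()]); the default `"okseq"` matches Okazaki-fragment
#' chemistry. Requires the Rsamtools package.
#'
#' @param path BAM path.
#' @param convention `"okseq"` or `"direct"`.
#' @return data.frame `chrom,start,end,direction`.
#' @export
read_reads_bam <- function(path, convention = c("okseq", "direct")) {
  convention <- match.arg(convention)
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stopf("reading BAM requires the Rsamtools package")
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "qwidth", "strand"),
                               flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  strand <- as.character(b$strand)
  plus_is <- if (convention == "direct") "R" else "L"
  minus_is <- if (convention == "direct") "L" else "R"
  data.frame(chrom = as.character(b$rname),
             start = b$pos - 1, end = b$pos - 1 + b$qwidth,
             direction = ifelse(strand == "+", plus_is, minus_is))
}
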