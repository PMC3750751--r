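#' Genomic coordinate conventions and fixed-size binning
#'
#' All coordinates inside the package are 1-based and inclusive at both ends,
#' the convention in which published coordinates at the NF1 locus are printed.
#' A genome bin of size `bin_size` and index `i` covers positions
#' `i * bin_size` to `(i + 1) * bin_size - 1`, so the 1-Mb bin with index 29
#' on chr17 covers exactly 29,000,000-29,999,999. Intervals are passed around
#' as [GenomicRanges::GRanges] objects (which share the 1-based inclusive
#' convention); on-disk BED and bedGraph files are 0-based half-open and are
#' converted on read/write by rtracklayer.
#'
#' @name genome-binning
NULL

#' Construct a genomic interval
#'
#' Convenience constructor for a validated single interval as a `GRanges`.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive positions; `start >= 1`, `end >= start`.
#' @param strand Strand, one of `"+"`, `"-"`, `"*"`.
#' @return A length-one [GenomicRanges::GRanges].
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  if (any(start < 1) || any(end < start)) {
    input_error(sprintf(
      "invalid interval %s:%s-%s (need start >= 1 and end >= start)",
      chrom[1], start[1], end[1]
    ))
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

#' Bin containing a genomic position
#'
#' Maps positions to fixed-size genome bins, `index = floor(pos / bin_size)`.
#' Vectorised over `chrom` and `pos`.
#'
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s), `>= 1`.
#' @param bin_size Bin size in bp (default 1 Mb, the resolution of published
#'   genome-wide contact maps).
#' @return A data frame with columns `chrom`, `index`, `bin_size`.
#' @examples
#' bin_of_position("chr17", 29421945)  # NF1 start -> bin 29
#' @export
bin_of_position <- function(chrom, pos, bin_size = 1e6) {
  if (length(bin_size) != 1 || bin_size < 1) {
    input_error("bin_size must be a single value >= 1")
  }
  if (any(pos < 1)) input_error("positions must be >= 1")
  data.frame(
    chrom = as.character(chrom),
    index = floor(pos / bin_size),
    bin_size = bin_size,
    stringsAsFactors = FALSE
  )
}

#' Interval covered by genome bins
#'
#' @param bins A bin data frame as returned by [bin_of_position()].
#' @return A [GenomicRanges::GRanges] of the covered intervals.
#' @export
bin_interval <- function(bins) {
  GenomicRanges::GRanges(
    bins$chrom,
    IRanges::IRanges(
      start = bins$index * bins$bin_size,
      end = (bins$index + 1) * bins$bin_size - 1
    )
  )
}

#' Bins overlapping an interval
#'
#' @param iv A length-one `GRanges` (or anything [genomic_interval()] built).
#' @param bin_size Bin size in bp.
#' @return A data frame of consecutive bins sorted by index, each overlapping
#'   `iv`.
#' @export
bins_overlapping_interval <- function(iv, bin_size = 1e6) {
  if (length(iv) != 1) input_error("iv must be a single interval")
  s <- GenomicRanges::start(iv)
  e <- GenomicRanges::end(iv)
  if (s < 1 || e < s) input_error("invalid interval")
  idx <- seq(floor(s / bin_size), floor(e / bin_size))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(iv)),
    index = idx,
    bin_size = bin_size,
    stringsAsFactors = FALSE
  )
}

#' Strand-aware upstream distance from a region to a gene start
#'
#' For a plus-strand gene and a region lying entirely 5' of it the distance is
#' `start(gene) - end(region)` (positive); a region that abuts or overlaps the
#' gene start yields 0. On the minus strand "upstream" means higher
#' coordinates and the arithmetic is mirrored. Distances are reported
#' downstream of this function rounded to the nearest kb for display.
#'
#' @param gene A length-one `GRanges` with strand (see [read_gene_bed()]).
#' @param region A length-one `GRanges`.
#' @return Distance in bp (non-negative).
#' @export
upstream_distance <- function(gene, region) {
  check_same_chrom(gene, region)
  d <- if (as.character(GenomicRanges::strand(gene)) == "-") {
    GenomicRanges::start(region) - GenomicRanges::end(gene)
  } else {
    GenomicRanges::start(gene) - GenomicRanges::end(region)
  }
  max(0, d)
}

#' Signed gene-relative distance of a region
#'
#' Positive for regions upstream of the gene, negative for regions downstream
#' of it, 0 for regions overlapping the gene body. Used to annotate distal
#' candidates; trans (other-chromosome) candidates have no defined distance.
#'
#' @inheritParams upstream_distance
#' @return Signed distance in bp.
#' @export
gene_distance <- function(gene, region) {
  check_same_chrom(gene, region)
  minus <- as.character(GenomicRanges::strand(gene)) == "-"
  gs <- GenomicRanges::start(gene)
  ge <- GenomicRanges::end(gene)
  rs <- GenomicRanges::start(region)
  re <- GenomicRanges::end(region)
  if (re < gs) {
    d <- gs - re          # region at lower coordinates
    if (minus) -d else d
  } else if (rs > ge) {
    d <- rs - ge          # region at higher coordinates
    if (minus) d else -d
  } else {
    0
  }
}

check_same_chrom <- function(gene, region) {
  gc <- as.character(GenomicRanges::seqnames(gene))
  rc <- as.character(GenomicRanges::seqnames(region))
  if (!identical(gc, rc)) {
    rs_stop(
      sprintf("gene (%s) and region (%s) lie on different chromosomes", gc, rc),
      c("regscout_incompatible_coordinates", "regscout_input_error")
    )
  }
  invisible(TRUE)
}

#' Read a gene annotation from a BED6 file
#'
#' The on-disk BED is 0-based half-open; rtracklayer converts to the internal
#' 1-based inclusive convention on import.
#'
#' @param path Path to a BED6 file with one record per gene.
#' @return A `GRanges` with `name` metadata and strand set.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) input_error(sprintf("gene BED not found: %s", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) parse_error(sprintf("failed to parse BED %s: %s", path, conditionMessage(e)))
  )
  if (length(gr) == 0) parse_error(sprintf("no gene records in %s", path))
  gr
}
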