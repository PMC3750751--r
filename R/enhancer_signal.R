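#' Enhancer-mark signal tracks
#'
#' Signal (e.g. H3K27ac ChIP-seq enrichment) is modelled as a
#' piecewise-constant track: sorted, non-overlapping intervals each carrying
#' a non-negative value, with implicit value 0 everywhere else. Tracks are
#' held as [GenomicRanges::GRanges] with a `score` column; bedGraph files
#' (0-based half-open on disk) are converted by rtracklayer on read/write.
#'
#' @name enhancer-signal
NULL

#' Construct and validate a signal track
#'
#' @param gr A `GRanges` with a numeric `score` metadata column.
#' @param track_label Name of the track (mark + cell context).
#' @return The sorted, validated `GRanges`.
#' @export
signal_track <- function(gr, track_label = "signal") {
  if (!"score" %in% names(S4Vectors::mcols(gr))) input_error("track needs a 'score' column")
  if (length(gr) && any(S4Vectors::mcols(gr)$score < 0)) {
    input_error("signal values must be >= 0")
  }
  gr <- GenomicRanges::sort(gr)
  if (!IRanges::isDisjoint(gr)) input_error("signal intervals must not overlap")
  S4Vectors::metadata(gr)$track_label <- track_label
  gr
}

#' Read a bedGraph signal track
#'
#' @param path Path to a 4-column bedGraph file.
#' @param track_label Track name; defaults to the file name.
#' @return A validated signal-track `GRanges` (1-based inclusive).
#' @export
read_bedgraph <- function(path, track_label = basename(path)) {
  if (!file.exists(path)) input_error(sprintf("bedGraph not found: %s", path))
  lines <- readLines(path)
  body <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$score <- numeric(0)
    return(signal_track(gr, track_label))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) parse_error(sprintf("failed to parse bedGraph %s: %s", path, conditionMessage(e)))
  )
  if (any(S4Vectors::mcols(gr)$score < 0)) {
    parse_error(sprintf("%s: negative signal value", path))
  }
  if (!IRanges::isDisjoint(gr)) {
    parse_error(sprintf("%s: overlapping signal intervals", path))
  }
  signal_track(gr, track_label)
}

#' Write a signal track as bedGraph
#'
#' @param track A signal-track `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  tryCatch(
    rtracklayer::export(GenomicRanges::sort(track), path, format = "bedGraph"),
    error = function(e) input_error(sprintf("cannot write %s: %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Highest-enrichment region within a query interval
#'
#' Operationalises "the relatively short region with the highest enrichment"
#' inside a query window: let `M` be the maximum signal in the query; take
#' all positions with signal `>= frac * M`, merge runs separated by at most
#' `max_gap` bp, discard merged runs shorter than `min_width` bp, and return
#' the surviving run that contains the (leftmost) position where `M` is
#' attained. Returns `NULL` when the query has no positive signal or the
#' maximal run is discarded.
#'
#' @param track A signal-track `GRanges`.
#' @param query A length-one `GRanges` to search within.
#' @param frac Fraction of the query maximum used as threshold, in (0, 1].
#' @param max_gap Maximum gap (bp) bridged when merging above-threshold runs.
#' @param min_width Minimum width (bp) of a surviving run.
#' @return One-row data frame with `chrom`, `start`, `end`, `peak_height`
#'   (= `M`), `area` (sum of value times covered length inside the region),
#'   or `NULL`.
#' @export
highest_enrichment_region <- function(track, query, frac = 0.5, max_gap = 200,
                                      min_width = 100) {
  if (frac <= 0 || frac > 1) input_error("frac must be in (0, 1]")
  if (max_gap < 0) input_error("max_gap must be >= 0")
  if (min_width < 1) input_error("min_width must be >= 1")
  if (length(query) != 1) input_error("query must be a single interval")

  hits <- GenomicRanges::findOverlaps(track, query)
  if (length(hits) == 0) return(NULL)
  seg <- IRanges::pintersect(track[S4Vectors::queryHits(hits)],
                             rep(query, length(hits)))
  val <- S4Vectors::mcols(seg)$score
  M <- max(val)
  if (M <= 0) return(NULL)

  above <- seg[val >= frac * M]
  runs <- GenomicRanges::reduce(above, min.gapwidth = max_gap + 1)
  runs <- runs[GenomicRanges::width(runs) >= min_width]
  if (length(runs) == 0) return(NULL)
  argmax <- min(GenomicRanges::start(seg)[val == M])  # leftmost maximal position
  inrun <- GenomicRanges::start(runs) <= argmax & GenomicRanges::end(runs) >= argmax
  if (!any(inrun)) return(NULL)
  run <- runs[which(inrun)[1]]

  cov_hits <- GenomicRanges::findOverlaps(seg, run)
  cov <- IRanges::pintersect(seg[S4Vectors::queryHits(cov_hits)],
                             rep(run, length(cov_hits)))
  area <- sum(S4Vectors::mcols(cov)$score * GenomicRanges::width(cov))

  data.frame(
    chrom = as.character(GenomicRanges::seqnames(run)),
    start = GenomicRanges::start(run),
    end = GenomicRanges::end(run),
    peak_height = M,
    area = area,
    stringsAsFactors = FALSE
  )
}

#' Order enrichment regions by peak height
#'
#' Stable descending sort by `peak_height`; ties keep input order.
#'
#' @param regions Data frame of enrichment regions (rows as returned by
#'   [highest_enrichment_region()]).
#' @return The reordered data frame.
#' @export
compare_peak_heights <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0) input_error("no regions to compare")
  out <- regions[order(-regions$peak_height), , drop = FALSE]
  rownames(out) <- NULL
  out
}
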