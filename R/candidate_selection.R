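#' Nominate candidate regulatory regions for a gene
#'
#' Orchestrates the prioritisation: the anchor is the bin containing the gene
#' midpoint; partner bins are the consensus of each contact map's top-`top_k`
#' partners of the anchor (see [consensus_top_partners()]), optionally plus
#' the anchor bin itself (the gene-containing fragment is itself screened for
#' a proximal enhancer); within each selected bin the highest-enrichment
#' region is located with [highest_enrichment_region()]; bins without
#' positive signal are dropped. Candidates are returned ordered by peak
#' height descending.
#'
#' @param maps List of `contact_map` objects (one per enzyme experiment),
#'   all at the same bin size.
#' @param gene Length-one `GRanges` gene annotation with `name` and strand.
#' @param track Signal-track `GRanges`.
#' @param scope Partner scope passed to [rank_partners()]: `"intra"`
#'   (default), `"inter"`, or `"all"`.
#' @param top_k Depth of each map's partner list entering the consensus;
#'   `top_k = 0` with `include_anchor_bin = TRUE` degenerates to an enhancer
#'   scan of the gene's own bin.
#' @param include_anchor_bin Also scan the gene-containing bin (default TRUE).
#' @param frac,max_gap,min_width Peak-calling parameters, see
#'   [highest_enrichment_region()].
#' @return Data frame of class `candidate_regions`: one row per candidate
#'   with the region coordinates, `peak_height`, `area`, source bin,
#'   `locality` (`proximal` = anchor bin, `distal` = same chromosome,
#'   `trans` = other chromosome), signed `distance_to_gene` (bp; NA for
#'   trans), and one `count_<enzyme>` column per map giving the bin's
#'   interaction count with the anchor.
#' @export
select_candidates <- function(maps, gene, track, scope = "intra", top_k = 1,
                              include_anchor_bin = TRUE, frac = 0.5,
                              max_gap = 200, min_width = 100) {
  if (length(maps) && length(unique(vapply(maps, `[[`, 0, "bin_size"))) > 1) {
    input_error("all contact maps must share a bin size")
  }
  bin_size <- if (length(maps)) maps[[1]]$bin_size else 1e6
  gchrom <- as.character(GenomicRanges::seqnames(gene))
  midpoint <- floor((GenomicRanges::start(gene) + GenomicRanges::end(gene)) / 2)
  anchor <- bin_of_position(gchrom, midpoint, bin_size)

  bins <- data.frame(chrom = character(), index = integer(), stringsAsFactors = FALSE)
  if (length(maps) && top_k >= 1) {
    rankings <- lapply(maps, rank_partners, anchor = anchor, scope = scope, top_k = top_k)
    bins <- consensus_top_partners(rankings, k = top_k)[c("chrom", "index")]
  }
  if (include_anchor_bin) {
    bins <- rbind(bins, anchor[c("chrom", "index")])
    bins <- bins[!duplicated(bins), , drop = FALSE]
  }
  labels <- vapply(maps, `[[`, "", "enzyme_label")
  empty <- candidate_skeleton(labels)
  if (nrow(bins) == 0) return(empty)

  rows <- lapply(seq_len(nrow(bins)), function(i) {
    b <- data.frame(chrom = bins$chrom[i], index = bins$index[i],
                    bin_size = bin_size, stringsAsFactors = FALSE)
    region <- highest_enrichment_region(track, bin_interval(b), frac = frac,
                                        max_gap = max_gap, min_width = min_width)
    if (is.null(region)) return(NULL)
    is_anchor <- b$chrom == anchor$chrom && b$index == anchor$index
    locality <- if (b$chrom != gchrom) "trans" else if (is_anchor) "proximal" else "distal"
    dist <- if (locality == "trans") {
      NA_real_
    } else if (locality == "proximal") {
      0
    } else {
      gene_distance(gene, genomic_interval(region$chrom, region$start, region$end))
    }
    counts <- vapply(maps, contact_count, 0,
                     chromA = anchor$chrom, binA = anchor$index,
                     chromB = b$chrom, binB = b$index)
    out <- data.frame(
      label = sprintf("%s_bin%d_%d_%d", region$chrom, b$index, region$start, region$end),
      chrom = region$chrom, start = region$start, end = region$end,
      peak_height = region$peak_height, area = region$area,
      source_chrom = b$chrom, source_index = b$index,
      locality = locality, distance_to_gene = dist,
      stringsAsFactors = FALSE
    )
    for (j in seq_along(labels)) out[[paste0("count_", labels[j])]] <- counts[j]
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  cand <- do.call(rbind, rows)
  cand <- cand[order(-cand$peak_height), , drop = FALSE]
  rownames(cand) <- NULL
  class(cand) <- c("candidate_regions", "data.frame")
  cand
}

candidate_skeleton <- function(enzyme_labels) {
  out <- data.frame(
    label = character(), chrom = character(), start = integer(), end = integer(),
    peak_height = numeric(), area = numeric(),
    source_chrom = character(), source_index = integer(),
    locality = character(), distance_to_gene = numeric(),
    stringsAsFactors = FALSE
  )
  for (l in enzyme_labels) out[[paste0("count_", l)]] <- numeric()
  class(out) <- c("candidate_regions", "data.frame")
  out
}

#' Export candidate regions as a BED6 sequencing-target file
#'
#' One row per candidate in input order: name = candidate label, score =
#' peak height clamped to \[0, 1000\]. The on-disk BED is 0-based half-open;
#' re-importing reproduces the intervals exactly.
#'
#' @param candidates A `candidate_regions` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_targets <- function(candidates, path) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    input_error("no candidate regions to export")
  }
  gr <- GenomicRanges::GRanges(
    candidates$chrom,
    IRanges::IRanges(candidates$start, candidates$end),
    strand = "*",
    name = candidates$label,
    score = pmin(pmax(round(candidates$peak_height), 0), 1000)
  )
  tryCatch(rtracklayer::export(gr, path, format = "bed"),
           error = function(e) input_error(sprintf("cannot write %s: %s", path, conditionMessage(e))))
  invisible(path)
}

#' Read a sequencing-target BED back as candidate intervals
#'
#' Companion to [export_targets()], used by the variant-screening stage when
#' driven from files.
#'
#' @param path BED file path.
#' @return Data frame with `label`, `chrom`, `start`, `end`, `peak_height`.
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) input_error(sprintf("targets BED not found: %s", path))
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) parse_error(sprintf("failed to parse BED %s: %s", path, conditionMessage(e))))
  data.frame(
    label = if ("name" %in% names(S4Vectors::mcols(gr))) S4Vectors::mcols(gr)$name
            else sprintf("region_%d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    peak_height = if ("score" %in% names(S4Vectors::mcols(gr))) S4Vectors::mcols(gr)$score
                  else NA_real_,
    stringsAsFactors = FALSE
  )
}
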