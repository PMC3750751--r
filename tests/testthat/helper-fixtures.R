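suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Build the NF1 worked-example fixture once per test run.
nf1_fixture_paths <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_nf1_fixture()
    cache
  }
})

nf1_gene <- function() read_gene_bed(nf1_fixture_paths()[["gene"]])[1]
nf1_anchor <- function() bin_of_position("chr17", 29421945, 1e6)

# --- random input generators (seeded by the caller) -------------------------

random_contact_entries <- function(n_chrom = 2, n_bins = 6, n_pairs = 10,
                                   max_count = 50) {
  chroms <- paste0("c", seq_len(n_chrom))
  all_pairs <- expand.grid(
    chromA = chroms, binA = seq_len(n_bins) - 1L,
    chromB = chroms, binB = seq_len(n_bins) - 1L,
    stringsAsFactors = FALSE
  )
  keep <- all_pairs$chromA < all_pairs$chromB |
    (all_pairs$chromA == all_pairs$chromB & all_pairs$binA < all_pairs$binB)
  all_pairs <- all_pairs[keep, ]
  picked <- all_pairs[sample(nrow(all_pairs), min(n_pairs, nrow(all_pairs))), ]
  picked$count <- sample(0:max_count, nrow(picked), replace = TRUE)
  rownames(picked) <- NULL
  picked
}

random_contact_map <- function(...) {
  contact_map(random_contact_entries(...), enzyme_label = "rand", bin_size = 10)
}

# Random sorted non-overlapping track over small coordinates (1..span).
random_track <- function(n_intervals = 10, span = 2000, max_value = 10) {
  cuts <- sort(sample(seq_len(span - 1), 2 * n_intervals))
  starts <- cuts[seq(1, length(cuts), by = 2)]
  ends <- cuts[seq(2, length(cuts), by = 2)]
  keep <- ends >= starts
  gr <- GenomicRanges::GRanges(
    "cS", IRanges::IRanges(starts[keep], ends[keep]),
    score = round(stats::runif(sum(keep), 0, max_value), 3)
  )
  signal_track(gr, "random")
}

# --- independent oracles ----------------------------------------------------

# Exhaustive sort of all anchor-touching pairs.
oracle_rank <- function(map, anchor, scope) {
  e <- map$entries
  rows <- list()
  for (i in seq_len(nrow(e))) {
    for (side in 1:2) {
      a <- if (side == 1) c(e$chromA[i], e$binA[i]) else c(e$chromB[i], e$binB[i])
      b <- if (side == 1) c(e$chromB[i], e$binB[i]) else c(e$chromA[i], e$binA[i])
      if (a[1] == anchor$chrom && as.integer(a[2]) == anchor$index &&
          !(b[1] == anchor$chrom && as.integer(b[2]) == anchor$index)) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = b[1], index = as.integer(b[2]), count = e$count[i],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(chrom = character(), index = integer(), count = numeric())
  out <- switch(scope,
    intra = out[out$chrom == anchor$chrom, ],
    inter = out[out$chrom != anchor$chrom, ],
    all = out
  )
  out <- out[order(-out$count, out$chrom, out$index), ]
  rownames(out) <- NULL
  out
}

# Position-by-position scan for the highest-enrichment run.
# Works on plain data frames to stay independent of GRanges dispatch.
oracle_peak <- function(track, query, frac, max_gap, min_width) {
  tdf <- as.data.frame(track)
  qdf <- as.data.frame(query)
  qs <- qdf$start; qe <- qdf$end
  vals <- numeric(qe - qs + 1)
  tq <- tdf[as.character(tdf$seqnames) == as.character(qdf$seqnames), ]
  for (i in seq_len(nrow(tq))) {
    s <- max(tq$start[i], qs); e <- min(tq$end[i], qe)
    if (s <= e) vals[(s - qs + 1):(e - qs + 1)] <- tq$score[i]
  }
  M <- max(vals)
  if (M <= 0) return(NULL)
  above <- which(vals >= frac * M)
  if (!length(above)) return(NULL)
  gap_break <- c(TRUE, diff(above) > max_gap + 1)
  run_id <- cumsum(gap_break)
  runs <- do.call(rbind, lapply(split(above, run_id), function(p) {
    data.frame(start = min(p) + qs - 1, end = max(p) + qs - 1)
  }))
  runs <- runs[runs$end - runs$start + 1 >= min_width, , drop = FALSE]
  if (!nrow(runs)) return(NULL)
  argmax <- min(which(vals == M)) + qs - 1
  hit <- which(runs$start <= argmax & runs$end >= argmax)
  if (!length(hit)) return(NULL)
  run <- runs[hit[1], ]
  area <- sum(vals[(run$start - qs + 1):(run$end - qs + 1)])
  data.frame(chrom = as.character(qdf$seqnames), start = run$start,
             end = run$end, peak_height = M, area = area)
}

# Brute-force variant-to-region assignment.
oracle_screen_assignment <- function(variants, candidates) {
  rows <- list()
  for (v in seq_len(nrow(variants))) {
    for (r in seq_len(nrow(candidates))) {
      if (variants$chrom[v] == candidates$chrom[r] &&
          variants$pos[v] >= candidates$start[r] &&
          variants$pos[v] <= candidates$end[r]) {
        rows[[length(rows) + 1]] <- cbind(variants[v, , drop = FALSE],
                                          region_label = candidates$label[r])
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

random_cohort <- function(n_variants = 30, n_patients = 10, span = 1000) {
  df <- data.frame(
    patient_id = sprintf("P%02d", sample(n_patients, n_variants, replace = TRUE)),
    chrom = sample(c("c1", "c2"), n_variants, replace = TRUE),
    pos = sample(span, n_variants, replace = TRUE),
    ref = "A", alt = sample(c("C", "G", "T"), n_variants, replace = TRUE),
    zygosity = "het", stringsAsFactors = FALSE
  )
  df <- df[!duplicated(df[c("patient_id", "chrom", "pos", "ref", "alt")]), ]
  attr(df, "cohort_size") <- n_patients
  df
}

random_regions <- function(n = 3, span = 1000) {
  starts <- sample(span - 100, n)
  data.frame(
    label = sprintf("R%d", seq_len(n)),
    chrom = sample(c("c1", "c2"), n, replace = TRUE),
    start = starts, end = pmin(starts + sample(20:120, n, replace = TRUE), span),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain data.frame view of a partner_ranking (drops ranking metadata attrs)
ranking_df <- function(r) {
  data.frame(chrom = r$chrom, index = r$index, count = r$count,
             stringsAsFactors = FALSE)
}
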