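#' Simulation configuration
#'
#' One configuration object drives all three generators so a study condition
#' is stated in a single place and every generator is a pure function of it
#' (seed included).
#'
#' Contact maps: the expected count of two bins at distance `d` on the same
#' chromosome is `base_count * d^-decay_exponent` (the classic approximate
#' power-law decay of intra-chromosomal contact frequency, exponent 1 by
#' default), multiplied for planted pairs; inter-chromosomal pairs have a
#' constant expected background. Realised counts are Poisson.
#'
#' Signal tracks: sparse background segments of width `bg_segment_width`
#' spaced `bg_segment_spacing` bp apart with Exponential heights (mean
#' `signal_background`), plus planted rectangular plateaus which override the
#' background. The sparse spacing emulates the punctate character of
#' acetylation peaks over a quiet baseline.
#'
#' Cohorts: exactly the planted variants with exactly the planted carriers,
#' plus optional uniform background variants (per-patient Poisson rate) drawn
#' inside `background_region` but outside `background_exclude`.
#'
#' @param seed Integer RNG seed.
#' @param bin_size Bin size in bp.
#' @param n_bins Named integer vector: number of bins per chromosome.
#' @param decay_exponent Power-law exponent of contact decay (> 0).
#' @param base_count Expected intra-chromosomal count at distance 1 (> 0).
#' @param planted_contacts Data frame `chromA`, `binA`, `chromB`, `binB`,
#'   `multiplier` of planted high-contact pairs.
#' @param inter_background Expected inter-chromosomal count.
#' @param track_region Data frame `chrom`, `start`, `end`: span of the
#'   simulated signal track.
#' @param signal_background Mean background enrichment (0 disables background).
#' @param bg_segment_width,bg_segment_spacing Background segment geometry (bp).
#' @param planted_peaks Data frame `chrom`, `start`, `end`, `height` of
#'   planted plateaus (must not overlap).
#' @param cohort_size Number of patients.
#' @param planted_variants Data frame `chrom`, `pos`, `ref`, `alt`,
#'   `carriers` (semicolon-separated patient ids), optional `zygosity`.
#' @param background_variant_rate Expected background variants per patient.
#' @param background_region,background_exclude Data frames `chrom`, `start`,
#'   `end` bounding/excluding background variant positions.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, bin_size = 1e6, n_bins = c(chr17 = 60),
                              decay_exponent = 1, base_count = 100,
                              planted_contacts = NULL, inter_background = 1,
                              track_region = NULL, signal_background = 1,
                              bg_segment_width = 200, bg_segment_spacing = 300,
                              planted_peaks = NULL, cohort_size = 47,
                              planted_variants = NULL,
                              background_variant_rate = 0,
                              background_region = NULL,
                              background_exclude = NULL) {
  if (decay_exponent <= 0) input_error("decay_exponent must be > 0")
  if (base_count <= 0) input_error("base_count must be > 0")
  if (bin_size < 1) input_error("bin_size must be >= 1")
  if (!is.null(planted_peaks) && nrow(planted_peaks)) {
    if (any(planted_peaks$start < 1) || any(planted_peaks$end < planted_peaks$start)) {
      input_error("planted peak intervals are invalid")
    }
    pk <- GenomicRanges::GRanges(planted_peaks$chrom,
                                 IRanges::IRanges(planted_peaks$start, planted_peaks$end))
    if (!IRanges::isDisjoint(pk)) input_error("planted peaks must not overlap")
  }
  structure(
    list(seed = as.integer(seed), bin_size = bin_size, n_bins = n_bins,
         decay_exponent = decay_exponent, base_count = base_count,
         planted_contacts = planted_contacts, inter_background = inter_background,
         track_region = track_region, signal_background = signal_background,
         bg_segment_width = bg_segment_width, bg_segment_spacing = bg_segment_spacing,
         planted_peaks = planted_peaks, cohort_size = cohort_size,
         planted_variants = planted_variants,
         background_variant_rate = background_variant_rate,
         background_region = background_region,
         background_exclude = background_exclude),
    class = "simulation_config"
  )
}

label_offset <- function(label) sum(utf8ToInt(label)) %% 10000L

#' Simulate a binned contact map
#'
#' See [simulation_config()] for the generative model. Distinct enzyme
#' labels draw from distinct (but seed-determined) RNG streams so two enzyme
#' maps simulated from one config are independent replicates.
#'
#' @param cfg A `simulation_config`.
#' @param enzyme_label Name of the simulated enzyme map.
#' @return A `contact_map`; zero-count pairs are left implicit.
#' @export
simulate_contact_map <- function(cfg, enzyme_label = "sim") {
  if (!inherits(cfg, "simulation_config")) input_error("cfg must be a simulation_config")
  chroms <- names(cfg$n_bins)
  if (is.null(chroms)) input_error("n_bins must be a named vector")
  with_seed(cfg$seed + label_offset(enzyme_label), {
    pieces <- list()
    for (chrom in chroms) {
      n <- cfg$n_bins[[chrom]]
      if (n < 2) next
      pr <- t(utils::combn(seq_len(n) - 1L, 2))
      d <- pr[, 2] - pr[, 1]
      lambda <- cfg$base_count * d^(-cfg$decay_exponent)
      pieces[[length(pieces) + 1]] <- data.frame(
        chromA = chrom, binA = pr[, 1], chromB = chrom, binB = pr[, 2],
        lambda = lambda, stringsAsFactors = FALSE
      )
    }
    if (length(chroms) > 1) {
      cp <- t(utils::combn(chroms, 2))
      for (i in seq_len(nrow(cp))) {
        g <- expand.grid(binA = seq_len(cfg$n_bins[[cp[i, 1]]]) - 1L,
                         binB = seq_len(cfg$n_bins[[cp[i, 2]]]) - 1L)
        pieces[[length(pieces) + 1]] <- data.frame(
          chromA = cp[i, 1], binA = g$binA, chromB = cp[i, 2], binB = g$binB,
          lambda = cfg$inter_background, stringsAsFactors = FALSE
        )
      }
    }
    e <- do.call(rbind, pieces)
    pc <- cfg$planted_contacts
    if (!is.null(pc) && nrow(pc)) {
      for (i in seq_len(nrow(pc))) {
        hit <- (e$chromA == pc$chromA[i] & e$binA == pc$binA[i] &
                  e$chromB == pc$chromB[i] & e$binB == pc$binB[i]) |
               (e$chromA == pc$chromB[i] & e$binA == pc$binB[i] &
                  e$chromB == pc$chromA[i] & e$binB == pc$binA[i])
        e$lambda[hit] <- e$lambda[hit] * pc$multiplier[i]
      }
    }
    e$count <- stats::rpois(nrow(e), e$lambda)
    e <- e[e$count > 0, c("chromA", "binA", "chromB", "binB", "count")]
    contact_map(e, enzyme_label = enzyme_label, bin_size = cfg$bin_size)
  })
}

#' Simulate an enrichment signal track
#'
#' @param cfg A `simulation_config` with `track_region` set.
#' @return A signal-track `GRanges` (sorted, non-overlapping).
#' @export
simulate_signal_track <- function(cfg) {
  if (!inherits(cfg, "simulation_config")) input_error("cfg must be a simulation_config")
  tr <- cfg$track_region
  if (is.null(tr)) input_error("cfg$track_region is required to simulate a track")
  with_seed(cfg$seed + 1L, {
    segs <- NULL
    if (cfg$signal_background > 0) {
      starts <- seq(tr$start, tr$end,
                    by = cfg$bg_segment_width + cfg$bg_segment_spacing)
      ends <- pmin(starts + cfg$bg_segment_width - 1, tr$end)
      segs <- data.frame(chrom = tr$chrom, start = starts, end = ends,
                         score = stats::rexp(length(starts),
                                             rate = 1 / cfg$signal_background),
                         stringsAsFactors = FALSE)
    }
    pk <- cfg$planted_peaks
    if (!is.null(pk) && nrow(pk)) {
      if (!is.null(segs)) {
        pkg_gr <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start, pk$end))
        seg_gr <- GenomicRanges::GRanges(segs$chrom, IRanges::IRanges(segs$start, segs$end))
        segs <- segs[!IRanges::overlapsAny(seg_gr, pkg_gr), , drop = FALSE]
      }
      segs <- rbind(segs, data.frame(chrom = pk$chrom, start = pk$start,
                                     end = pk$end, score = pk$height,
                                     stringsAsFactors = FALSE))
    }
    if (is.null(segs) || nrow(segs) == 0) {
      gr <- GenomicRanges::GRanges()
      S4Vectors::mcols(gr)$score <- numeric(0)
      return(signal_track(gr, "simulated"))
    }
    gr <- GenomicRanges::GRanges(segs$chrom, IRanges::IRanges(segs$start, segs$end),
                                 score = segs$score)
    signal_track(gr, "simulated")
  })
}

#' Simulate a patient cohort variant table
#'
#' @param cfg A `simulation_config`.
#' @return Data frame in the cohort format of [read_cohort_variants()], with
#'   a `cohort_size` attribute.
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "simulation_config")) input_error("cfg must be a simulation_config")
  patients <- sprintf("P%02d", seq_len(cfg$cohort_size))
  rows <- list()
  pv <- cfg$planted_variants
  if (!is.null(pv) && nrow(pv)) {
    for (i in seq_len(nrow(pv))) {
      carriers <- strsplit(pv$carriers[i], ";", fixed = TRUE)[[1]]
      if (!all(carriers %in% patients)) {
        input_error(sprintf("planted carriers of %s:%d outside the cohort",
                            pv$chrom[i], pv$pos[i]))
      }
      zyg <- if ("zygosity" %in% names(pv)) pv$zygosity[i] else "het"
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = carriers, chrom = pv$chrom[i], pos = as.integer(pv$pos[i]),
        ref = pv$ref[i], alt = pv$alt[i], zygosity = zyg,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), zygosity = character(),
               stringsAsFactors = FALSE)
  key <- paste(out$patient_id, out$chrom, out$pos, sep = "|")
  if (anyDuplicated(key)) input_error("duplicate planted (patient, site)")

  if (cfg$background_variant_rate > 0) {
    br <- cfg$background_region %||% cfg$track_region
    if (is.null(br)) input_error("background variants need background_region")
    out <- with_seed(cfg$seed + 2L, {
      bases <- c("A", "C", "G", "T")
      excl <- cfg$background_exclude
      for (p in patients) {
        n <- stats::rpois(1, cfg$background_variant_rate)
        made <- 0L
        while (made < n) {
          pos <- sample(seq(br$start, br$end), 1)
          if (!is.null(excl) && nrow(excl) &&
              any(excl$chrom == br$chrom & excl$start <= pos & excl$end >= pos)) next
          if (any(out$patient_id == p & out$chrom == br$chrom & out$pos == pos)) next
          ra <- sample(bases, 2)
          out <- rbind(out, data.frame(
            patient_id = p, chrom = br$chrom, pos = pos, ref = ra[1],
            alt = ra[2], zygosity = "het", stringsAsFactors = FALSE
          ))
          made <- made + 1L
        }
      }
      out
    })
  }
  out <- out[order(out$chrom, out$pos, out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cohort_size") <- cfg$cohort_size
  out
}

#' Write a cohort as a minimal VCF v4.2
#'
#' One sample column per patient; carriers get `0/1` (het) or `1/1` (hom),
#' everyone else `0/0`.
#'
#' @param cohort Cohort data frame (with a `cohort_size` attribute or
#'   `cohort_size` given).
#' @param path Output path.
#' @param cohort_size Number of patients (columns).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, cohort_size = attr(cohort, "cohort_size")) {
  if (is.null(cohort_size)) input_error("cohort_size is required")
  patients <- sprintf("P%02d", seq_len(cohort_size))
  extra <- setdiff(unique(cohort$patient_id), patients)
  if (length(extra)) input_error(sprintf("patient ids outside P01..P%02d: %s",
                                         cohort_size, extra[1]))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", patients), collapse = "\t")
  )
  sites <- unique(cohort[c("chrom", "pos", "ref", "alt")])
  sites <- sites[order(sites$chrom, sites$pos, sites$alt), , drop = FALSE]
  rows <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    gt <- rep("0/0", cohort_size)
    carriers <- cohort[cohort$chrom == s$chrom & cohort$pos == s$pos &
                         cohort$ref == s$ref & cohort$alt == s$alt, ]
    gt[match(carriers$patient_id, patients)] <-
      ifelse(carriers$zygosity == "hom", "1/1", "0/1")
    paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a cohort as TSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
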