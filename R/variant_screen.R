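#' Read cohort variant calls
#'
#' Accepts either a minimal VCF v4.2 (CHROM/POS/REF/ALT plus per-patient GT
#' sample columns) or a flat TSV with columns `patient_id`, `chrom`, `pos`,
#' `ref`, `alt`, `zygosity`. One record is produced per patient per variant
#' site carried; reference-only and missing genotypes yield no record.
#' Multi-allelic VCF records are split into biallelic records.
#'
#' @param path Path to the cohort file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return Data frame with columns `patient_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `zygosity` (`het`/`hom`), plus a `cohort_size` attribute when the
#'   input names every patient (VCF sample columns).
#' @export
read_cohort_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) input_error(sprintf("cohort file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  out <- if (format == "vcf") read_cohort_vcf(path) else read_cohort_tsv(path)
  key <- paste(out$patient_id, out$chrom, out$pos, out$ref, out$alt, sep = "|")
  if (anyDuplicated(key)) {
    consistency_error(sprintf("duplicate (patient, site) record: %s", key[duplicated(key)][1]))
  }
  out
}

read_cohort_vcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) parse_error(sprintf("failed to parse VCF %s: %s", path, conditionMessage(e))))
  empty <- data.frame(patient_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      zygosity = character(), stringsAsFactors = FALSE)
  n_samples <- ncol(vcf@gt) - 1
  if (nrow(vcf@fix) == 0 || n_samples < 1) {
    attr(empty, "cohort_size") <- max(n_samples, 0)
    return(empty)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  rows <- list()
  for (v in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[v], ",", fixed = TRUE)[[1]]
    for (p in colnames(gt)) {
      g <- gt[v, p]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      alleles <- strsplit(g, "[/|]")[[1]]
      if (!all(grepl("^[0-9]+$", alleles))) {
        parse_error(sprintf("%s: malformed genotype '%s' (patient %s)", path, g, p))
      }
      alleles <- as.integer(alleles)
      if (any(alleles > length(alts))) {
        parse_error(sprintf("%s: genotype '%s' refers to missing ALT allele", path, g))
      }
      for (ai in unique(alleles[alleles > 0])) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = p, chrom = fix$CHROM[v], pos = as.integer(fix$POS[v]),
          ref = fix$REF[v], alt = alts[ai],
          zygosity = if (sum(alleles == ai) >= 2) "hom" else "het",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "cohort_size") <- n_samples
  out
}

read_cohort_tsv <- function(path) {
  tab <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) parse_error(sprintf("failed to parse TSV %s: %s", path, conditionMessage(e))))
  need <- c("patient_id", "chrom", "pos", "ref", "alt", "zygosity")
  if (!all(need %in% names(tab))) {
    parse_error(sprintf("%s: cohort TSV needs columns %s", path, paste(need, collapse = ", ")))
  }
  if (nrow(tab) && !all(tab$zygosity %in% c("het", "hom"))) {
    parse_error(sprintf("%s: zygosity must be 'het' or 'hom'", path))
  }
  tab$pos <- as.integer(tab$pos)
  tab[need]
}

#' Read a known-variant catalog
#'
#' TSV with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#' `clinical_significance`, `maf`, `mac` (e.g. dbSNP identifiers with
#' 1000 Genomes minor-allele frequency/count).
#'
#' @param path Path to the catalog TSV.
#' @return Data frame of known-variant records.
#' @export
read_variant_catalog <- function(path) {
  if (!file.exists(path)) input_error(sprintf("catalog not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab))) {
    parse_error(sprintf("%s: catalog needs columns %s", path, paste(need, collapse = ", ")))
  }
  if ("maf" %in% names(tab) && nrow(tab) &&
      any(!is.na(tab$maf) & (tab$maf < 0 | tab$maf > 0.5))) {
    parse_error(sprintf("%s: maf must lie in [0, 0.5]", path))
  }
  tab$pos <- as.integer(tab$pos)
  tab
}

#' Read transcription-factor binding sites from BED4
#'
#' The name field carries the factor name (e.g. p300, c-Fos, c-Jun).
#'
#' @param path BED file path.
#' @return A `GRanges` with a `name` metadata column.
#' @export
read_tf_sites <- function(path) {
  if (!file.exists(path)) input_error(sprintf("TF-site BED not found: %s", path))
  tryCatch(rtracklayer::import(path, format = "bed"),
           error = function(e) parse_error(sprintf("failed to parse BED %s: %s", path, conditionMessage(e))))
}

#' Number of TF binding sites containing a position
#'
#' Interval membership is inclusive at both bounds, consistent with the
#' package-wide 1-based inclusive convention.
#'
#' @param pos 1-based position.
#' @param sites TF-site `GRanges` (see [read_tf_sites()]).
#' @param chrom Optional chromosome; when given, only sites on it count.
#' @return Integer count of containing sites.
#' @export
site_overlap_count <- function(pos, sites, chrom = NULL) {
  if (pos < 1) input_error("pos must be >= 1")
  length(tf_hits_at(pos, sites, chrom))
}

tf_hits_at <- function(pos, sites, chrom = NULL) {
  if (length(sites) == 0) return(character(0))
  keep <- GenomicRanges::start(sites) <= pos & GenomicRanges::end(sites) >= pos
  if (!is.null(chrom)) {
    keep <- keep & as.character(GenomicRanges::seqnames(sites)) == chrom
  }
  nm <- S4Vectors::mcols(sites)$name
  if (is.null(nm)) nm <- sprintf("site_%d", seq_along(sites))
  nm[keep]
}

#' Screen cohort variants against candidate regions
#'
#' Assigns each variant to every candidate whose region contains its position
#' (inclusive bounds, same chromosome); annotates each distinct site as
#' `known:<id>` when the catalog holds a record with the same chromosome,
#' position and alleles, else `novel`; records which TF binding sites contain
#' the position; and counts distinct carrier patients per region.
#'
#' @param variants Cohort data frame from [read_cohort_variants()].
#' @param candidates `candidate_regions` data frame (or anything with
#'   `label`, `chrom`, `start`, `end` columns, e.g. [read_targets()]).
#' @param catalog Known-variant data frame from [read_variant_catalog()].
#' @param sites TF-site `GRanges`; may be empty.
#' @param cohort_size Number of patients screened; defaults to the cohort
#'   file's sample count when available.
#' @return A `screen_report`: list with `per_region` (label, n_sites,
#'   n_carriers, zero_variants), `per_site` (region_label, chrom, pos, ref,
#'   alt, novelty, carrier_count, tf_hits), and `cohort_size`.
#' @export
screen <- function(variants, candidates, catalog = NULL, sites = NULL,
                   cohort_size = NULL) {
  if (is.null(sites)) sites <- GenomicRanges::GRanges()
  if (is.null(cohort_size)) cohort_size <- attr(variants, "cohort_size")
  if (is.null(cohort_size)) cohort_size <- length(unique(variants$patient_id))
  if (nrow(variants) && length(unique(variants$patient_id)) > cohort_size) {
    input_error("more distinct patients than cohort_size")
  }

  per_region <- data.frame(
    label = candidates$label, n_sites = 0L, n_carriers = 0L,
    zero_variants = TRUE, stringsAsFactors = FALSE
  )
  per_site <- data.frame(
    region_label = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), novelty = character(),
    carrier_count = integer(), tf_hits = character(), stringsAsFactors = FALSE
  )
  if (nrow(variants) && nrow(candidates)) {
    vgr <- GenomicRanges::GRanges(variants$chrom,
                                  IRanges::IRanges(variants$pos, variants$pos))
    cgr <- GenomicRanges::GRanges(candidates$chrom,
                                  IRanges::IRanges(candidates$start, candidates$end))
    hits <- GenomicRanges::findOverlaps(vgr, cgr)
    if (length(hits)) {
      asg <- data.frame(
        variants[S4Vectors::queryHits(hits), , drop = FALSE],
        region_label = candidates$label[S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE
      )
      site_key <- paste(asg$region_label, asg$chrom, asg$pos, asg$ref, asg$alt, sep = "|")
      per_site <- do.call(rbind, lapply(split(asg, site_key), function(g) {
        data.frame(
          region_label = g$region_label[1], chrom = g$chrom[1], pos = g$pos[1],
          ref = g$ref[1], alt = g$alt[1],
          novelty = novelty_of(g$chrom[1], g$pos[1], g$ref[1], g$alt[1], catalog),
          carrier_count = length(unique(g$patient_id)),
          tf_hits = paste(tf_hits_at(g$pos[1], sites, g$chrom[1]), collapse = ","),
          stringsAsFactors = FALSE
        )
      }))
      per_site <- per_site[order(per_site$region_label, per_site$chrom, per_site$pos,
                                 per_site$alt), , drop = FALSE]
      rownames(per_site) <- NULL
      for (i in seq_len(nrow(per_region))) {
        lab <- per_region$label[i]
        per_region$n_sites[i] <- sum(per_site$region_label == lab)
        per_region$n_carriers[i] <-
          length(unique(asg$patient_id[asg$region_label == lab]))
      }
      per_region$zero_variants <- per_region$n_sites == 0L
    }
  }
  if (any(per_region$n_carriers > cohort_size)) {
    consistency_error("carrier count exceeds cohort size")
  }
  structure(
    list(per_region = per_region, per_site = per_site, cohort_size = cohort_size),
    class = "screen_report"
  )
}

novelty_of <- function(chrom, pos, ref, alt, catalog) {
  if (is.null(catalog) || nrow(catalog) == 0) return("novel")
  hit <- catalog$chrom == chrom & catalog$pos == pos &
    catalog$ref == ref & catalog$alt == alt
  if (any(hit)) paste0("known:", catalog$id[which(hit)[1]]) else "novel"
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Cohort screen: %d patient(s), %d candidate region(s)\n",
              x$cohort_size, nrow(x$per_region)))
  for (i in seq_len(nrow(x$per_region))) {
    r <- x$per_region[i, ]
    cat(sprintf("  %s: %d distinct site(s), %d carrier(s)%s\n", r$label,
                r$n_sites, r$n_carriers,
                if (r$zero_variants) " [no variants]" else ""))
  }
  if (nrow(x$per_site)) {
    cat("Sites:\n")
    for (i in seq_len(nrow(x$per_site))) {
      s <- x$per_site[i, ]
      cat(sprintf("  %s:%d %s>%s %s, %d carrier(s)%s\n", s$chrom, s$pos, s$ref,
                  s$alt, s$novelty, s$carrier_count,
                  if (nzchar(s$tf_hits)) paste0(", TF sites: ", s$tf_hits) else ""))
    }
  }
  invisible(x)
}

#' Write a screen report as TSV
#'
#' The per-region summary is written as `#`-prefixed header lines above the
#' per-site table so the file stays a single parseable TSV.
#'
#' @param report A `screen_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path) {
  hdr <- c(
    sprintf("# cohort_size=%d", report$cohort_size),
    sprintf("# region=%s\tn_sites=%d\tn_carriers=%d\tzero_variants=%s",
            report$per_region$label, report$per_region$n_sites,
            report$per_region$n_carriers,
            tolower(report$per_region$zero_variants))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(report$per_site, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
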