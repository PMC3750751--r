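#' Run the full prioritisation-and-screen pipeline
#'
#' Wires the stages end to end from a flat configuration: read the contact
#' maps, gene annotation and signal track; nominate candidate regions
#' ([select_candidates()]); export them as a sequencing-target BED
#' ([export_targets()]); screen the cohort variants against them
#' ([screen()]); and write the screen report plus a machine-readable run log
#' (parameters and package version). No stage mutates its inputs, and
#' identical inputs produce byte-identical outputs.
#'
#' @param config Either a named list or the path of a YAML file with keys:
#'   `maps` (one or more contact-map TSV paths), `gene` (BED), `signal`
#'   (bedGraph), `out_dir`, and optionally `variants` (VCF/TSV),
#'   `variants_format`, `catalog` (TSV), `tf_sites` (BED), `cohort_size`,
#'   `scope`, `top_k`, `include_anchor_bin`, `frac`, `max_gap`, `min_width`.
#' @return Invisibly, a list with `candidates`, `report` (NULL when no
#'   cohort is configured), and the written `paths`.
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) input_error(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  for (key in c("maps", "gene", "signal", "out_dir")) {
    if (is.null(config[[key]])) input_error(sprintf("config key '%s' is required", key))
  }
  for (p in c(unlist(config$maps), config$gene, config$signal,
              config$variants, config$catalog, config$tf_sites)) {
    if (!file.exists(p)) input_error(sprintf("input file not found: %s", p))
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)

  scope <- config$scope %||% "intra"
  top_k <- config$top_k %||% 1
  include_anchor_bin <- config$include_anchor_bin %||% TRUE
  frac <- config$frac %||% 0.5
  max_gap <- config$max_gap %||% 200
  min_width <- config$min_width %||% 100

  maps <- lapply(unlist(config$maps), read_contact_map)
  gene <- read_gene_bed(config$gene)[1]
  track <- read_bedgraph(config$signal)

  candidates <- select_candidates(maps, gene, track, scope = scope,
                                  top_k = top_k,
                                  include_anchor_bin = include_anchor_bin,
                                  frac = frac, max_gap = max_gap,
                                  min_width = min_width)
  paths <- c(targets = file.path(config$out_dir, "targets.bed"),
             log = file.path(config$out_dir, "run_log.json"))
  if (nrow(candidates) == 0) input_error("no candidate regions were nominated")
  export_targets(candidates, paths[["targets"]])

  report <- NULL
  if (!is.null(config$variants)) {
    variants <- read_cohort_variants(config$variants,
                                     format = config$variants_format %||% "auto")
    catalog <- if (!is.null(config$catalog)) read_variant_catalog(config$catalog)
    sites <- if (!is.null(config$tf_sites)) read_tf_sites(config$tf_sites)
    report <- screen(variants, candidates, catalog = catalog, sites = sites,
                     cohort_size = config$cohort_size %||% attr(variants, "cohort_size"))
    paths[["report"]] <- file.path(config$out_dir, "report.tsv")
    write_screen_report(report, paths[["report"]])
  }

  log <- list(
    package = "regscout",
    version = as.character(utils::packageVersion("regscout")),
    parameters = list(scope = scope, top_k = top_k,
                      include_anchor_bin = include_anchor_bin, frac = frac,
                      max_gap = max_gap, min_width = min_width),
    inputs = config[intersect(names(config),
                              c("maps", "gene", "signal", "variants",
                                "catalog", "tf_sites", "cohort_size"))],
    anchor_gene = S4Vectors::mcols(gene)$name %||% NA_character_,
    n_candidates = nrow(candidates),
    candidates = candidates$label
  )
  jsonlite::write_json(log, paths[["log"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(list(candidates = candidates, report = report, paths = paths))
}
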