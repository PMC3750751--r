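#' Build the packaged NF1 worked-example fixture
#'
#' Writes the file set for the worked example at the NF1 locus (chr17,
#' GRCh37 coordinates): two 1-Mb contact maps carrying the published
#' interaction counts of the NF1-containing bin (HindIII-map: bin 28 = 703,
#' bin 31 = 222, bin 32 = 59; NcoI-map: bin 28 = 255, bin 31 = 699,
#' bin 32 = 150, plus the weak inter-chromosomal contact with chr1 bin 0 =
#' 21), an H3K27ac-style signal track with plateaus at region A
#' (chr17:28,846,790-28,847,790) and region B (chr17:29,378,421-29,379,750),
#' the NF1 gene annotation (chr17:29,421,945-29,709,134, plus strand), the
#' p300/c-Fos/c-Jun binding-site intervals, a known-variant catalog
#' (rs78190160, rs71372224; MAF 0.007, MAC 16), and a 47-patient cohort
#' carrying the three reported region-A variants.
#'
#' The signal track itself is synthetic: only the plateau bounds and the
#' ordering of their heights (region A above region B) are published, so the
#' heights (10 vs 4 over a background of 1) and the carrier overlap pattern
#' (novel variant in P01,P02; rs78190160 in P01,P03,P04; rs71372224 in
#' P02,P03,P05, five distinct carriers) are fixture conventions, documented
#' here.
#'
#' @param outdir Output directory (created if missing).
#' @return Named character vector of the written file paths (`hindiii_map`,
#'   `ncoi_map`, `signal`, `gene`, `tf_sites`, `catalog`, `cohort_vcf`,
#'   `cohort_tsv`).
#' @export
build_nf1_fixture <- function(outdir = tempfile("nf1_fixture_")) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) input_error(sprintf("cannot create fixture directory %s", outdir))
  }
  paths <- c(
    hindiii_map = file.path(outdir, "hindiii_map.tsv"),
    ncoi_map = file.path(outdir, "ncoi_map.tsv"),
    signal = file.path(outdir, "h3k27ac_synthetic.bedgraph"),
    gene = file.path(outdir, "nf1_gene.bed"),
    tf_sites = file.path(outdir, "tf_sites.bed"),
    catalog = file.path(outdir, "known_variants.tsv"),
    cohort_vcf = file.path(outdir, "cohort_synthetic.vcf"),
    cohort_tsv = file.path(outdir, "cohort_synthetic.tsv")
  )

  hindiii <- contact_map(data.frame(
    chromA = "chr17", binA = c(28L, 29L, 29L),
    chromB = "chr17", binB = c(29L, 31L, 32L),
    count = c(703, 222, 59), stringsAsFactors = FALSE
  ), enzyme_label = "HindIII", bin_size = 1e6)
  write_contact_map(hindiii, paths[["hindiii_map"]])

  ncoi <- contact_map(data.frame(
    chromA = c("chr17", "chr17", "chr17", "chr1"),
    binA = c(28L, 29L, 29L, 0L),
    chromB = "chr17", binB = c(29L, 31L, 32L, 29L),
    count = c(255, 699, 150, 21), stringsAsFactors = FALSE
  ), enzyme_label = "NcoI", bin_size = 1e6)
  write_contact_map(ncoi, paths[["ncoi_map"]])

  # plateaus at regions A and B over a sparse unit background
  track <- signal_track(GenomicRanges::GRanges(
    "chr17",
    IRanges::IRanges(
      start = c(28500000, 28846790, 28900000, 29100000, 29378421, 29500000),
      end   = c(28500199, 28847790, 28900199, 29100199, 29379750, 29500199)
    ),
    score = c(1, 10, 1, 1, 4, 1)
  ), track_label = "H3K27ac_synthetic")
  write_bedgraph(track, paths[["signal"]])

  gene <- GenomicRanges::GRanges("chr17", IRanges::IRanges(29421945, 29709134),
                                 strand = "+", name = "NF1", score = 0)
  rtracklayer::export(gene, paths[["gene"]], format = "bed")

  tf <- GenomicRanges::GRanges(
    "chr17",
    IRanges::IRanges(start = c(28846840, 28846815, 28846819),
                     end = c(28847158, 28847158, 28847094)),
    name = c("p300", "c-Fos", "c-Jun")
  )
  rtracklayer::export(tf, paths[["tf_sites"]], format = "bed")

  catalog <- data.frame(
    id = c("rs78190160", "rs71372224"),
    chrom = "chr17",
    pos = c(28847605L, 28846883L),
    ref = c("G", "C"), alt = c("A", "T"),
    clinical_significance = "unknown",
    maf = 0.007, mac = 16L,
    stringsAsFactors = FALSE
  )
  utils::write.table(catalog, paths[["catalog"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cohort <- data.frame(
    patient_id = c("P01", "P02",                 # novel C>T at 28,846,793
                   "P01", "P03", "P04",          # rs78190160 at 28,847,605
                   "P02", "P03", "P05"),         # rs71372224 at 28,846,883
    chrom = "chr17",
    pos = c(28846793L, 28846793L, 28847605L, 28847605L, 28847605L,
            28846883L, 28846883L, 28846883L),
    ref = c("C", "C", "G", "G", "G", "C", "C", "C"),
    alt = c("T", "T", "A", "A", "A", "T", "T", "T"),
    zygosity = "het",
    stringsAsFactors = FALSE
  )
  attr(cohort, "cohort_size") <- 47L
  write_cohort_vcf(cohort, paths[["cohort_vcf"]])
  write_cohort_tsv(cohort, paths[["cohort_tsv"]])

  paths
}
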