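test_that("cohort VCF and TSV readers agree and validate genotypes", {
  fx <- nf1_fixture_paths()
  vcf <- read_cohort_variants(fx[["cohort_vcf"]])
  tsv <- read_cohort_variants(fx[["cohort_tsv"]])

  expect_equal(sum(vcf$pos == 28846793), 2)   # novel variant in two patients
  expect_equal(attr(vcf, "cohort_size"), 47)
  expect_true(all(vcf$zygosity == "het"))

  key <- function(d) sort(paste(d$patient_id, d$chrom, d$pos, d$ref, d$alt,
                                d$zygosity, sep = "|"))
  expect_equal(key(vcf), key(tsv))

  # all-reference VCF -> empty list
  allref <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/0"
  ), allref)
  expect_equal(nrow(read_cohort_variants(allref)), 0)

  # malformed genotype
  badgt <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/x"
  ), badgt)
  expect_error(read_cohort_variants(badgt), class = "regscout_parse_error")

  # duplicate (patient, site) rejected
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tchrom\tpos\tref\talt\tzygosity",
               "P01\tchr1\t100\tA\tT\thet",
               "P01\tchr1\t100\tA\tT\thet"), dup)
  expect_error(read_cohort_variants(dup), class = "regscout_consistency_error")
})

test_that("multi-allelic and homozygous VCF genotypes split correctly", {
  multi <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\t.\tA\tT,G\t.\tPASS\t.\tGT\t1/2\t1/1\t0/0"
  ), multi)
  v <- read_cohort_variants(multi)
  expect_equal(nrow(v), 3)
  s1 <- v[v$patient_id == "S1", ]
  expect_setequal(s1$alt, c("T", "G"))
  expect_true(all(s1$zygosity == "het"))
  expect_equal(v$zygosity[v$patient_id == "S2"], "hom")
})

test_that("TF-site overlap counting is inclusive at both bounds", {
  sites <- read_tf_sites(nf1_fixture_paths()[["tf_sites"]])
  expect_equal(length(sites), 3)
  expect_equal(site_overlap_count(28846883, sites), 3)  # rs71372224
  expect_equal(site_overlap_count(1, sites), 0)
  # inside p300 and c-Fos, past the c-Jun end (28,847,094)
  expect_equal(site_overlap_count(28847100, sites), 2)
  # bounds themselves count
  expect_equal(site_overlap_count(28847158, sites), 2)
  expect_equal(site_overlap_count(28847159, sites), 0)
})

fixture_report <- function() {
  fx <- nf1_fixture_paths()
  maps <- lapply(fx[c("hindiii_map", "ncoi_map")], read_contact_map)
  cand <- select_candidates(maps, nf1_gene(), read_bedgraph(fx[["signal"]]))
  screen(read_cohort_variants(fx[["cohort_vcf"]]), cand,
         catalog = read_variant_catalog(fx[["catalog"]]),
         sites = read_tf_sites(fx[["tf_sites"]]))
}

test_that("the fixture cohort screen reproduces the reported counts", {
  rep <- fixture_report()
  expect_equal(rep$cohort_size, 47)

  region_a <- rep$per_region[grepl("bin28", rep$per_region$label), ]
  region_b <- rep$per_region[grepl("bin29", rep$per_region$label), ]
  expect_equal(region_a$n_sites, 3)
  expect_equal(region_a$n_carriers, 5)
  expect_false(region_a$zero_variants)
  expect_equal(region_b$n_sites, 0)
  expect_true(region_b$zero_variants)

  ps <- rep$per_site
  expect_equal(nrow(ps), 3)
  novel <- ps[ps$pos == 28846793, ]
  expect_equal(novel$novelty, "novel")
  expect_equal(novel$carrier_count, 2)
  rs224 <- ps[ps$pos == 28846883, ]
  expect_equal(rs224$novelty, "known:rs71372224")
  expect_setequal(strsplit(rs224$tf_hits, ",")[[1]], c("p300", "c-Fos", "c-Jun"))
  rs160 <- ps[ps$pos == 28847605, ]
  expect_equal(rs160$novelty, "known:rs78190160")
  expect_equal(rs160$carrier_count, 3)
  expect_equal(rs160$tf_hits, "")
})

test_that("empty cohorts and report serialisation behave", {
  fx <- nf1_fixture_paths()
  maps <- lapply(fx[c("hindiii_map", "ncoi_map")], read_contact_map)
  cand <- select_candidates(maps, nf1_gene(), read_bedgraph(fx[["signal"]]))
  empty <- data.frame(patient_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      zygosity = character())
  rep <- screen(empty, cand, cohort_size = 47)
  expect_true(all(rep$per_region$zero_variants))
  expect_equal(sum(rep$per_region$n_sites), 0)

  full <- fixture_report()
  out <- tempfile(fileext = ".tsv")
  write_screen_report(full, out)
  lines <- readLines(out)
  expect_true(any(grepl("^# cohort_size=47", lines)))
  body <- utils::read.delim(out, comment.char = "#")
  expect_equal(nrow(body), 3)
})

test_that("novelty depends only on position and alleles", {
  catalog <- read_variant_catalog(nf1_fixture_paths()[["catalog"]])
  cand <- data.frame(label = "R", chrom = "chr17", start = 28846000,
                     end = 28848000, stringsAsFactors = FALSE)
  # same position as rs71372224 but a different alt allele -> novel
  v <- data.frame(patient_id = "P01", chrom = "chr17", pos = 28846883L,
                  ref = "C", alt = "G", zygosity = "het")
  rep <- screen(v, cand, catalog = catalog, cohort_size = 47)
  expect_equal(rep$per_site$novelty, "novel")
})

test_that("screening matches the exhaustive membership oracle on random cohorts", {
  for (seed in 1:20) {
    set.seed(seed)
    variants <- random_cohort()
    regions <- random_regions()
    rep <- screen(variants, regions, cohort_size = attr(variants, "cohort_size"))
    want <- oracle_screen_assignment(variants, regions)

    for (lab in regions$label) {
      w <- if (is.null(want)) NULL else want[want$region_label == lab, ]
      n_sites <- if (is.null(w) || nrow(w) == 0) 0 else
        nrow(unique(w[c("chrom", "pos", "ref", "alt")]))
      n_carriers <- if (is.null(w) || nrow(w) == 0) 0 else length(unique(w$patient_id))
      got <- rep$per_region[rep$per_region$label == lab, ]
      expect_equal(got$n_sites, n_sites, info = sprintf("seed %d %s", seed, lab))
      expect_equal(got$n_carriers, n_carriers)
    }
    # conservation: per-region site rows = assigned distinct (region, site) pairs
    n_pairs <- if (is.null(want)) 0 else
      nrow(unique(want[c("region_label", "chrom", "pos", "ref", "alt")]))
    expect_equal(nrow(rep$per_site), n_pairs)
    expect_equal(sum(rep$per_region$n_sites), n_pairs)
  }
})

test_that("screening is additive over cohort partitions", {
  set.seed(99)
  variants <- random_cohort(40, n_patients = 12)
  regions <- random_regions(4)
  whole <- screen(variants, regions, cohort_size = 12)

  half <- variants$patient_id %in% sprintf("P%02d", 1:6)
  p1 <- variants[half, ]; p2 <- variants[!half, ]
  attr(p1, "cohort_size") <- 12; attr(p2, "cohort_size") <- 12
  r1 <- screen(p1, regions, cohort_size = 12)
  r2 <- screen(p2, regions, cohort_size = 12)

  merged_sites <- unique(rbind(
    r1$per_site[c("region_label", "chrom", "pos", "ref", "alt")],
    r2$per_site[c("region_label", "chrom", "pos", "ref", "alt")]
  ))
  expect_equal(nrow(merged_sites), nrow(whole$per_site))
  for (lab in regions$label) {
    carriers <- function(rep, vs) unique(
      oracle_screen_assignment(vs, regions)$patient_id[
        oracle_screen_assignment(vs, regions)$region_label == lab]
    )
    expect_equal(
      whole$per_region$n_carriers[whole$per_region$label == lab],
      length(union(carriers(r1, p1), carriers(r2, p2)))
    )
  }
})
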