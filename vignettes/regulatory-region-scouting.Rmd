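---
title: "Scouting remotely acting regulatory regions from contact maps and enhancer signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scouting remotely acting regulatory regions from contact maps and enhancer signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regscout)
```

## The problem and the model

In a minority of patients with a monogenic disorder, no pathogenic lesion is
found in the gene's coding sequence, splice junctions or proximal promoter.
One explanation is a mutation in a remotely acting regulatory element —
an enhancer that may sit hundreds of kb away, or even on another chromosome,
yet contact the gene in the nuclear three-dimensional architecture. regscout
operationalises a simple in silico triage for such elements, combining two
observable proxies:

1. **Spatial proximity.** A binned chromatin-contact (Hi-C) map records, for
   every pair of fixed-size genomic bins (1 Mb by default), the number of
   ligation contacts observed between them. Bins whose contact count with the
   gene-containing bin is high are candidate neighbourhoods for regulatory
   elements. Maps are consumed already normalised for experimental biases, one
   map per restriction enzyme; counts may therefore be fractional.
2. **Enhancer activity.** H3K27ac enrichment distinguishes active enhancers
   from inactive ones. Within each high-contact bin the pipeline delimits the
   short region of highest enrichment in a piecewise-constant signal track.

The nominated regions are exported as sequencing targets, and cohort variant
calls are screened against them: each variant is assigned to the region(s)
containing its position, annotated as novel or known against a catalog
(position *and* alleles must match — position-only matching would mislabel a
different allele at a catalogued site), and intersected with
transcription-factor binding-site intervals.

## Coordinate and binning conventions

All internal coordinates are 1-based and inclusive at both ends, the
convention of the printed coordinates at the NF1 locus that the packaged
worked example reproduces; BED and bedGraph files are 0-based half-open on
disk and converted by rtracklayer at the I/O boundary. A bin of index $i$ and
size $s$ covers $[i\,s, (i+1)\,s - 1]$, so the 1-Mb bin 29 of chr17 covers
29,000,000–29,999,999 — exactly the published NF1-containing fragment — and
`bin_of_position()` is plain `floor(pos / s)`.

"Upstream" is defined relative to gene strand. `upstream_distance()` returns
`start(gene) - end(region)` for a plus-strand gene (mirrored on minus),
clamped at 0 when the region abuts or overlaps the gene start; display
rounding is to the nearest kb. The signed `gene_distance()` used to annotate
candidates is positive upstream, negative downstream, 0 on overlap; trans
candidates carry an undefined (NA) distance.

Two prose-versus-coordinate discrepancies in the source material are resolved
in favour of the coordinates: the NF1 span 29,421,945–29,709,134 is 287,190 bp
(sometimes quoted as "283 kb"), and the distal region's computed distance is
574,155 bp (quoted loosely as "approximately 600 kb"). The pipeline always
reports the computed values.

## Partner ranking and the consensus rule

`rank_partners()` sorts all stored partners of the anchor bin by count
descending, ties broken by chromosome name then bin index so rankings are
deterministic; the anchor is never its own partner, and absent pairs count 0
(a sparse representation of a dense map). The published worked example
reports each enzyme map separately and never states a combination rule, so
the combiner is this package's explicit design: `consensus_top_partners()`
orders bins by the number of maps in whose top-$k$ they appear, then by best
rank, then by the deterministic tie-break. With $k = 1$ on the worked-example
maps this selects both the adjacent upstream bin (top of the HindIII-map,
703 contacts) and the first downstream bin (top of the NcoI-map, 699); only
the former carries signal in the packaged track, so exactly two candidate
regions emerge — one distal, one proximal. Note the two maps genuinely
disagree about which partner is strongest; the consensus rule surfaces both
rather than adjudicating.

## Delimiting the enrichment region

The source procedure says only that "relatively short regions corresponding
to the highest enrichment" were selected; the concrete rule here is a
fraction-of-maximum run merge, with all three knobs exposed:

* `frac` (default 0.5): positions with signal $\ge$ `frac` $\times$ the query
  maximum are above threshold. 0.5 is the conventional "half-maximum" width
  definition.
* `max_gap` (default 200 bp): above-threshold runs separated by at most this
  many bp are merged, bridging nucleosome-scale dips inside one element.
* `min_width` (default 100 bp): merged runs shorter than this are discarded —
  an enhancer candidate narrower than a nucleosome is noise.

The returned region is the surviving run containing the (leftmost, for
determinism on ties) position of the maximum; `peak_height` is the maximum
and `area` the value-times-length integral inside the run. Raising `frac`
never widens the region, and the region always contains an argmax of the
signal within the query — both are property-tested. One region per bin is
returned, matching a screening design that sequences one amplicon per
fragment.

## The anchor bin and selection defaults

The anchor is the bin containing the gene *midpoint* — unambiguous even for
a gene straddling a bin boundary (NF1 sits almost centrally in its bin, so
the choice is inert in the worked example). `include_anchor_bin` defaults to
`TRUE` because the gene-containing fragment itself is screened for a proximal
element; `top_k` defaults to 1, reproducing the worked example, and can be
raised to pursue the additional high-contact fragments (the 222/59-count
downstream bins, the weak 21-count chr1 contact). `scope` defaults to
intra-chromosomal; inter-chromosomal candidates are available but a
locality of `trans` is annotated with no distance.

## What the simulators emulate — and what they do not

`simulate_contact_map()` draws Poisson counts around a power-law expectation
$\mathrm{E}[c_{ij}] = c_0\, d_{ij}^{-\alpha}$ with $\alpha = 1$ by default —
the well-known approximate distance scaling of intra-chromosomal contact
frequency — a constant inter-chromosomal background, and multiplicative
planted high-contact pairs. Poisson noise is the simplest defensible model
for event tallies; real normalised maps have over-dispersion, domain
structure and bias residuals that the simulator does not attempt.

`simulate_signal_track()` lays sparse background segments (default 200 bp
wide, 300 bp apart — wider than the default `max_gap`, so background never
merges into a planted plateau) with Exponential heights of mean
`signal_background`, and rectangular planted plateaus that override the
background. Real H3K27ac tracks have correlated, shoulder-shaped peaks; the
rectangles make planted truth unambiguous for recovery studies.

`simulate_cohort()` realises exactly the planted carriers (the worked
example's carrier overlap — novel variant in P01,P02; rs78190160 in
P01,P03,P04; rs71372224 in P02,P03,P05, five distinct carriers of 47 — is a
fixture convention; only the per-variant counts and the five-carrier total
are published), plus optional uniform background variants outside excluded
regions. No linkage disequilibrium or mutation-rate structure is modelled.

Passing the planted-truth suites therefore shows the pipeline recovers
strong, isolated signals under idealised noise; it does not certify
performance on real maps with domain structure or on broad, overlapping
enhancer clusters.

## Problem sizes and study conditions

The recovery studies use one 30-bin chromosome at 10-kb bin size with
`base_count` 100, a planted pair two bins from the anchor at multiplier 20
(expected count $100 \times 2^{-1} \times 20 = 1000$ against an adjacent-bin
background of 100), and a 1-kb plateau at 8× the unit background mean —
satisfying the $\ge 5\times$ planted-height regime with headroom over the
Exponential background tail. The end-to-end study runs 100 seeded replicates
(observed recovery 99–100%), the peak-midpoint study 200 (within one
`max_gap` of the planted midpoint in ≥ 95%); oracle equivalence suites run
100 random instances per stage. The planted pair sits close to the anchor
deliberately: under steeper decay exponents a distant planted pair would fall
below the adjacent-bin expectation by construction, a regime no ranking
method could recover.

## Degenerate inputs and numerical choices

Empty maps rank to empty lists; an all-zero query returns no region rather
than a zero-height one; `top_k = 0` with the anchor bin degenerates to a
single-bin enhancer scan. Contact counts serialise with 17 significant
digits so write–read round-trips are exact for fractional normalised counts.
Asymmetrically stored pairs (both orientations with different counts) are a
consistency error, not a warning. Maps, tracks and cohorts are validated at
the boundary with classed conditions (`regscout_input_error`,
`regscout_parse_error` with line numbers for the bespoke contact dialect,
`regscout_consistency_error`), which the command-line wrapper maps to exit
codes 2 and 3.

## Known limitations

* No statistical significance is attached to contact counts; ranking is
  purely ordinal, as in the source procedure. A background model per distance
  stratum would be the natural extension.
* The signal track is consumed as given; no input normalisation, replicate
  handling or peak-shape modelling.
* One enrichment region per bin by default; broad super-enhancer-like
  domains will be truncated to the maximal run.
* Variant novelty requires exact allele match; complex or multi-nucleotide
  representations are not normalised.
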