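# ampliscreen

Batch CRISPR/Cas9 guide design and amplicon-sequencing indel screens, in R.

Producing knockout lines with CRISPR/Cas9 is mostly a screening problem:
guides must be tested for cutting activity, and injected founders (G0)
are genetically mosaic, so the alleles in an easily sampled tissue (a fin
clip) need not be the alleles their germline transmits. Screening the
germline directly — deep-sequencing amplicons from sperm samples — gives
both the transmission rate and the exact indel sequences that the next
generation can inherit. ampliscreen implements that workflow end to end
for labs running such screens in batch:

* **Guide design** — scan target regions for sites matching the
  `N20-NGG` protospacer/PAM consensus (either `GGN19GG`, directly
  T7-transcribable, or the relaxed `N21GG` used for tail-to-tail guide
  pairs with two extra 5' G added at oligo construction); enumerate
  genomic off-target matches up to *k* protospacer mismatches with a
  complete seed-and-extend search; score sites
  (`1/(1 + Σ 2^-m)` over off-target hits with `m` mismatches, times a
  transcript-position term); select guide pairs with cut sites 30–100 bp
  apart in tail-to-tail orientation; emit T7 construction oligos.
* **Assay design** — nested PCR primers (nearest-neighbor Tm, 250–300 bp
  internal product, cut site offset so a 150 bp read 1 covers it) and the
  three-round barcoded Illumina library structure with 11-nt sample
  barcodes at pairwise Hamming distance ≥ 3.
* **Indel quantification** — demultiplex pooled reads, trim library
  scaffold including 3' read-through caused by large deletions, discard
  reads trimmed below 50 bp, align with a native overlap aligner (affine
  gaps plus a long-gap cost ceiling so 100+ bp deletions map as one
  deletion), left-align indels to canonical coordinates, group identical
  signatures into alleles and report each allele's within-sample
  frequency and the percent of reads carrying an indel. Pre-aligned
  SAM/BAM plus a YAML run configuration is an equivalent entry point.
* **Screen analytics** — 96-well plate maps, germline-versus-soma
  concordance (per-guide Pearson *r*, fin-only sample counts, shared
  variant counts), and Wilcoxon rank-sum comparisons (exact or
  tie-corrected normal approximation with continuity correction) for
  contrasts such as guide-design consensus efficiency.
* **Simulation** — ground-truth generators for genomes with planted
  sites, mosaic founder samples (multinomial allele mixtures), and
  multiplexed error-bearing read sets, used throughout the test suite.

All tabular results are tibbles; fitted/summary objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

Design a guide and screening amplicon on a simulated 20 kb region, then
quantify a mosaic founder sample (55 % wild type, 30 % of a 7 bp
deletion, 15 % of a 2 bp insertion; 2,000 reads at 0.3 % substitution
error):

```r
library(ampliscreen)
library(tibble)

g <- sim_genome(20000, seed = 1, n_sites = 3, consensus = "GGN19GG")
region <- tibble(id = "gene_a", seq_name = "chr1", start = 0L, end = 20000L,
                 strand = "+", sequence = g$genome[["chr1"]])
sites  <- scan_sites(region, "GGN19GG")
target <- sites[match(g$sites$start[1], sites$start), ]
idx    <- build_genome_index(g$genome)
scored <- score_sites(target, find_offtargets(target, idx, max_mismatches = 3))

cut <- scored$cut_pos[1]
sub <- tibble(id = "gene_a", seq_name = "chr1", start = cut - 400L,
              end = cut + 400L, strand = "+",
              sequence = substr(g$genome[["chr1"]], cut - 399L, cut + 400L))
amp <- design_amplicon(sub, cut_sites = cut)
amp
#> amplicon gene_a_amp : 253 bp at [7493,7746)
#>   cut site(s) at 7539 ( 46 bp into the product )
#>   role     strand sequence                    start   end length    gc    tm
#> 1 internal +      TGTGGGGCTCGATACCGGCC         7493  7513     20 0.7    60.7
#> 2 internal -      GGGAGTAGTCCTCAACATTTTGCATCA  7719  7746     27 0.444  57.3
#> 3 external +      AGCAGTTGCAGCGGCATACATTGT     7439  7463     24 0.5    60.0
#> 4 external -      CGATCGTTGGGTTTGTGAACTCGCT    7772  7797     25 0.52   60.0

sheet <- make_barcode_sheet("founder_01", seed = 2)
lay   <- build_library_structure(amp, sheet$barcode[1], sample_id = "founder_01")
spec  <- mosaic_spectrum(tibble(
  allele = c("WT", "DEL7", "INS2"), type = c("WT", "DEL", "INS"),
  pos = c(NA, amp$cut_local - 3L, amp$cut_local),
  len = c(NA, 7L, 2L), seq = c("", "", "AT"),
  frequency = c(0.55, 0.30, 0.15)))
sim <- simulate_sample(spec, lay, n_reads = 2000, sub_error_rate = 0.003,
                       seed = 3)

res <- count_indels(sim$reads, lay)
tidy(res)[, c("allele_id", "type", "pos", "net_length_change",
              "read_count", "frequency")]
#>             allele_id type pos net_length_change read_count frequency
#> 1 founder_01_allele01  DEL  42                -7        625    0.3125
#> 2 founder_01_allele02  INS  46                 2        290    0.1450
glance(res)[, c("total_reads", "reads_mapped", "pct_reads_with_indel")]
#>   total_reads reads_mapped pct_reads_with_indel
#> 1        2000         2000                45.75
```

The multinomial draw behind this simulation was 53.8 % WT / 31.5 % DEL7 /
14.7 % INS2, so both recovered frequencies (31.25 % and 14.5 %) are
within sampling error of truth. `autoplot(res, cut_pos = amp$cut_local)`
draws the variants relative to the cut; `plate_report()` +
`autoplot()` render whole plates.

A thin CLI over the same functions is installed at `exec/ampliscreen`
(subcommands `design`, `offtarget`, `primers`, `simulate`, `count`,
`stats`).

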