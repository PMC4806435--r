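---
title: "ampliscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ampliscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ampliscreen implements a batch CRISPR/Cas9 screening workflow for model
organisms such as zebrafish: design guide RNAs against target regions,
design nested amplicons for multiplexed deep sequencing, and quantify the
insertion/deletion (indel) alleles that injection founders carry — in
particular in sperm samples, where allele frequencies measure germline
transmission directly. This vignette records the models, parameter
choices and numerical decisions behind each stage, and what the
simulation-based tests do and do not demonstrate.

## Guide discovery and scoring

A Cas9 target site is a 20-nt protospacer followed by an NGG PAM, i.e. a
23-nt genomic window. Two consensi are supported:

* **N21GG** — any protospacer. Guides designed this way receive two extra
  5' G bases at oligo construction so T7 transcription can initiate,
  making the sgRNA spacer 22 nt.
* **GGN19GG** — protospacer beginning GG, transcribable directly; spacer
  stays 20 nt.

`scan_sites()` reports every match on both strands, overlaps included,
in 0-based half-open forward-strand coordinates, with the protospacer and
PAM given as read on the site's own strand. Windows containing N are
excluded: such sites cannot be synthesised or screened unambiguously.
The predicted blunt cut lies 3 bp 5' of the PAM (between protospacer
positions 17 and 18), the canonical SpCas9 geometry; `cut_pos` stores the
forward-strand coordinate of that bond so that the two strands of one
site agree on the genomic position.

Off-target search (`build_genome_index()` + `find_offtargets()`) is a
native seed-and-extend scan rather than a call to an external mapper, so
its completeness is checkable: the protospacer is split into
`max_mismatches + 1` contiguous chunks and, by pigeonhole, any window
within the mismatch budget matches at least one chunk exactly. Test
genomes up to 100 kb are verified against an exhaustive Hamming scan.
Decisions a mapper would make implicitly are explicit here: off-target
windows must carry an NGG PAM (NAG is not counted), mismatches are
counted over the protospacer only with the PAM's N position free, and
N-containing windows are skipped. The default budget of 4 mismatches is
an arbitrary but conventional ceiling; gapped ("bulge") off-targets are
out of scope.

Scoring has no published closed form to reproduce, so the package uses a
simple, monotone, configurable convention:

* `offtarget_score = 1 / (1 + sum(2^-m))` over non-identical hits with
  `m` mismatches — a second perfect copy halves the score, a
  3-mismatch hit costs little;
* `position_score = 1 - d/L` inside an annotated transcript (distance
  `d` of the cut from the 5' end, length `L`), else 1 — favouring
  early-truncating alleles;
* `combined_score` is the product, so both components stay in [0, 1] and
  extra hits can only lower it.

The weight function is an argument (`weight`), so alternative penalty
models drop in without touching the search.

Guide pairs for larger deletions (`select_pairs()`) must be tail-to-tail
— upstream site on the reverse strand, downstream site on the forward
strand — with cut positions 30–100 bp apart, bounds inclusive, measured
cut-to-cut. Pairs are ranked by the sum of the member scores with a
deterministic coordinate tie-break.

## Amplicon and library design

`design_amplicon()` picks an internal primer pair whose product is
250–300 bp and covers every cut site within 100 bp of a product end,
then external primers strictly outside that product for the first-round
PCR. Because the indel caller processes read 1 only (see below), the
search iterates placements cut-near-the-start first, so a 150 bp read
starting at the product's 5' end sequences across the cut. Cut sites are
additionally kept at least 45 bp from the product boundaries: trimmed
reads then retain an anchor of matching sequence on both sides of the
cut, without which an indel beginning at the first aligned base is
indistinguishable from a shifted alignment start.

The native primer picker uses unified nearest-neighbor thermodynamics
(the standard ΔH/ΔS dinucleotide table with terminal initiation terms
and an entropic salt correction), two-state Tm at 50 nM primer and
50 mM monovalent salt. Constraints: length 18–27 nt, GC 30–70 %, Tm
57–63 °C, target 60 °C, ties broken leftmost-then-shortest so the design
is deterministic. These mirror common defaults of interactive primer
design tools; an external designer can be substituted upstream by
supplying its primers directly. Dimer/hairpin screening is not
implemented — a known limitation.

The three-round PCR library is modelled explicitly
(`build_library_structure()`): outer adaptor + 11-nt sample barcode +
partial adaptor tail + internal primer + insert + the reverse
complements of the far primer, tail and adaptor. Barcodes from
`make_barcode_sheet()` are drawn with pairwise Hamming distance ≥ 3, so
demultiplexing at one allowed mismatch can never cross-assign a read
with a single sequencing error. The partial-tail defaults are
Nextera-style sequences and are configurable.

## Indel calling

The native path replaces an external aligner + realignment-based caller
with three checkable components:

1. **Trimming** (`trim_reads()`): the 5' scaffold
   (barcode/tail/primer) is matched allowing ≤ 10 % substitutions and
   stripped; the 3' end is scanned for the earliest occurrence of the
   far primer/tail/adaptor — which a read reaches whenever a large
   deletion shortens the insert — with partial terminal overlaps of
   ≥ 5 nt accepted. Primer bases are removed along with adaptor so
   primer-dimer artefacts cannot masquerade as wild-type signal. Reads
   shorter than 50 bp after trimming are discarded; this removes
   uninformative fragments while keeping large-deletion alleles whose
   trimmed insert is still mappable.
2. **Alignment** (`align_reads()`): overlap-style dynamic programming
   with affine gaps — match +1, mismatch −2, gap open −6, gap extend
   −0.5/bp — free soft-clipping of read ends and free reference flanks,
   and a long-gap cost ceiling of 25 implemented as a second gap state
   (open = 25, extend = 0). The ceiling keeps a single 100+ bp deletion
   cheaper than clipping half the read, which plain affine scoring does
   not guarantee near read ends. Traceback is deterministic (M over D
   over I on ties, leftmost optimum). The inner loop is C++; scores are
   verified against an independently formulated R oracle.
3. **Extraction and grouping** (`extract_indels()`,
   `call_alleles()`): I/D runs become events, adjacent runs merge into
   COMPLEX events, and simple events are left-aligned to the smallest
   coordinate preserving the haplotype, so identical biological events
   from different reads collapse to one allele signature. Events lying
   entirely more than 10 bp from the predicted cut (configurable
   `window`) are flagged as unlikely to be Cas9-induced and excluded
   from frequencies. Reads sharing a normalised signature form an
   allele; frequency is supporting reads over mapped reads; alleles
   with fewer than 5 reads or below 1 % frequency are dropped as noise.
   The thresholds are defaults chosen to sit well below the frequencies
   a transmissible allele needs while suppressing polymerase/sequencing
   artefacts; both are arguments.

Base qualities are carried through but not used in calling; the caller
relies on the noise thresholds instead. Read 2 is ignored by default
(the amplicon design guarantees read 1 covers the cut); paired-end
merging is out of scope. Externally aligned reads enter through
`import_alignments()`, which maps SAM/BAM files to samples and amplicons
via a YAML run configuration and feeds the identical extraction and
grouping code, giving a parity path for users who prefer a dedicated
mapper.

## Screening statistics

`tissue_concordance()` compares germline (sperm) and somatic (fin)
results per individual and guide: the per-guide Pearson correlation of
percent-reads-with-indel, the count of fin-only samples (≥ 1 retained
fin variant, none in sperm), and variant sharing, where identity is the
exact left-aligned `(amplicon, pos, ref, alt)` signature. Because "total
variants" can count either per tissue-sample occurrence or per unique
signature, both accountings are reported (`total_occurrences`,
`total_unique`).

`wilcoxon_rank_sum()` implements the Mann-Whitney U test natively: the
exact null distribution (by the standard counting recurrence) when
`n1 * n2 ≤ 400` and the data are tie-free, otherwise a normal
approximation with tie-corrected variance and a 0.5 continuity
correction — the switching rule of the de-facto standard statistical
environment, so results are comparable with analyses done there. The
exact path is verified against full enumeration for all group sizes ≤ 6,
the approximate path against the reference implementation.

`plate_report()` and the `autoplot()` methods reproduce the operational
readouts: a 96-well tile map of percent reads with indel plus read
totals, and a per-sample variant display relative to the cut site.

## The simulator, and what the tests show

`sim_genome()`, `mosaic_spectrum()`, `simulate_sample()` and
`multiplex_samples()` generate ground-truth data emulating the screen:
i.i.d. genomes at a requested GC content with planted consensus sites;
founder samples as multinomial mixtures of a wild-type allele and indel
alleles at stated frequencies; read 1 of a 150 bp run through the full
barcoded construct (so large deletions genuinely read into the far
adaptor); i.i.d. substitution errors at a MiSeq-like 0.3 % default. The
defaults used throughout the tests — 2,000 reads per sample, 0.3 %
substitution error, frequency grid 0.05–0.9 — are desk-scale versions of
a realistic screen (hundreds of samples pooled on one run, thousands of
reads per amplicon).

The simulator deliberately omits PCR amplification bias and chimeras,
quality-score structure, indel-type sequencing errors (an optional
low-rate mode exercises the noise filters), and paired-end overlap.
Passing the recovery tests therefore shows the pipeline is correct and
unbiased under substitution noise and faithful library structure; it
does not certify accuracy under heavy PCR distortion or degraded input,
where wet-lab replication remains the control. The headline supplementary
counts of the original screen derive from its own sequencing data and are
not recomputable from simulations; the statistics functions accept such
per-sample tables directly when users have them.

## Problem sizes and determinism

The shipped test suite uses 2 kb regions (50 replicates) for site-scan
verification, a 100 kb genome for off-target completeness, 200 random
read/reference instances (including planted 1–120 bp indels) for
alignment optimality, and an 18-point mosaic frequency grid at 2,000
reads per sample for end-to-end recovery — sizes chosen so the full
suite runs in a few minutes while still exercising every code path at
realistic read depths. All randomness is seeded; simulators take
explicit `seed` arguments and are byte-reproducible.
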