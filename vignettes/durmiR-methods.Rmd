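---
title: "durmiR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{durmiR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(durmiR)
```

## What the package does

durmiR re-implements, as a tested and reusable pipeline, a two-pronged
small RNA-seq analysis of durum wheat (*Triticum turgidum* ssp. *durum*)
under water deficit stress:

1. **Conserved miRNA profiling.** Adapter-trimmed reads of 15–50 nt are
   annotated against a mature-miRNA reference set allowing up to two
   mismatches, normalized to reads per million (RPM), and screened with
   explicit differential-abundance rules. Pattern classifiers then label
   each miRNA by genotype preference (groups I–IV), tissue predominance and
   stress response.
2. **De novo pre-miRNA hairpin discovery.** Filtered 19–26 nt unique reads
   are aligned to a genome; a locus is nominated wherever one read has a
   perfect alignment facing an imperfect (2–5 mismatch) alignment on the
   opposite strand at an inner-edge distance of 54–1000 bp. Nominated
   regions (±20 bp) are folded, gated on miRNA-biogenesis plausibility, and
   classified into the eight coverage categories A–H by three Boolean
   metrics. Category-A hairpins finally enter a moderated linear-model test
   of the tolerance × treatment interaction.

The experimental design behind both approaches is factorial: genotypes
(each either water-deficit *tolerant* or *sensitive*, recoded 0/1) × two
tissues (flag leaf, developing head) × two treatments (control, water
deficit) × biological replicates. The full study layout is 4 × 2 × 2 × 6 =
96 libraries (`make_design()` with defaults); tests and the example
workflow use a reduced 2 × 2 × 2 × 3 layout to stay fast.

Because the original sequencing data and the wheat survey-sequence
reference are far beyond desk scale, the package ships a synthetic-data
generator that emulates the study with known ground truth, and every claim
the test suite makes is a property checked against that truth or against an
independent brute-force oracle.

## The synthetic study generator

`simulate_study()` builds, from one master seed:

* a uniform-random genome (`make_genome`);
* planted pre-miRNA hairpins (`plant_hairpins`): mature arm (21 nt) + loop
  (54–90 nt, matching the discovery gap window) + star arm, where the star
  arm is the reverse complement of the mature arm carrying 2–4
  substitutions placed ≥2 nt from the arm ends and in runs of at most 2 nt.
  The substitution count sits inside the 2–5 mismatch window the discovery
  stage accepts; runs ≤2 keep the imperfections the size of the small
  bulges and interior loops seen in genuine miRNA/miRNA\* duplexes, which
  is what the structural gate (below) tolerates. Five substitutions are
  allowed by configuration but can push a duplex past the gate's
  `mature_unpaired <= 4` threshold, so the default stays at 2–4;
* negative-binomial counts per hairpin and library (`simulate_counts`),
  with log-link factorial means: baseline × 2^(tolerance·β_tol +
  tissue·β_tis + treatment·β_trt + tolerance·treatment·β_int). The
  literature reports no distributional model for these libraries; the
  negative binomial is the standard overdispersion model for small RNA
  counts and gives the interaction test something honest to detect. The
  per-genotype abundance offsets enter through the binary tolerance class
  (β_tol), since the analysis model itself only sees the tolerance
  recoding; in a reduced two-genotype design a per-genotype offset would be
  aliased with it anyway;
* reads: each hairpin's library count is split by its truth category's
  signature into mature-arm, star-arm, loop and antisense reads, each
  emitted as insert + 3' adapter truncated to the read length (36 nt,
  constant qualities). Contaminant reads (exact substrings of labelled
  rRNA/organellar/vector/repeat references) are mixed in at a configured
  fraction, plus optional breakdown products of longer transcripts,
  low-abundance junk, and a singleton random "background" class
  (`n_background`) that emulates the unannotated bulk of a real library.

**Category signatures.** The three Boolean metrics are: (1) ≥95% of reads
on one strand; (2) ≥95% of reads in one terminal 50 bp window; (3) ≤5% of
reads in the loop. The generator's per-category read mixtures keep a safety
margin from these thresholds (e.g. the true-miRNA signature A uses 97.5%
mature, 1% star, 1% loop, 0.5% antisense) so that multinomial sampling at
realistic depths does not flip a truth category. Because each read is
assigned to exactly one subregion, ≥95% in one terminal window forces ≤5%
in the loop: the combinations B (Y,Y,N) and F (N,Y,N) are unrealizable
under this read-assignment definition, and the generator refuses to plant
them. `assign_category()` still maps all eight Boolean combinations.

**What the generator does not emulate.** No sequencing-error model beyond
structure (qualities are constant), no 5'/3' isomiR heterogeneity, no
genomic repeat structure, no GC bias, no real contaminant sequence
families. Passing tests therefore demonstrate that the pipeline's logic is
correct under its stated assumptions — not that those assumptions hold for
any particular real library.

## Pre-processing

The cascade follows the printed order: adapter trimming (a read is trimmed
at the earliest ≥8 nt exact match to a prefix of the 3' adapter; reads with
no match form the untrimmed partition), N-containing reads dropped (the
package's stand-in for an unspecified "low-quality" rule — a declared
approximation), length partitioning (19–26 nt for hairpin discovery, 15–50
nt for conserved profiling), unique-read collapsing, then removal of rows
that are (a) low abundance (total ≤5 across all libraries), (b) ungapped
≤2-mismatch hits to any contaminant class, or (c) hits to ≥50 bp contigs
assembled de novo (k = 17) from the untrimmed partition plus the unique
reads — the breakdown products of longer transcripts. The assembler is a
minimal de Bruijn unbranched-path walker: the assembly exists only to build
a filter reference, so bubble popping and read tracking are deliberately
out of scope. Assembly runs before contaminant filtering would matter only
for reads removed by both; the package assembles from the pre-contaminant
table, following the order in which the steps are described.

Ungapped mismatch-bounded mapping (`map_ungapped`) is exhaustive over
offsets and strands with no indels; it is implemented on
`Biostrings::matchPattern` and cross-checked in the test suite against a
brute-force Hamming scanner written independently in plain R.

## Conserved profiling rules

All thresholds live in `de_criteria()`:

| parameter | default | meaning |
|---|---|---|
| `zero_floor` | 0.01 RPM | substituted for exact zeros before fold changes |
| `min_rpm` | 10 RPM | required in at least one member of a compared pair |
| `fc_threshold` | 1.5 | fold change must strictly exceed this |
| `candidate_min_rpm` | 2 RPM | candidate rule: strictly exceeded ... |
| `candidate_min_fraction` | 0.5 | ... in at least this fraction of libraries |
| `annot_max_mismatch` | 2 | annotation mismatch budget |

Pairwise comparisons use the mean RPM across the replicate libraries of a
factor cell; whether the original analysis used means or pooled counts is
not stated, so the choice is declared here. The candidate rule, in
contrast, counts individual replicate libraries, as its wording refers to
the full set of libraries. Fold changes are reported as max/min with a
direction flag, so swapping the inputs flips direction and nothing else.

"Predominantly expressed" is operationalized over *called* comparisons
only, because the printed pattern tables contain blanks (fold change below
1.5 or undetermined at low abundance): group I/II require every called cell
to favor the tolerant/sensitive class respectively (at least one called
cell); groups III/IV require a direction flip between control and stress
with at least one called cell per treatment; tissue predominance requires
at least 6 of the 8 genotype × treatment strata called, all in one
direction. Strata that cannot be called contribute a log2 fold change of
zero to the stress-response matrix, mirroring how undetermined cells enter
the clustering displays.

## Hairpin discovery

* **Alignment.** Perfect hits are 0-mismatch ungapped occurrences on either
  strand; imperfect hits carry 2–5 mismatches — 1-mismatch hits are
  excluded, exactly per the printed range. The imperfect scan is restricted
  to the reads and contigs involved in perfect alignments.
* **Pairing.** "Separated by 54–1000 bp" is read as the inner-edge gap
  between the two alignment intervals (the prospective loop plus spacer),
  not a center-to-center distance: 54 bp is a plausible minimal loop span
  but absurd as a center distance for 19–26 nt arms. Same-read pairing is
  used ("of a given read"); duplicate regions are collapsed, keeping the
  perfect hit with the highest read support as the mature-arm
  representative.
* **Folding.** `fold_hairpin()` computes an optimal nested structure by
  dynamic programming over Watson–Crick plus G·U wobble pairs with minimum
  loop 3 nt, scoring `pair_score` (default 2) per pair minus
  `helix_penalty` (default 5) per helix opening. The penalty term matters:
  plain maximum base pairing lets the abundant short helices of random
  sequence outcompete the genuine arm-to-arm duplex, which defeats any gate
  built on the global structure. With `helix_penalty = 0` the scorer
  reduces to plain maximum pairing. The DP is verified against exhaustive
  enumeration of all nested structures for sequences up to 14 nt. This is a
  fold-back plausibility model, not an energy model: no thermodynamic
  parameters, multiloop terms or pseudoknots.
* **Structural gate.** `mircheck_like()` checks four mature-arm statistics,
  computed from the best antiparallel duplex the mature arm can form with
  any other same-length window of the hairpin (the direct operationalization
  of "forms a miRNA/miRNA\* duplex"): unpaired mature bases ≤ 4, largest
  internal unpaired run (bulge) ≤ 2 nt, an opposite-arm window exists, and
  ≥60% of the mature arm paired within that single duplex. On shuffled
  controls of planted hairpins the gate rejects ≥95% (the expected minimum
  Hamming-type mismatch count of a 21-nt arm against ~130 nt of random
  sequence is far above 4).
* **Coverage metrics.** Terminal windows are the first and last 50 bp of
  the candidate region; the loop is everything strictly between them, so
  regions ≤100 bp have an empty loop and metric 3 is vacuously true. Each
  read is assigned to the subregion holding the majority of its bases;
  exact ties go to the terminal window (conservative in favor of metric 2).
  Fractions are read-count weighted.
* **Known vs novel.** A candidate is "known" when any mature reference is
  an exact substring of its sense-strand sequence (U normalized to T);
  forward-strand search by default with `match_both_strands` available,
  since the original search orientation is unstated.

## Interaction analysis

Counts per candidate hairpin (summed over unique reads whose perfect hits
overlap the region) are transformed to log2 counts-per-million with a 0.5
prior count. The CPM denominators should be the *full* library totals (all
putative small RNA reads), not the hairpin-table column sums: in a real
library the hairpins are a negligible fraction of reads, and normalizing by
a hairpin-dominated total feeds any strong interaction back into every
other feature as a compositional artifact. The model per feature is
ordinary least squares on intercept + tolerance + treatment + tissue +
tolerance × treatment; tissue enters as a main effect because all libraries
are analysed together (a per-tissue mode is available by subsetting the
design). Only the interaction coefficient is tested.

Variance moderation follows the standard empirical-Bayes scheme: the prior
degrees of freedom and variance are estimated by method of moments on the
log sample variances (trigamma inversion by Newton iteration, tolerance
1e-8, ≤100 iterations; an infinite-d0 limit is handled when the variances
are effectively constant, and a single feature falls back to the ordinary
t with a warning). The moderated t uses d0 + d_g degrees of freedom; at
d0 → 0 it reduces to the ordinary t. The test suite checks the whole chain
numerically against limma's `lmFit`/`eBayes` on the same inputs. No
mean–variance (voom-style) weights are used — hairpin-level counts are
moderate and the generator's dispersion is configurable; this is a declared
simplification. Multiple testing is Benjamini–Hochberg at α = 0.05 (no
procedure is printed in the source analysis; this is the field default and
configurable), applied within the candidate set under test.

`signature_check()` replaces manual read-coverage inspection with a
deterministic rule: strand bias ≥ 0.98, ≥ 0.90 of reads in the mature
terminal window, and the modal 5' read end accounting for ≥ 50% of the
mature-window reads (crisp Dicer-like processing). These thresholds are
stricter than category A on purpose and are configurable.

## Numerical and scale choices

Identifiers print 1-based inclusive coordinates
(`contig:start-end[mature_start,mature_length]`, ASCII hyphen emitted, en
dash accepted); all internal interval arithmetic is 0-based half-open with
conversion only at the codec and BED boundaries. Test and example problem
sizes — a 30–100 kb genome, 19–40 planted hairpins, 24 libraries, 2,000
features for the statistical calibrations — were chosen as the smallest
sizes at which every property under test is comfortably away from its
sampling noise; all are configurable upward, and the 96-library layout is
one `make_design()` call away. Cascade recall is evaluated over clean
unique sequences abundant enough to clear the ≤5-total rule, since the
abundance filter legitimately removes rarer clean reads.

## Known limitations

* The fold model is combinatorial, not thermodynamic; its helix penalty is
  a tuning constant, not an energy.
* The fold-change rules are threshold rules without replicate-level error
  control; at shallow simulated depth they are visibly permissive, which is
  a property of the rules, not of the implementation.
* Contaminant classes and references are synthetic stand-ins; per-class
  removal tallies are only as meaningful as the reference set supplied.
* The interaction model assumes a common tissue effect across genotypes and
  no tissue × treatment term; with 96 libraries richer models would fit,
  but only the tolerance × treatment contrast is in scope.
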