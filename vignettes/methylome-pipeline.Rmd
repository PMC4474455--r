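---
title: "Methods: bisulfite methylome analysis with anchored mate rescue and monoclonization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bisulfite methylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylace)
```

## Scope

`methylace` implements a complete analysis chain for paired-end
whole-genome bisulfite sequencing (BS-seq) of wild-type and DNA
methyltransferase (DNMT) knockout cells: read simulation, three-letter
alignment with mate rescue, PCR-duplicate removal, per-cytosine
methylation calling, strand-symmetry statistics, discovery of
reduction-resistant methylation regions (RRMRs), binned methylation
profiles of genes and retrotransposons (LINEs, LTRs), and the link
between promoter methylation and expression change. This vignette
documents the model behind each stage, the tunable parameters and their
defaults, and the design decisions taken where several readings were
possible.

## Methylation model and statistics

Bisulfite treatment converts unmethylated cytosine to uracil (read as
T); methylated cytosine stays C. At a cytosine interrogated by `rC`
reads retaining C and `rT` reads converted to T, the methylation rate is

\[ S = \frac{rC}{rC + rT}. \]

Regional ("overall") methylation pools counts across sites,
\( S = \Sigma rC / (\Sigma rC + \Sigma rT) \); it is a count-weighted
rate, **not** the mean of per-site rates, and the test suite pins the
identity `overall_methylation(x) == methylation_rate(sum(rC), sum(rT))`
exactly. Except in strand analyses, the two cytosines of a CG
dinucleotide are combined into one site keyed by the top-strand C.

Strand asymmetry of a CG site with sense/antisense rates
\(S_p, S_n\) is measured by the bias index

\[ BI = \frac{S_n - S_p}{S_n + S_p} \in [-1, 1], \]

with the convention that \(S_n = S_p = 0\) is unbiased (BI = 0) rather
than undefined. Genome-wide symmetry is summarised by the Pearson
correlation of \((S_p, S_n)\) over CG sites with coverage at least 10 on
each strand.

Methylation loss in a knockout relative to wild type is the deletion
index

\[ D_i = \frac{S_{wt} - S_{ko}}{S_{wt}}, \]

undefined (missing) where \(S_{wt} = 0\). An RRMR is a maximal run of at
least `min_run` *consecutive* CG sites, each with \(D_i < 0.3\), where
"consecutive" means consecutive among sites covered above the floor
(combined coverage > 6) in **both** genotypes: uncovered sites are
transparent rather than run-breakers, since coverage gaps would
otherwise shred runs arbitrarily. Run lengths default to 7 for the
DNMT3a/3b double-knockout comparison and 5 for the DNMT1 single
knockout; the scanner treats the length bound as \(\ge\) and it is
configurable. The threshold \(D_i < 0.3\) is strict.

RRMRs are assigned to repeat elements within a gap tolerance (50 bp for
the double-knockout scan, 200 bp for the single knockout) using
`IRanges`/`GenomicRanges` overlap machinery; an RRMR within reach of
several repeats resolves to the nearest, ties broken by larger overlap
and then by coordinate. Class/family/subtype enrichment uses a
two-sided Fisher exact test against the genome-wide element composition
(element counts by default; the sample cross-product odds ratio is
reported alongside, because the conditional-MLE estimate of
`fisher.test` is less familiar to readers of contingency tables). The
test suite cross-checks the p-value against an explicit hypergeometric
enumeration.

## Three-letter alignment with anchored mate rescue

Bisulfite conversion destroys C/T contrast, so alignment uses converted
references: a C→T genome and a G→A genome. In a directional
(Lister-style) library, read 1 reports the converted original strand and
read 2 its reverse complement. Read 1 is C→T-converted and searched
forward on the C2T genome (top-strand fragments) and as its reverse
complement on the G2A genome (bottom-strand fragments); read 2 is
G→A-converted and searched symmetrically. Only these directional
combinations are searched.

Candidates come from exact lookup of disjoint seeds (default length 18,
four seeds per read). Under the mismatch budget — at most 3 mismatches
in the leading 40 bases **and** a summed Phred score at mismatched
positions of at most 140, applied conjunctively — a read with at most
`floor(140/Q)` total mismatches always has one clean seed (pigeonhole),
so the seed search finds every alignment a full scan would; the test
suite verifies exact equivalence against a brute-force scanner on a
repeat-rich toy genome. At most 20 candidates are retained, ranked by
summed Phred at mismatches. Indels are not modelled; the seeds extend by
substitution-only comparison, matching the behaviour of the ungapped
short-read aligners this scheme descends from.

Pairs resolve in three ways. If both mates are unique and concordant
(same chromosome, convergent orientation, fragment length inside the
library window, default [300, 600] bp), the pair passes. If exactly one
mate is unique, it anchors its multi-mapping partner: among the
partner's candidates, those forming a concordant fragment inside the
window survive, and the pair is **rescued** only if exactly one
survives. If several survive the pair is discarded rather than resolved
to the best score — a deliberately conservative policy that avoids
systematically crediting the reference copy of a repeat. The pair score
used downstream is the summed Phred-at-mismatch of both mates (lower is
better); the per-mate Phred budget is applied per mate, both choices
configurable since neither is fully pinned down by convention.

## Monoclonization

Sonication breaks the chromosomes of different cells at effectively
unique positions, so two read pairs whose fragments share *both* end
coordinates (and the bisulfite strand — the two strands are separate
observations and are kept distinct) are PCR copies of one molecule.
`monoclonize()` collapses each such group to one clone, keeping the
best-scoring pair, with score ties broken deterministically by the
lexicographically first read identifier. The operation is idempotent.

The package ships the canonical worked example
(`simulate_pcr_bias_demo()`): one CG covered by three fragments, two
methylated and one unmethylated, so the true rate is 2/3. Amplifying the
fragments 10/10/50-fold distorts the observed top-strand rate to
20/70 ≈ 0.29; collapsing to clones restores 2/3 ≈ 0.67. The bottom
strand, amplified evenly, reads 2/3 throughout. The acceptance script
recomputes both numbers through the full simulate → align → dedup →
call chain.

## Cytosine calling conventions

- Contexts are classified from the reference, not the reads: CG, CHG,
  CHH (H = A/T/C) are exclusive labels, while the overlapping special
  contexts CWG (C[A/T]G), GC and GWC are carried as flags, since a
  cytosine can be, e.g., both CHG and CWG.
- Read bases other than C/T at a cytosine (sequencing errors) are
  excluded from both counts rather than counted as unconverted.
- Mates of one clone overlapping in the fragment middle interrogate the
  same molecule and are counted once per position.
- Internally coordinates are 0-based half-open; the CX-style report is
  written 1-based to match the common dialect.
- CG density of a site is the number of CG dinucleotides within the
  600-bp window centred on it (300 bp each side), focal site included;
  windows truncate as-is at chromosome ends. The ±1 focal-site
  convention is pinned by tests.
- Whether the global coverage floor (> 6) applies per strand or
  combined is not a settled convention; the combined-strand reading is
  the default and the parameter is exposed.

## Element profiles

LINE promoters are the strand-aware interval from 100 bp upstream to
1000 bp downstream of the TSS (a downstream-quarter rule is available
for RRMR overlap work). Element filters are strict (>): LINE promoter
analyses use length > 1500, CG count > 30 and summed site coverage > 50
in every genotype compared; LTR analyses use CG count > 9 and
coverage > 50 over the full element; body profiles use CG > 50/20/15
and length > 3000/1000/300 for genes/LINEs/LTRs. Where a CG-count
threshold is described as a "density" for LTRs, the element CG count is
used — the two are used interchangeably at element scale.

Body profiles cut each element into equal-CG bins (50/20/15 bins for
genes/LINEs/LTRs), ordered 5'→3' in element orientation, remainder
sites to the earliest bins; elements are grouped into ten equal-count
CG-density groups (or three coverage tertiles, GR1–GR3), and bins of
the same ordinal are pooled within a group by the overall-methylation
formula. Gene promoters instead use 40 equal-length 200-bp bins over
TSS ± 4 kb, with genes sorted by FPKM then promoter CG count into 500
equal-count groups. LTR subtypes with more than 50 members are
summarised by the fraction of members in six methylation ranges,
[0, 0.1), [0.1, 0.2), …, [0.4, 0.5), [0.5, 1] — half-open except the
last, closed at 1 — ordered by the top-range fraction, then the second.

## Expression integration

Fold change is log2(TKO/WT): positive means induced upon
hypomethylation. The direction of a "ratio between WT and TKO" is
ambiguous in words; the induced-in-TKO orientation matches the
biology being modelled (methylation-silenced genes reactivating) and a
flag flips it. The filter cascade keeps genes with both FPKM > 0,
FPKM sum > 1 and |log2 FC| ≤ 6, in that order, with per-criterion
removal counts reported. Deregulation is classified at strict
|log2 FC| > 2.5. Subgroup analysis sorts filtered genes by fold change
(or WT FPKM), partitions them into 500 equal-count groups, and reports
per group the median fold change, the pooled overall methylation of all
CG sites within TSS ± 500 bp, the mean promoter CG count and the median
FPKM. The promoter window here (±500 bp) is deliberately distinct from
the ±4-kb profiling window.

## The synthetic-data generator

The generator is first-class, tested code: it is the ground truth every
downstream stage is validated against.

**Genome.** Background sequence is i.i.d. with a chosen GC fraction
(default 0.42, a mammalian-like value). CG islands and feature
interiors are emitted from a token process ("CG" with probability
matched to the target per-600-bp density, otherwise a C-free filler
base), which controls realised CG density tightly — islands hit their
target within ±20% — at the cost of having no isolated (non-CpG)
cytosines inside islands; this does not affect CG-level statistics.
Gene/LINE/LTR features are placed explicitly with declared length,
strand and CG-density class; `duplicate_region()` builds repeat
families with controlled divergence.

**Methylomes.** Each genotype maps feature classes to CG methylation
probabilities. Defaults: WT 0.78 outside CG islands and 0.02 inside
(the high-methylation/low-methylation dichotomy of mammalian genomes);
the DNMT1 knockout (KO1) retains 0.78 only at LINE promoters and drops
to 0.18 elsewhere; the DNMT3a/3b double knockout (DKO) retains 0.78
only at (IAP-like) LTRs; the triple knockout is ≤ 0.01 everywhere. CHH
and CHG cytosines take a genotype CHH rate (0.02 in WT and KO1, where
de-novo activity persists; near 0 otherwise). By default every
cytosine takes its class probability verbatim, which keeps the
probability table exactly reconstructable in tests. For strand-symmetry
studies a site-dispersion option draws each CG's probability from a
two-point mixture (0.03 / 0.90) whose weight matches the class mean —
real methylomes are strongly bimodal, and without between-site variance
a strand correlation would be undefined. In symmetric mode the two
strands share one draw (maintenance methylation copies states across
strands); in independent mode each strand draws separately. The
expected correlation under fully independent strands is not something
the underlying biology pins down; it is a free simulation parameter,
and the acceptance simulation uses a single-class genome for the
independent mode so that feature structure does not itself induce
inter-strand correlation.

**Libraries.** Fragments are uniform over the genome with lengths
uniform on [300, 600] bp — the size-selected range governs the library,
rather than the wider pre-selection shearing distribution — and reads
default to 75 bp. Methylation states are drawn per fragment (per
molecule); unmethylated cytosines convert with probability 0.995
(conversion efficiency within the range expected of a good library;
over-conversion of methylated C is not modelled). Only the directional
protocol is simulated. Sequencing errors are off by default and
available as a substitution rate; base-quality modelling is out of
scope, and emitted qualities are constant Phred 40. PCR bias is an
explicit per-fragment amplification factor — the situation
monoclonization is designed to undo — not a learned sequence
preference. The emitted pair count always equals the summed
amplification factors, and `truth_alignments()` converts the fragment
truth table into a perfect alignment so downstream statistics can be
isolated from aligner behaviour.

**Expression.** `simulate_expression()` draws three gene classes:
induced genes (WT promoter methylation ≈ 0.75 at CG density ≈ 24,
log2 FC clamped above 2.6), a smaller suppressed class with the same
hypermethylated promoters, and unchanged genes (methylation ≈ 0.02,
density ≈ 60, |log2 FC| < 0.5). Per-gene promoter counts are binomial
at ~30 reads per CG so pooled subgroup methylation recovers the class
means. All genes are kept past the FPKM filters by construction so the
class structure survives filtering intact.

**What the generator does not emulate.** Realistic mouse sequence
composition (isochores, repeat landscapes), indels, base-quality decay,
chimeric fragments, over-conversion, copy-number variation, and
sequence-specific (as opposed to fragment-specific) PCR preference.
Passing tests therefore demonstrate correctness of the computational
chain under the stated generative model, not robustness to every
artefact of real libraries.

## Problem sizes and numerical choices

The test and acceptance simulations run at sizes chosen to give the
statistics enough resolution while keeping the suite quick: aligner
oracle equivalence on a 50-kb genome with a five-copy, 1%-diverged 2-kb
repeat and 1000 read pairs; knockout parameter recovery on a 30-kb
genome (6-kb LINE, 1.5-kb LTR) at 30× coverage per genotype with the
real aligner; strand-mode separation on a 130-kb single-class genome at
36× (≥ 5000 CG sites passing the ≥10-per-strand filter); RRMR oracle
equivalence on 10,000 sites; expression integration on 6000 genes and
500 subgroups. Stochastic recovery checks use 3-binomial-SE tolerances
(plus 0.005 for the ~0.5% upward shift that incomplete conversion
imposes on measured rates).

Tie-breaks and edge conventions are deterministic throughout: candidate
lists order by (Phred, chromosome, start); duplicate groups break score
ties by read id; equal-count partitions give remainders to the earliest
groups; methylation-range bins are [lo, hi) except the final [0.5, 1];
empty or degenerate inputs (no coverage, zero variance, zero margins)
return missing values with warnings rather than errors. All randomness
flows through explicit seeds, and reruns are bit-identical.

## Limitations

The aligner is a faithful but simplified model of seeded ungapped
bisulfite alignment: no indels, no quality-aware mismatch weighting
beyond the constant-quality budget, no PBAT or non-directional
protocols. RRMR discovery is threshold-based by design — it is not a
general DMR caller with smoothing or hypothesis testing. Full-scale
results (genome-wide RRMR counts, whole-genome strand correlations,
repeat-composition percentages) require real deposited methylomes and a
RepeatMasker annotation; the package reproduces the machinery and
validates it on synthetic data at desk scale.
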