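---
title: "Methods: detecting and analysing chloroplast RNA editing with plastedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and analysing chloroplast RNA editing with plastedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastedit)
```

## The problem

Chloroplast transcripts of land plants are post-transcriptionally edited at
specific positions, overwhelmingly C-to-U; gymnosperm plastomes additionally
carry a rarer G-to-A class with low editing efficiency, a distinct sequence
context, and a bias toward non-coding regions. Detecting such sites requires
matched DNA and strand-specific RNA sequencing from the *same individual*:
without the matched DNA, a genomic polymorphism between individuals is
indistinguishable from an editing event.

`plastedit` implements the desk side of this analysis: a rule-based caller on
per-position base counts, an indel-rescue path, sense-strand type
classification, consequence annotation, cross-species homology and
gain/loss reconstruction, and cohort statistics. A synthetic-data generator
with planted ground truth makes every stage testable end to end.

## The calling model

The caller consumes a per-position pileup holding, for each genomic
position: the reference base, DNA base counts, and RNA base counts split by
transcript orientation (`fwd`/`rev` relative to the reference plus strand)
and by read pool (`clean` = reads without an indel within `w` bp of the
site, `all` = every read after gap-aware projection). For each position and
orientation a site is emitted when **all** of the following hold on the
clean counts:

1. DNA depth $\geq$ 10 reads;
2. the DNA major allele equals the reference base with fraction
   $\geq 0.95$ — this rejects heterozygous or polymorphic positions, and a
   major allele *differing* from the reference is skipped with an
   assembly-error warning rather than called;
3. RNA depth $n \geq 10$ on the calling orientation;
4. the best non-reference base has $k \geq 3$ supporting reads;
5. a one-sided binomial test rejects sequencing error:
   $\Pr(X \geq k \mid n, e) \leq 10^{-3}$ with per-base error rate
   $e = 0.001$;
6. editing efficiency $k/n \geq 0.05$;
7. strand purity: of the edited-base reads across both orientations, at
   least 90% lie on the calling orientation; below that the site is flagged
   ambiguous and suppressed.

Efficiency is exactly $k/n$ on the calling orientation. These numeric
defaults follow common practice for count-based organellar editing callers
(a handful of supporting reads tested against a 0.1% error floor); each is a
single `caller_params()` field and is exposed as a CLI flag. No
multiple-testing correction is applied by default; with only ~10^5 plastome
positions and $\alpha = 10^{-3}$ combined with the $k \geq 3$ and efficiency
floors, the expected number of error-driven false calls per genome is well
below one (the acceptance suite measures precision directly).

**Indel rescue.** Reads carrying an insertion or deletion at or near an
edited site are excluded from the clean pool, which can push a genuine site
below the RNA-depth or supporting-read thresholds. Positions that pass every
DNA criterion but fail *only* those two RNA criteria are re-evaluated on the
all-reads pool; positions passing the full rule set there are emitted with
`rescued = TRUE`. The rescue is count-based rather than realignment-based:
the pipeline consumes counts, and re-applying the identical rule set on the
wider pool reproduces the masking phenomenon deterministically. A rescue can
never override a DNA-level rejection, and never duplicates a clean call.

**Type classification.** Editing types are expressed on the transcribed
strand: a genomic G→A change inside a minus-strand gene is a C-to-U event.
The strand is read-derived (from which orientation carried the edited
reads); when it contradicts the annotation strand of an overlapping gene the
site is flagged an antisense-transcript candidate and the read-derived
strand kept. Each G-to-A site is additionally marked `gta_supported` when a
called C-to-U site lies within 150 bp (inclusive) on the same strand — a
plausibility check exploiting the observed co-occurrence of the two types.

## Annotation choices

* **Region precedence** for overlapping features is CDS > tRNA > rRNA >
  intron > intergenic; a position inside a gene's span but outside its exons
  is an intron. Exonic sites are labelled `<gene>-<position>` by their
  1-based position in the spliced sense-strand gene sequence.
* **Genetic code**: NCBI translation table 11 (plastid/bacterial). Edits
  creating an ATG are flagged `start_gain` but not re-annotated as CDS
  extensions.
* **Hydropathy**: the partition is configurable; the default hydrophobic
  set is {A, C, F, G, I, L, M, P, V, W}, chosen so that Ser→Leu is
  hydrophilic→hydrophobic while Pro→Leu maintains hydrophobicity —
  the behaviour repeatedly described for chloroplast C-to-U editing. Stop
  gain/loss is its own category.
* **Context**: windows are reported on the sense strand
  (reverse-complemented for minus-strand sites) with circular wrap-around;
  the position-frequency matrix aggregates all sites of a type. Where a
  published per-type site count is ambiguous, we simply aggregate over every
  site of the type under study.
* Coordinates are 1-based closed intervals throughout (GFF3 convention);
  features spanning the origin of a circular plastome are expected split
  into two exons, matching GenBank deposition practice.

## The synthetic-data generator

The generator is the package's study-condition stand-in for real matched
sequencing data. Defaults (all `sim_config()` fields) describe a mid-size
gymnosperm experiment and were fixed once:

* 120 kb circular genome at 37% GC — the middle of the observed gymnosperm
  plastome range (110–165 kb, 34.7–39.7% GC);
* 40 CDS (one intron in 20% of them), 10 tRNA, 4 rRNA genes, both strands,
  with intergenic gaps;
* 150 C-to-U and 6 G-to-A sites per genome, matching the heavily edited end
  of the per-species range; 79% of C-to-U and 32% of G-to-A sites coding;
* efficiencies Beta(8,2) for C-to-U ("highly efficiently edited") and
  Beta(2,8) for G-to-A ("generally low");
* codon-position weights 0.45/0.45/0.10 for coding C-to-U sites (the 1st+2nd
  position skew), a 0.65 pyrimidine probability at the −1 sense position of
  C-to-U sites (">65% pyrimidine") and a 0.55 A probability for G-to-A
  ("A-dominant");
* Poisson 50× DNA and RNA depth, 0.1% per-base error, 30% relative RNA
  coverage in intergenic space and 2% antisense leakage within genes;
* 40 heterozygous DNA decoys (50/50 alleles, mirrored in the RNA) that a
  caller ignoring the DNA would miscall;
* 8 indel-adjacent sites whose clean counts keep only 10% of reads, which
  defeats the clean-pool caller and exercises the rescue path.

Counts are simulated directly rather than via reads: the pipeline consumes
counts, so read-level artefacts (mapping bias, soft-clipping, adapter
read-through, paralogous mismapping from IRs or nuclear transfers) are *not*
emulated. Consequently, passing tests demonstrate the correctness of the
rule set and estimators on honestly noisy counts — not robustness to
alignment artefacts, which on real data are handled upstream of the pileup.
RNA-level polymorphism (as reported at rrn23) is represented simply as
partial efficiency.

## Cross-species homology and intersections

Sites are keyed across species by (gene, alignment column): each site's
spliced-gene position is projected through the per-gene multiple alignment.
Alignments are *inputs* (any aligner); a small Needleman–Wunsch (match 1,
mismatch −1, gap −2) and a consensus-based progressive wrapper are included
only so tests are self-contained. When alignments are gapless the column
key reduces to the per-gene nucleotide index. Lineage membership uses
any-member semantics (a lineage carries a homologous site if any member
species does), and species lacking a gene are recorded as missing (`?`)
rather than absent — missing lineages are excluded from a column's
intersection key, keeping gene loss (e.g. the *ndh* complex in Pinaceae and
Gnetales) distinct from editing loss.

## Gain/loss reconstruction

Presence/absence characters evolve under a two-state continuous-time Markov
chain with gain rate $g$ (0→1) and loss rate $l$ (1→0):
$$P_{01}(t) = \pi_1(1 - e^{-(g+l)t}), \qquad
  P_{10}(t) = \pi_0(1 - e^{-(g+l)t}), \qquad \pi_1 = \tfrac{g}{g+l}.$$
The likelihood is computed by Felsenstein pruning with missing entries
contributing a partial likelihood of 1 for both states; the root prior
defaults to the stationary distribution. Rates are fitted by bounded
L-BFGS-B on log rates from the fixed start $g = l = 1$ (deterministic).
Optional K discrete rate categories (equal weights, mean-one exponential
quantile midpoints) provide a light-weight analogue of mixture gain/loss
models; the full mixture machinery of dedicated tools is deliberately not
replicated, since per-branch gain/loss tallies are reproducible in structure
without it.

Per-branch event counts are posterior *expectations*: for each branch, the
joint endpoint posterior (from an up-down pass) is combined with the
closed-form conditional expected number of 0→1 and 1→0 transitions of the
two-state chain — the transition kernel is a constant plus one exponential,
so the path integral has an explicit form. A seeded stochastic-mapping
sampler (endpoint-conditioned rejection sampling) is included purely as an
independent Monte-Carlo cross-check, and Fitch parsimony (missing states
unconstrained) as a second, minimum-change oracle; the expectation always
dominates the parsimony minimum. Published per-branch integers for such
analyses do not state whether they are expectations, MAP counts or
parsimony reconstructions; this package outputs expectations plus rounded
tallies and documents that ambiguity rather than resolving it.

Numerical notes: rates are bounded in $[e^{-12}, e^{8}]$; an all-absent or
all-present matrix triggers a boundary warning and reports a rate at its
bound; likelihood identifiability under joint rescaling of rates and branch
lengths is covered by a test; multifurcations are resolved arbitrarily
(zero-length branches) before pruning.

## Cohort statistics

`summarize_cohort()` produces the per-species × type count table (totals,
coding sites by codon position and by synonymy, non-coding sites by region)
and enforces its marginal identities (coding = 1st+2nd+3rd = silent +
nonsynonymous; rows sum to totals). The packaged 19-species gymnosperm
summary reproduces the published arithmetic exactly: 1364 C-to-U and 71
G-to-A sites in total, 1082 coding C-to-U sites, and per-species totals such
as 307 for *Ginkgo biloba*. Pearson correlations between editing-site
abundance and plastome features (size, GC/C content, substitution rates) use
the product-moment estimate with the two-sided t-transform p-value on
$n-2$ degrees of freedom, with pairwise-complete deletion and an error on
constant input; the published correlation values themselves depend on
per-species feature tables not shipped here, so the operation is validated
on synthetic features with planted correlations instead.

## Problem sizes used by the tests

The default test and acceptance runs use: five simulated 120 kb genomes for
caller recall/precision (plus one at RNA depth 100 for efficiency error),
2000-site matrices on the packaged 19-tip tree across ten seeds for rate
recovery, 10^4 stochastic-mapping samples on a four-tip toy for the
expected-event cross-check, and exhaustive enumeration oracles on trees of
at most five tips. These sizes give comfortably tight Monte-Carlo and
binomial tolerances while keeping a full run in minutes on one core.

## Known limitations

* The caller is count-based; it cannot detect artefacts that corrupt the
  counts upstream (mis-mapping, strand mis-assignment by the library
  protocol, reference assembly errors beyond a consensus mismatch).
* Inverted-repeat copies are reported as separate genomic positions; no
  IR-aware deduplication is attempted.
* The rescue uses the clean/all count pools; it does not realign reads.
* Gain/loss inference assumes independent sites and a fixed, correct tree.
* The progressive aligner is for tests only and is not a substitute for a
  production multiple aligner.
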