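---
title: "Methods: TCRα repertoire annotation, overlap statistics and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TCRα repertoire annotation, overlap statistics and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrarep)
```

This vignette is the package's own account of its models and numerical
choices: what each stage assumes, which parameters matter and why their
defaults are what they are, what the simulator does and does not emulate,
and where the design was genuinely open.

## The annotation model

A read is assumed to span the V(D)J junction starting at the first base of
the rearranged TRAV and running through the TRAJ.  Assignment is ungapped
and end-anchored: each V ambiguity-group representative is laid on the
read's 5′ end and each J representative on the 3′ end, with candidate
spans shortening the germline by 0–`max_trim` junction-proximal bases to
model exonucleolytic trimming.  Within a group the span with the fewest
mismatches wins (ties to the longer span); across groups, fewest
mismatches, then longest span, then lexicographic group id — a total
order, so assignment is deterministic.  A read is unassignable when no
span stays under the mismatch ceiling (default 10% of the aligned span).
Indels are not modelled: the error process of the targeted amplicon
protocol is substitution-dominated, and the germline segments themselves
do not somatically mutate.

**Ambiguity groups.**  Duplicated TRAV subfamily members can be
byte-identical over the stored sequence and are then inherently
indistinguishable; they are collapsed into one group named by the shared
family–subfamily stem plus the sorted duplication-class letters
(`TRAV06-3ADN`).  Identical sequences in *different* stems are kept
separate with a warning — merging across families would silently change
family-level usage statistics.  The comparison region is the full stored
segment sequence: the reference supplier decides how much of the V is
distinguishable, and the simulator controls read coverage.

**Error correction.**  Germline-encoded positions cannot mutate, so any
read/germline mismatch inside the aligned spans is a sequencing (or PCR)
error — except near the junction, where trimming and N addition make the
germline prediction unreliable.  Corrections are therefore applied only
more than three nucleotides before the predicted V end and more than three
nucleotides after the predicted J start; the three junction-proximal
positions on each side are never touched.  "More than three" is read
strictly (positions 1–3 protected, 4+ correctable).  When the V and J
spans overlap (a junction-free read) nothing in the overlap is corrected
and the read is flagged.  Under this rule a correction can only move a
read towards its pre-error sequence: inside the spans the germline *is*
the pre-error truth, and positions whose attribution is uncertain are
protected.

**CDR3α and N bases.**  CDR3α runs from the first base of the conserved
V-end cysteine codon through the last base of the conserved J F/W/L codon,
inclusive; a read is productive when that junction is a multiple of three,
translates starting C and ending F/W/L, and contains no stop.  The number
of untemplated bases is estimated by maximal germline attribution: the
longest contiguous 5′ stretch matching the germline V is assigned first,
then the longest 3′ stretch matching the germline J over the remainder;
the leftover is the N estimate.  This convention is deterministic but not
unique — a junction base that happens to match a trimmed germline base is
counted as templated, so the estimate is a lower bound on the bases the
recombination machinery actually inserted.  P-nucleotides are not
modelled.  Because deep junctions are unreliable at singleton depth,
clonotypes observed once per sample are removed before any repertoire is
built (threshold configurable via `min_count`).

## Repertoires and their summaries

Clonotypes are keyed by full TCRα identity (V group, J group, CDR3α amino
acids) by default; CDR3α-only and V–J-pair keys are available, and
coarsening a key scheme can only merge clonotypes, never split them.
Segment usage is abundance-weighted (per read) by default, matching
per-cell usage summaries; CDR3α length, N-base and positional amino-acid
summaries default to unique-clonotype weighting, the natural unit when
the question is about *different sequences*.  Both weightings are exposed
everywhere.  TRAV usage axes are ordered by family then subfamily; TRAJ
axes by chromosomal position.  CDR3α positions are numbered 1-based from
the conserved cysteine.  Standard errors are computed across mice at
cohort level, never across clonotypes within one mouse — clonotypes in a
mouse are not independent draws.

## Diversity and overlap statistics

*Accumulation curves* subsample reads without replacement
(`permutations` Monte-Carlo permutations per depth, default 100, seeded);
at full depth the curve hits the observed richness with zero variance by
construction.  *Chao1* uses the classic estimator
S_obs + f1²/(2 f2), switching to the bias-corrected
S_obs + f1(f1−1)/(2(f2+1)) when no doubletons exist.  The richness
estimator behind published bracketed totals is generally unnamed; Chao1
is the standard abundance-based choice and is reported as such.

*Jaccard* is plain set overlap over unique keys.  The *Chao-Jaccard*
abundance-based index estimates, for each sample, the total relative
abundance U (resp. V) of the clonotypes shared with the other sample,
adding a rare-species correction driven by the shared clonotypes that are
singletons/doubletons in the other sample, and returns UV/(U+V−UV).
Numerical conventions: when the doubleton count in the correction term is
zero it is replaced by 1; U and V are clamped to 1 (the estimator can
overshoot); no shared clonotypes gives 0 exactly.  Because U and V weight
shared clonotypes by abundance, a pair sharing its *abundant* clonotypes
scores much higher than its unique-sequence Jaccard — that gap is
diagnostic of repeated, selection-favoured sequences.

*Usage distances* scale counts to a fixed total of 10⁴ sequences, add a
pseudocount (default 1 count-per-10⁴ unit, needed because absent segments
are common) and take log₂; the distance is the Euclidean norm.  Samples
are ordered by average-linkage (UPGMA) clustering of that matrix; linkage
was an open choice and UPGMA is the conventional one for symmetric
distance heatmaps.  Trees are exported as Newick.

*Cohort classes.*  Unordered sample pairs are partitioned into
same/different MHC × same/different TCRβ; self-pairs are excluded from
class summaries.  SEMs over pairs ignore the non-independence of pairs
sharing a mouse — a known limitation, matching common practice.  The
per-V/J-pair CDR3α comparison requires *every* mouse in the comparison to
carry at least five distinct CDR3α sequences for the pair (default
`min_unique = 5`); raising the threshold can only shrink the admissible
set.

## The simulator

The generator reproduces the statistical structure the analysis assumes,
with no mechanistic biology beyond it:

* **Germline pool** — configurable numbers of distinct V and J sequences;
  the first few V sequences are emitted as byte-identical A/D/N alleles to
  exercise ambiguity-group collapsing.  V segments carry the cysteine
  anchor 6 nt before their end; J segments carry the F/W/L-G anchor 12 nt
  from their start, so default trimming (≤ 6 nt) never destroys an anchor
  on the J side and only rarely (by re-rearrangement) on the V side.
* **Rearrangement** — V drawn by accessibility weights; J drawn with
  probability ∝ exp(b·i), i increasing towards the distal end (default
  b = 0.15, a mild distal preference; b = 0 is uniform).  Trimming and N
  addition are censored geometric (defaults: trim p = 0.45 capped at 6;
  N p = 0.2 capped at 12, mean ≈ 3.7).  Non-productive candidates trigger
  re-rearrangement, implemented as batched rejection.
* **Selection** — deterministic hash acceptance: a candidate CDR3α is
  accepted for a genotype iff a 32-bit FNV-1a hash of (genotype key,
  CDR3α), mapped to [0,1), falls below the acceptance rate (default 0.1).
  The genotype key is hashed first so its differing bytes diffuse through
  every subsequent multiply round.  This reproduces the observable —
  identical CDR3α shared deterministically within a genotype,
  ~acceptance-rate chance overlap between genotypes — without inventing an
  affinity model.  An `aa_preference` mode multiplies the rate by a boost
  for configured (length, position, amino acid) motifs, planting
  detectable positional enrichments.
* **Abundance and errors** — distinct clonotypes are weighted by their
  generation multiplicity (convergent rearrangement) times a lognormal
  factor (default σ = 1.5, an uneven, non-Poissonian clone-size
  distribution); reads are a multinomial of the configured depth and
  receive independent per-base substitutions (default 0.002).

Defaults mirror a single-TCRβ mouse cohort: MHC alleles b/f/s crossed
with two TCRβ chains, three mice per genotype.  Depth (5000 reads/mouse)
and per-mouse clonotype draws (300) are desk-scale choices that keep
simulated richness in the few-hundred range while leaving every statistic
well determined; the acceptance checks use cohorts between 400 and 10⁴
reads per mouse as noted in their code.

What the simulator does **not** emulate: negative selection, CD4/CD8
lineage choice, TCRβ pairing energetics, P-nucleotides, indel errors,
PCR amplification bias between TRAV families, and UMI structure.  Passing
tests therefore demonstrate the pipeline's correctness and statistical
behaviour under the stated generative assumptions, not robustness to
every artefact of real amplicon data.

## Numerical choices and degenerate inputs

* Assignment ties are broken (mismatches, span, group id) — see above;
  the mismatch ceiling is 10% of the aligned span.
* An empty repertoire is a valid object; overlap of two empty repertoires
  is undefined and returned as NA with a warning; a disjoint pair is 0.
* `estimate_n_bases` floors at 0; it cannot go negative because the J
  extension is confined to the remainder after the V extension.
* All randomness flows from one master seed through named FNV-derived
  substreams (`reference`, `genotype:<key>`, `abundance:<sample>`,
  `errors:<sample>`, …), so stages can be re-run independently and the
  full pipeline is byte-reproducible.
* Deterministic statistics (hashing, selection) deliberately avoid R's
  RNG so they are stable across sessions and platforms.

## Parameter-recovery caveats

Two identifiability points are worth spelling out because they shape the
package's own tests.  First, once trimming is possible, the *drawn* N
count is not recoverable from sequence: a junction base matching a trimmed
germline base is absorbed by maximal attribution.  The simulator therefore
records, as its per-clonotype ground truth, the canonical
(maximal-V-first) N count computed on the pre-error read — the quantity an
exact annotator should return — alongside the raw draw.  Recovery of the
generative N mean is only a well-posed check with trimming off.  Second,
productivity conditions the N distribution: with the default segment
geometry the fixed CDR3α flanks are 9 + 15 nt, so in-frame junctions need
N ≡ 0 (mod 3), the N bases then form whole random codons, and each codon
survives the stop check with probability 61/64.  The package's checks
compare draw-weighted estimates against that conditional mean, not the
unconditional one; unique-clonotype means are additionally biased upward
when the zero-N candidate space is small enough for repeated draws to
collapse.  The same conditioning touches V usage: although simulated
segments are stop-free in their CDR3α-contributing stretches (as real
coding segments are), V-trimming can create a stop codon where the
truncated tail meets junction bases, making productivity weakly
V-dependent; neutral usage then tracks the productivity-conditioned
accessibility rather than the raw weights.  Usage-recovery checks against
the multinomial oracle are therefore run with V-trimming off and with as
many independent rearrangement draws (10⁴) as the oracle's sampling
distribution assumes.

## Known limitations

Ungapped assignment cannot rescue reads with indels; reads must start at
the V 5′ end (no partial-coverage mode); Chao-Jaccard variance estimators
are not implemented (cohort SEMs across mice serve instead); differential
segment-usage testing is intentionally out of scope — the exported count
tables feed any external differential-abundance tool.
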