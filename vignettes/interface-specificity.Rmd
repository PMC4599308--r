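---
title: "Interface prediction from subgroup specificity: methods and design notes"
author: "SeqHarmony authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface prediction from subgroup specificity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeqHarmony)
```

## The model

`SeqHarmony` predicts homodimer interface residues from sequence by
contrasting two labelled subgroups of one homologous family: an
interacting subgroup H of homodimers and a non-interacting subgroup M
of monomers, aligned together.  The premise is that interaction — and
its absence — is conserved within each subgroup, so positions that
maintain the interface in H but are free to drift in M acquire
systematically different amino-acid compositions in the two subgroups.
Conservation alone cannot find these positions: interface sites are on
average about as conserved as the rest of the surface, and the strongly
conserved positions are the buried core, which both subgroups share.

Two per-column quantities carry the analysis.  Column entropy on a
subgroup's composition, $S_i = -\sum_x p_{i,x} \log_2 p_{i,x}$,
measures conservation (0 = invariant, $\log_2 20 \approx 4.32$ bits =
uniform).  Sequence Harmony measures compositional overlap between the
subgroups:

$$
SH_i \;=\; -\tfrac12 \sum_x p^{H}_{i,x} \log_2
           \frac{p^{H}_{i,x}}{p^{H}_{i,x}+p^{M}_{i,x}}
       \;-\;\tfrac12 \sum_x p^{M}_{i,x} \log_2
           \frac{p^{M}_{i,x}}{p^{H}_{i,x}+p^{M}_{i,x}},
$$

summed over the 20 amino-acid types with $0\log 0 := 0$.  $SH = 0$
means disjoint compositions (complete specificity), $SH = 1$ identical
compositions (complete overlap).  Low-SH columns are predicted as
interface; the two-state predictor uses $SH \le 0.2$, the score's
conventional operating point.

### Numerical conventions

* **Logarithm base.**  All logarithms are base 2.  For SH the base is
  forced by the normalisation: with $p^H = p^M$ every term is
  $\log(1/2)$, and the $-\tfrac12$ prefactors give exactly 1 only in
  base 2.  Entropy uses the same base for consistency, so both scores
  are in bits.
* **Gaps and X.**  The sums run over the 20 canonical amino acids
  only.  Gap characters and `X` are excluded from the counts, not
  treated as a 21st symbol; frequencies are normalised per subgroup
  over its non-gap, non-X residues at that column.  A column where
  either subgroup has no countable residue gets no SH and is excluded
  from prediction and evaluation.
* **Weighting.**  Sequences are counted unweighted.  Redundancy is
  controlled upstream by the identity-clustering filter instead of by
  per-sequence weights.
* **Clamping.**  SH is clamped to $[0,1]$ within $10^{-9}$; a value
  outside that tolerance is treated as a programming error, not
  rounded away.

## Building pair groups

Subgroups come from ranked all-against-all homology hits
(BLAST-tabular input; running the search itself is outside the
package).  For a homodimer query, hits are ranked by ascending
e-value — ties broken by descending bitscore, then subject id, a fixed
rule that makes construction deterministic — with the self-hit removed
and only the first HSP per query–subject pair used.  The **first-cross
rule** takes every homodimer ranked strictly above the query's first
monomer hit as the interacting subgroup (plus the query itself); that
first monomer *anchors* the non-interacting side, whose subgroup is
built symmetrically from the anchor's hit list.  Both subgroups must
reach five members, the minimum for a usable composition.

Two choices here were genuinely open:

* **The query counts toward its subgroup.**  Whether the
  minimum-of-five includes the query is ambiguous; including it
  guarantees the alignment contains the structure-annotated sequence,
  which the evaluation needs, so it is included (and likewise the
  anchor on the M side).
* **Filtering order.**  Identity filtering is applied to the sequence
  sets before group construction, matching the dataset-construction
  order of the workflow this package implements.

Three threshold variants probe robustness of the e-value cut:
`lower_of_two` truncates both subgroups at the lower of the two
first-cross cuts (missing-data stress), `fixed_evalue` uses one fixed
cut (default $10^{-10}$; no cross-class annotation needed), and
`mixed20` relaxes each side's threshold past the first cross until up
to 20 % of the other class is mixed in (label-pollution stress).  For
`mixed20` the *membership* lists carry the polluted assignment — a
mixed-in monomer sits in the interacting subgroup and is scored there —
while the record keeps its true class for bookkeeping; this is what
makes pollution actually degrade the signal, and the truth tables of
the synthetic generator record both labels the same way.

## Sequence-level filters

* Minimum length 50 aa (inclusive).
* Exact duplicates removed within each interaction class (an identical
  sequence may legitimately appear once per class).
* Greedy longest-first identity clustering with presets
  40–100 %: sequences sorted by length descending (ties by id), each
  joining the first representative it matches at or above the
  threshold, representatives returned.  Identity is
  100 × identical aligned positions / shorter sequence length on a
  global alignment (BLOSUM62, gap open 10, extend 0.5) — the
  convention of greedy incremental clustering tools, computed exactly
  here rather than via their word-index heuristics.  A precomputed
  `.clstr` file can be imported instead.

## Evaluation

Query residues are classified from accessible surface area before
association (ASA) and surface area buried on association (BSA):
interface (ASA>0, BSA>0), surface (ASA>0, BSA=0), buried (both 0);
ASA=0 with BSA>0 is physically impossible and rejected.  Residues
lacking annotation or a defined SH column are excluded from numerator
and denominator everywhere.

The default evaluation universe is all classified residues (the task
is to find interaction sites among *all* residues); a surface-only
universe is available for contrasting interface specifically against
the remaining surface.  The two-state predictor yields confusion
counts and recall / FPR / precision, with a metric reported as `NA`
when its denominator is zero.  Threshold-free performance is the ROC
AUC with $-SH$ as predictor, computed by the rank-sum (Mann–Whitney)
formulation with midranks for ties — equal, instance by instance, to
the trapezoidal area under the threshold-swept ROC, which the test
suite verifies against both an exhaustive pair-counting oracle and a
trapezoid oracle.  Midranks are a deliberate choice; the alternative
(optimistic or pessimistic tie-breaking) biases AUC on the heavily
tied score vectors short alignments produce.

Class differences are tested with the classical pooled-variance
two-sample t-test on per-group class means (Welch behind a flag).
Per-group means, not pooled per-column values, enter the test: groups
are the independent sampling units, columns within a group are not.
Degenerate inputs are given explicit semantics rather than an error:
zero pooled variance returns $p = 1$ for equal means and $p = 0$ for
unequal ones.

## The synthetic generator

Real inputs require a structure database harvest plus homology
searches and alignments, none of which belong in a test suite.  The
generator `simulatePairGroup()` instead emulates the *shape* of one
pair group under controlled conditions, deterministically from a seed:

* default sizes $n_H = 25$, $n_M = 14$ — the average observed subgroup
  sizes of the corpus this method targets — and 120 columns split
  roughly 12 % interface / 48 % surface / 40 % buried, matching the
  proportions in the worked structural examples;
* **buried columns**: one dominant residue (default probability 0.95)
  with rare substitutions drawn from a two-letter minor pool *shared
  by both subgroups* — low entropy, high SH, the conserved-core
  pattern.  The shared minor pool matters: drawing substitution noise
  from all 20 letters would make buried columns look spuriously
  specific in small subgroups;
* **surface columns**: both subgroups draw from one shared
  five-residue pool — diverse but overlapping;
* **interface columns**: with probability `specificity` (default 0.6)
  the subgroups draw from disjoint three-letter alphabets (planted
  SH = 0); otherwise the column behaves like surface.

Annotations assign ASA/BSA consistent with the planted classes, and
ranked hits are laid out so the first-cross rule reconstructs the
simulated membership exactly — which the tests assert, closing the
loop from generator through grouping to scoring.

The `specificity` dial is the generator's analogue of the
HSP-informative-divergence effect seen on real data: pair groups
linked by longer HSPs carry more between-subgroup divergence and score
higher AUC, so raising `specificity` should — and, per the tests, does —
raise AUC monotonically in expectation.

What the generator does **not** emulate: phylogenetic correlation
between rows (columns are independent; a star-tree option was
considered and rejected because independence keeps closed-form
expectations checkable), alignment errors and gaps, compositional bias,
and any structural realism in the ASA/BSA values beyond class
consistency.  Tests passing on synthetic data therefore demonstrate
correctness of the machinery and the qualitative orderings —
interface < surface ≤ buried in mean SH, AUC well above chance,
pollution degrading AUC — not the quantitative performance on real
protein families.

## Problem sizes in the test suite

Property-style checks use 100 seeded replicates of the default
generator for the class-ordering and AUC claims, 40 replicates per
setting for the monotonicity and pollution claims, 1000 random
composition pairs for the SH endpoint identities, and instances of at
most 12 residues / 8 sequences for the exhaustive AUC and clustering
oracles.  These sizes give stable Monte-Carlo means (standard error on
mean AUC ≈ 0.005) while keeping the whole suite under half a minute.

## Known limitations

* Alignment is an import boundary: the package consumes aligned FASTA
  produced externally (e.g. MUSCLE with defaults) and does not run
  aligners or BLAST.
* The method needs a non-interacting homolog subgroup; families
  without identifiable monomeric homologs are out of reach.
* "Non-interacting" means loss of the self-interaction only; a monomer
  may well bind other partners, which blurs but does not invalidate
  the specificity signal.
* Exact pairwise identity clustering is quadratic in the number of
  sequences; for corpus-scale inputs, import a precomputed `.clstr`
  instead.

## Session info

```{r}
sessionInfo()
```
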