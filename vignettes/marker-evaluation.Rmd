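---
title: "Evaluating barcoding markers with a naive Bayesian k-mer classifier"
author: "markerNBC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating barcoding markers with a naive Bayesian k-mer classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerNBC)
```

## Scope

`markerNBC` measures how well a DNA barcoding marker resolves taxa at
each rank of a six-rank lineage (phylum, class, order, family, genus,
species, in Greengenes-style prefixed strings). It curates and balances
a reference set, trains a naive Bayesian k-mer classifier with
bootstrap confidence, cross-validates it by exhaustive leave-one-out,
and summarizes per-rank accuracy, per-taxon F1 and cross-marker
problematic-genus diagnostics. This vignette documents the model, its
tunable parameters, the numerical choices, and what the simulation-based
validation does and does not establish.

## The classification model

Training reduces each reference sequence to the **set** of distinct
ACGT words of length $k$ it contains (windows with ambiguity codes are
skipped; abundance is deliberately ignored — presence/absence is the
Wang-style convention this classifier family uses). With $N$ training
sequences, of which $n(w)$ contain word $w$, and $M_s$ sequences in
species $s$ of which $m_s(w)$ contain $w$:

$$P(w) = \frac{n(w) + 0.5}{N + 1}, \qquad
  P(w \mid s) = \frac{m_s(w) + P(w)}{M_s + 1}.$$

Both quantities are strictly inside $(0,1)$, so scores stay finite even
for words never seen in training. A query with distinct word set $V$
receives per-species log joint scores $\sum_{w \in V} \log P(w|s)$,
accumulated in log space throughout (no underflow for queries up to at
least 10 kb). The arg-max species is the point assignment and its full
lineage is reported; classification is species-level only, with higher
ranks obtained by ancestor aggregation rather than per-rank models —
one model serves all six ranks, keeping the reported lineage internally
consistent.

**Bootstrap confidence.** Each of `nBootstrap` (default 100) trials
draws $\max(1, \lfloor |V|/8 \rfloor)$ distinct words (the
`subsampleDivisor` default of 8 gives the conventional "one eighth of
the k-mer set") uniformly *without replacement* — "subsets" of a word
set are naturally replacement-free; a with-replacement switch
(`bootstrapReplace`) exists for comparison. The confidence at rank $r$
is the percentage of trials whose winning species shares the point
assignment's lineage down to $r$. Because agreement at a rank implies
agreement at all shallower ranks, confidences are non-increasing from
phylum to species by construction; the suite asserts this on every
output. Assignments at or above `confidenceThreshold` (default 80%)
count as trusted.

**Tie-breaking.** Exactly tied species scores arise from identical
count profiles (e.g. duplicated training sequences across species
labels). The point assignment resolves ties toward the
lexicographically smallest species key, giving a deterministic headline
call; bootstrap trials resolve ties uniformly at random so that
symmetric ties contribute symmetric votes — two indistinguishable
conspecific-looking species then split the species-level vote near
50/50 while agreeing at genus level, which is precisely the signal the
problematic-genus diagnostics consume.

**Strand.** Queries are scored as given; `checkReverseComplement`
(default off) also scores the reverse complement and keeps the better
orientation. Reference databases and the simulator are
orientation-consistent, so the default avoids spending compute on a
non-issue.

## Curation and balancing

Two filters precede training: completeness (all six ranks present) and
length. "Almost full length" is inherently a judgment call when done by
hand; here it is a reproducible rule — records shorter than
$\max(\texttt{minLen}, \texttt{minFracOfMedian} \times \text{median
length})$ are dropped, with a 50 bp hard floor (the shortest usable
barcode fragment) and fraction 0.5 by default.

Balancing bounds per-species representation: species below
`minPerSpecies` are removed (a species with one sequence can never be
recovered under leave-one-out — its only record leaves no conspecific
training data), species above `maxPerSpecies` are subsampled without
replacement. The presets `2-20` and `5-20` are the two regimes used
when comparing markers: the former keeps sparsely represented species
to probe sensitivity to under-representation, the latter is the
better-balanced evaluation set. Species identity is always the
(genus, species-label) pair, so shared epithets across genera never
collide.

## Leave-one-out cross-validation

`leaveOneOut()` trains once, then for each record subtracts exactly
that record's word presences (`removeSequence`), classifies it, and
moves on — equivalent to retraining on $N-1$ records (the suite checks
field-by-field equality against full retraining and a brute-force
recount oracle) at a fraction of the cost. Records shorter than $k$
cannot contribute words or be classified; they are excluded from
training, reported with a warning, and kept in the output as
unclassified rows rather than silently dropped.

Every query draws its bootstrap randomness from a substream seeded by a
stable polynomial hash of `(seed, query_id)` reduced modulo a prime
below $2^{31}$. Results are therefore independent of record order (the
suite asserts permutation invariance), reproducible across sessions,
and safe to parallelize. All internal orderings (species columns,
per-sequence bookkeeping, balancing iteration) use C-locale radix
sorting so outputs are byte-identical across collation locales.

## Evaluation metrics

- **Assignment rate**: fraction of records with confidence at or above
  the threshold at a rank.
- **Rank accuracy**: among trusted records, the percentage whose
  predicted taxon at the rank equals the true one. Whether the
  denominator should be trusted records or all records is ambiguous in
  common usage, so both are reported (`denominator = "assigned"` or
  `"all"`); the trusted-denominator figure is the headline one.
- **Confusion matrix**: true taxa in rows, predicted taxa plus an
  `unclassified` column; row sums are conserved.
- **Precision/recall/F1** per species, one-vs-rest:
  $P = TP/(TP+FP)$, $R = TP/(TP+FN)$, $F1 = 2PR/(P+R)$ (harmonic mean;
  0 whenever the denominator is 0). Untrusted records count as FN for
  their true species and nobody's FP — "trusted assignment" semantics:
  a withheld call is a miss, not a misassignment. F1 is computed from
  trusted assignments only, consistently with that reading.
- **Genus F1**: unweighted mean of the genus's species F1 values.
- **Scenarios**: with mean F1 per genus per marker, a genus is *poor*
  on a marker when F1 $\le$ 0.25 (the cutoff is configurable; "at or
  below" is used consistently, and a genus exactly at 0.25 is poor).
  Scenario `a`: at least one non-poor marker (flagged when a poor one
  also exists); `b`: exactly one marker with data, poor; `c`: two or
  more markers, all poor — the problematic genera.
- **Divergence diagnostic**: mean ungapped pairwise identity (over the
  shorter sequence's length) within and between species of a genus,
  with a no-barcoding-gap flag when between-species identity reaches
  within-species identity minus `epsilon` (default 0.01). This replaces
  a visual multiple-alignment inspection with a number; since the
  simulator is substitution-only, ungapped identity is exact there. A
  true MSA-based diagnostic is out of scope.

F1 as the harmonic mean (not a precision/recall ratio) is the standard
definition and the one the `caret` package computes; the test suite
cross-checks our per-species scores against `caret` on clean confusion
matrices.

## The simulator

`simulateMarkers()` emulates the hierarchical structure a multi-marker
barcode database presents to a classifier: one phylum/class/order
(matching the single-phylum situation typical of a plant-marker
download), families with independent uniform-random ancestral
sequences, genus ancestors derived by per-site substitution at
`dGenus`, species ancestors at `dSpecies`, individuals at `dIntra`,
substitution-only (an indel-free model keeps the identity diagnostics
closed-form). `dFamily` participates in the required ordering
`dIntra < dSpecies < dGenus < dFamily` as the declared family-level
divergence bound, but family roots are drawn independently (expected
pairwise divergence 0.75), which is what fresh uniform roots give.
*Problematic genera* are constructed by forcing `dSpecies = 0` on the
listed markers: species ancestors collapse onto the genus ancestor and
only independent individual noise remains — by construction there is no
species signal to learn, reproducing the no-barcoding-gap failure mode.
A configurable fraction of species is emitted as singletons to exercise
the balancing filters.

The default preset (`simPreset("paper-like-mini")`) uses three 500-bp
markers, 5 families × 3 genera × 4 species × 8 sequences,
`dGenus = 0.10`, `dSpecies = 0.05`, `dIntra = 0.005`, 10% singleton
species and one problematic genus. These sizes keep exhaustive
leave-one-out (about 1,300 queries across the three markers) in the
minutes range while leaving a comfortable barcoding gap
(interspecific divergence an order of magnitude above intraspecific),
which is what a usable barcode locus looks like. The acceptance tests
run this preset, a two-marker problematic-genus design, 200 random
brute-force-checked instances, and 20 incremental-vs-naive
leave-one-out comparisons.

**What passing on simulated data shows — and does not.** The simulation
validates the machinery: exact agreement with brute-force Bayes
recomputation, exact incremental leave-one-out, correct bookkeeping of
every metric, recovery when a barcoding gap exists, and detection of
genera built without one. It does not establish real-world accuracy
figures: real marker databases have rate heterogeneity along sites and
lineages, indels, mislabelled and chimeric records, uneven taxon
sampling and shared haplotypes from hybridization — none of which the
substitution-only generator produces. Numbers from the simulator
characterize the pipeline, not any particular locus.

## Degenerate inputs and edge behavior

Empty reference sets error at training; empty filter results are legal
(and messaged). Queries shorter than $k$, or whose every window carries
an ambiguity code, are unclassifiable and reported as such. A rank with
no trusted records makes `rankAccuracy()` raise an error rather than
return a silent zero. Removing a species' last sequence removes the
species from the model (and `addSequence` restores it, byte for byte).
The run manifest records package version, parameters, seeds and input
checksums — and deliberately no timestamps, so identical-seed pipeline
runs are byte-identical, which the suite verifies.
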