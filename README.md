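# markerNBC

Evaluating the taxonomic resolution of DNA barcoding markers with a
naive Bayesian k-mer classifier.

## The problem

DNA barcoding and metabarcoding assign sequences of a short standardized
marker (for plants typically chloroplast loci such as *matK*, *rbcL*,
*trnL*, *rpoB*, *psbA-trnH* or *psbK*) to taxa using a reference
database. A marker is only useful at a given rank if interspecific
variation exceeds intraspecific variation (the *barcoding gap*), and in
practice some genera — hybridizing, polyploid or recently radiated
groups — carry essentially identical chloroplast haplotypes across
species, so no classifier can separate them. Deciding **which marker
resolves which taxa, and which genera are intrinsically problematic**
requires a controlled evaluation: curate and balance a reference set,
cross-validate a classifier on it, and summarize accuracy per rank and
per taxon. `markerNBC` packages that whole workflow, together with a
sequence simulator with a controllable barcoding gap so the pipeline can
be validated end to end without any database download.

## The classifier

The core is a Wang-style naive Bayesian k-mer classifier (the approach
behind the RDP classifier and mothur's `classify.seqs`), implemented
natively:

- every training sequence is decomposed into overlapping words of length
  *k* (default 8); windows containing non-ACGT characters are skipped;
- with *N* training sequences, *n(w)* of them containing word *w*, and
  *M_s* sequences in species *s* of which *m_s(w)* contain *w*, the
  smoothed word probabilities are

  P(w) = (n(w) + 0.5) / (N + 1)    (prior)

  P(w|s) = (m_s(w) + P(w)) / (M_s + 1)    (species conditional)

- a query's distinct words *V* give per-species log joint scores
  sum over w in V of log P(w|s); the maximum-score species is the
  assignment (its full six-rank lineage is reported);
- confidence is estimated by bootstrap: 100 random subsets of 1/8 of the
  query's words are re-classified, and the confidence at each rank is
  the percentage of trials agreeing with the assignment's lineage at
  that rank. Assignments at or above an 80% bootstrap value are
  "trusted".

Cross-validation is exhaustive leave-one-out: each sequence is
classified by a model with that one sequence removed (an exact
incremental update, verified against full retraining). Performance is
summarized as per-rank accuracy among trusted assignments, per-species
precision/recall/F1 (one-vs-rest, F1 = 2PR/(P+R)), genus F1 (unweighted
mean over its species), and a cross-marker genus categorization:
scenario **a** (some marker works), **b** (only one marker has data, and
it is poor) and **c** (two or more markers, all poor, F1 <= 0.25 — the
*problematic genera*).

## Worked example

Simulate two 400-bp markers over 2 families x 3 genera x 4 species x 6
sequences, with genus `Gen0101` built with **zero** interspecific
divergence (no barcoding gap), then cross-validate and score:

```r
library(markerNBC)

cfg <- simConfig(markers = c(matK = 400L, rbcL = 400L),
                 nFamilies = 2, generaPerFamily = 3, speciesPerGenus = 4,
                 seqsPerSpecies = 6, problematic = "Gen0101", seed = 11)
sim <- simulateMarkers(cfg)
cc  <- classifierConfig(seed = 42)   # k = 8, 100 bootstraps, 80% threshold

results <- lapply(sim$refsets, function(rs) {
  loo <- leaveOneOut(rs, cc)
  list(acc  = rankAccuracy(loo, "species", 80),
       rate = assignmentRate(loo, "species", 80),
       gf1  = genusF1(speciesScores(confusionMatrix(loo, "species", 80)),
                      genusMap(loo)))
})

results$matK$acc
#>   correct incorrect
#> 97.560976  2.439024
results$matK$rate
#> [1] 0.8541667
results$matK$gf1
#>     genus mean_f1 n_species
#> 1 Gen0101       0         4
#> 2 Gen0102       1         4
#> 3 Gen0103       1         4
#> 4 Gen0201       1         4
#> 5 Gen0202       1         4
#> 6 Gen0203       1         4
categorizeGenera(lapply(results, `[[`, "gf1"), f1Cutoff = 0.25)
#>           genus n_markers n_poor scenario has_poor_marker f1_matK f1_rbcL
#> Gen0101 Gen0101         2      2        c            TRUE       0 0.03125
#> Gen0102 Gen0102         2      0        a           FALSE       1 1.00000
#> ...
```

Reading the output: among the 85.4% of *matK* queries whose species
assignment reached the 80% bootstrap threshold, 97.6% were correct.
Every genus simulated with a real barcoding gap is recovered perfectly
(F1 = 1), while the collapsed genus `Gen0101` scores F1 ~ 0 on both
markers and is categorized scenario `c` — a problematic genus that no
marker can resolve, exactly the failure mode it was constructed to
show. `divergenceDiagnostic(sim$refsets$matK, "Gen0101")` confirms the
cause: between-species identity is as high as within-species identity.

For file-based work, `runPipeline()` (or the subcommand wrapper in
`inst/scripts/marker-nbc.R`) binds the stages — read, filter, balance
(presets `2-20` / `5-20`), leave-one-out, evaluate — and writes every
summary table plus a deterministic JSON run manifest.

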