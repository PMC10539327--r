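# dispersim

Individual-based quantitative-genetic simulation of dispersal evolution in
the red flour beetle (*Tribolium castaneum*), built to infer the genetic
architecture of the trait. Emigration behaviour responds rapidly to
artificial selection in this species, but the response curve alone cannot
tell one locus from ten, a dominant allele from a recessive one, or an
autosomal locus from an X-linked one. `dispersim` re-creates the full
experimental programme *in silico* — truncation selection, reciprocal
crosses between selected lines, and extreme inbreeding through sib mating —
under explicit competing architectures, and scores each scenario against
the published summaries of the real experiments.

## The model

Dispersal is controlled by `L` additive, unlinked, biallelic loci
(`L` ∈ {1, 3, 5, 10}; the single-locus case optionally X-linked, with
hemizygous males). Per locus the genotypic score is 0, `d` (heterozygote)
or 1; an individual's score `s` is the mean over loci, and each dispersal
opportunity succeeds with probability

```
p = h·s + (1 − h)·b        (baseline b = 0.5)
```

so `h = 0` removes all genetic signal and `h = 1` makes behaviour fully
genetic. A `k`-opportunity assay records Binomial(`k`, `p`) dispersals per
individual. Selection lines breed from individuals dispersing on all three
(high regime) or none (low regime) of their opportunities, 30 parents per
generation, cohorts of 200, for four cycles. The evaluation layer scores
simulated trajectories against the published selection-response model
(R² of fixed predictions), analyses simulated cross assays with the
published model structure, and tests inbred-line phenotype distributions
for multimodality with an exact, from-scratch implementation of Hartigan's
dip statistic (Monte Carlo p-values).

## A worked example

```r
library(dispersim)

arch <- genetic_architecture(n_loci = 1, d = 0.5, h = 0.6, A = 0.8)
traj <- run_selection_replicate(arch, regime = "low", seed = 1)
print(traj, digits = 3)
#>   line_id regime generation mean_dispersals allele_freq male_mean female_mean
#> 1      L1    low          1           2.040       0.795      1.87        2.21
#> 2      L1    low          2           1.270       0.360      1.31        1.23
#> 3      L1    low          3           0.795       0.117      0.88        0.71
#> 4      L1    low          4           0.780       0.060      0.75        0.81
#> 5      L1    low          5           0.595       0.000      0.63        0.56
```

Selection against dispersal purges the dispersal allele (frequency 0.795 →
0) and mean dispersals per individual fall from 2.04 to 0.60 of a possible
3 — the low line converges on the non-genetic baseline. Scanning a whole
scenario grid and scoring it against the experimental response model:

```r
scan   <- run_parameter_scan(build_parameter_grid(1), n_repeats = 10, seed = 1)
scores <- score_scan(scan)
scores
#> Scenario fit scores: 100 scenarios
#>   R-squared range: -30.989 to 0.924; 18 scenario(s) at R2 >= 0.80
#>   best fit: 1-locus d = 0.75, h = 0.6, A = 0.6 (R2 = 0.924)
```

Only scenarios with substantial heritability fit the experimental response;
`plot(scores)` draws the dominance-by-heritability fit heatmaps per
founding frequency. Inbreeding under a single locus then predicts a
bimodal outcome, which the dip test confirms:

```r
inb <- run_inbreeding_experiment(arch, n_lines = 250, seed = 1)
inb
#> Inbreeding experiment: 250 lines across 1 architecture(s)
#>   1-locus (d = 0.5, h = 0.6, A = 0.8): terminal dispersers 23-176 (median 158)
set.seed(1)
dip_test(inb$terminal_dispersers, n_mc = 10000)
#> Hartigan dip test of unimodality (Monte Carlo)
#>   D = 0.0540, n = 250, p = 9.999e-05 (10000 null samples)
```

After 11 generations of sib mating, lines have fixed either the dispersal
allele (≈160 of 200 dispersing) or its alternative (≈40), and the dip test
rejects unimodality decisively — the signature that distinguishes a
single-locus architecture from an oligogenic one, where the same experiment
leaves a unimodal distribution (D ≈ 0.02, not significant, under 10 loci).

`run_cross_experiment()` and `fit_cross_model()` cover the third line of
evidence (reciprocal crosses; X-linkage makes sons inherit their mother's
line phenotype), and `run_pipeline(pipeline_config())` chains every stage
into tidy seed-stamped output tables with a JSON manifest.

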