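---
title: "Simulating the genetic architecture of beetle dispersal"
author: "dispersim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the genetic architecture of beetle dispersal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispersim)
```

## The inference problem

Artificial selection on emigration behaviour in *Tribolium castaneum*
produces rapid, repeatable divergence between high- and low-dispersal lines,
but the response curve alone cannot identify how many loci control the
trait, how dominant the dispersal allele is, or whether the locus sits on
the X chromosome.  `dispersim` attacks this identifiability problem by
simulation: it re-creates the full experimental design *in silico* under
explicit, competing genetic architectures and asks which architecture makes
the simulated observables match the published summaries of the real
experiment.  Three lines of evidence are simulated:

1. **Selection response.**  Replicated high/low truncation-selection lines
   tracked for four selection cycles, scored against a published
   fixed-effect model of the experimental response.
2. **Reciprocal crosses.**  F1 cohorts from all four crosses between
   selected lines, assayed per sex; X-linkage predicts that sons express
   their mother's line phenotype, autosomal inheritance predicts reciprocal
   symmetry.
3. **Extreme inbreeding.**  Lines taken through 11 generations of sib
   mating; with one locus the terminal phenotype distribution must be
   bimodal (lines fix one allele or the other), with many loci it stays
   unimodal.  Multimodality is tested with Hartigan's dip statistic.

## The genetic model

An architecture is defined by the number of additive, unlinked, biallelic
loci $L \in \{1, 3, 5, 10\}$, a dominance coefficient $d \in [0, 1]$, a
heritability weight $h \in [0, 1]$, a founding dispersal-allele frequency
$A$ (the same at every locus), and an X-linkage flag (single-locus case
only).  At each locus the genotypic score is

$$s_\ell = \begin{cases} 0 & \text{no dispersal allele} \\
d & \text{heterozygote} \\ 1 & \text{two dispersal alleles,} \end{cases}$$

and an individual's score $s$ is the mean of $s_\ell$ over loci.  X-linked
males are hemizygous: a single X-borne allele gives $s \in \{0, 1\}$ and the
Y contributes nothing.  Each dispersal opportunity succeeds independently
with probability

$$p \;=\; h\,s + (1 - h)\,b,$$

with baseline $b = 0.5$ by default.  This affine map is the package's own
design choice for the genotype-to-phenotype link; it is the simplest map
that (i) abolishes the response to selection at $h = 0$, (ii) keeps stock
populations dispersing at intermediate rates (about $100$–$150$ of $200$
individuals in a 1-opportunity assay across the scanned scenarios), and
(iii) sends an F1 heterozygote with $h = 0.6$, $d = 0.5$ to $p = 0.5$,
matching the within-cross disperser counts near 50 of 100 that the
cross-assay analysis recovers.  There is no mutation, no linkage, no
epistasis, no density dependence and no learning across opportunities:
those are modelling *exclusions*, chosen to isolate the additive
architecture question.

A `k`-opportunity assay draws each individual's dispersal count as
Binomial($k$, $p$); a "disperser" is an individual with at least one
success.

## The simulated experiments

**Selection** (`run_selection_replicate()`, `run_parameter_scan()`).  Each
line founds 200 individuals at frequency $A$, assays them with $k = 3$
(generation 1, the stock behaviour), then repeats four cycles of: select
individuals with 3 dispersals (high regime) or 0 (low regime), cap at 30
parents chosen uniformly, mass-mate by polygamous random union, and assay
200 offspring (deterministic 1:1 sex ratio).  If the qualifying set lacks a
sex entirely — possible at extreme allele frequencies — the single
individual of the missing sex closest to the selection criterion is added,
so lines cannot go extinct; the real experiment's lines never did.  The
scan covers $d \in \{0, .25, .5, .75, 1\} \times h \in \{.2, .4, .6, .8,
1\} \times A \in \{.2, .4, .6, .8\}$, i.e. 100 scenarios per architecture,
with frequencies 0/1 and $h = 0$ excluded since no evolution is possible
there; the lattice is a package choice consistent with the published
constraints (100 combinations; the values named in the source analyses all
lie on it).  Fifty independent high/low pairs are run per scenario.

**Crosses** (`run_cross_experiment()`).  For the best-fitting single-locus
scenario ($h = 0.6$, $d = 0.5$, $A = 0.8$), the parents selected from each
replicate's final assay are re-mated in the four combinations HmHf, HmLf,
LmHf, LmLf (sire line first), each producing 200 offspring (100 per sex)
assayed once.  Per-sex disperser counts out of 100 are analysed by ordinary
least squares (`fit_cross_model()`) with cross type (reference HmLf), sex
(reference female) and optionally their interaction — the mixed model used
for the real data reduces to this because simulated line identity explains
no variance.

**Inbreeding** (`run_inbred_line()`, `run_inbreeding_experiment()`).  Each
line starts from one stock pair; ten successive single-pair sib matings
follow, the last of which produces a brood of 30 siblings; these 30 are
mass-mated (the eleventh inbreeding generation) to give the 200 offspring
that a 1-opportunity assay requires.  Intermediate sibships have 10
offspring with random sexes, redrawn in the rare event of a single-sex
brood — the size is a package choice (nothing larger is needed: what
matters for the heterozygosity decay is the single-pair bottleneck, which
the F-recursion $F_t = \tfrac14(1 + 2F_{t-1} + F_{t-2})$ describes and the
test suite verifies).  No extinction or fecundity depression is modelled;
250 replicate lines per architecture are kept, optionally subsampled to 64
to match the surviving experimental lines.  Founding frequencies for the
inbreeding stage are 0.8 (single locus) and 0.4 (3, 5, 10 loci), with
dominance and heritability taken from the scan's best fit at that frequency.

## Scoring against the published experimental models

Two printed coefficient sets ship as plain-text tables under
`inst/extdata/` (they are data, not code, and can be replaced via
`reference_model(file = ...)`).

The **selection-response model** predicts mean dispersals per individual
(0–3) from an orthogonal second-order polynomial of generation, selection
regime (reference "high"), their interactions, and a two-level block
effect.  The delicate point is the polynomial's normalisation: the
coefficients were estimated in R, whose `poly()` scales basis columns to
unit norm over the *model rows* — 32 lines at each of 5 generations — so
the column value at generation $g$ is $(g-3)/\sqrt{320}$ (linear) and
$((g-3)^2 - 2)/\sqrt{448}$ (quadratic).  Under that basis (the default,
`basis = "design"`) the printed coefficients reproduce trajectories on the
observable scale, high $\approx 1.81 \to 2.31$ and low $\approx 1.93 \to
0.51 \to 1.17$ mean dispersals.  Normalising over the five generation
values instead (`basis = "contrast"`), as one might naively assume, sends
predicted low-line means far outside 0–3, so no simulation could ever fit
them; both codings, and raw powers, are available, with the design coding
as the package default.  Predictions average over the two block levels
because simulations have no blocks.

Scenario fit is $R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2$
(`compute_r_squared()`) over all line-by-generation means of a scenario (50
repeats × 2 regimes × 5 generations in one pooled vector; per-regime values
are also reported).  Because the predictions come from fixed printed
coefficients, this $R^2$ can be negative and can never exceed the $R^2$ of
refitting the same fixed-effect family to the simulated data — an
inequality the test suite checks against `fit_selection_model()`.

The **cross model** predicts per-sex dispersers out of 100 from cross type,
sex and their interaction (references HmLf and female).  Its transfer
$R^2$ onto simulated cross tables (`cross_transfer_r_squared()`) measures
how well the experimental cross outcome matches each simulated
architecture; the package's simulations make the autosomal table fit better
than the X-linked one, which is the directional signature the comparison
exists to detect.  The absolute transfer $R^2$ values computed here (about
0.3 autosomal, 0.25 X-linked) follow arithmetically from the definition
above applied to cell means like the simulated coefficient tables the
package reproduces; figures reported elsewhere for this comparison are
substantially higher and cannot be obtained from those same printed
coefficient tables under this (standard) definition, so the package reports
what its own definition yields and asserts only the ordering and the gap in
its acceptance checks.

## The dip statistic

Hartigan's dip — the sup-norm distance between the empirical distribution
function and the nearest unimodal distribution function — is implemented
from scratch in C++ (`dip_statistic()`), since no dip implementation is
part of the package's dependency set.  It is computed exactly through the
excess-mass identity

$$D \;=\; \tfrac12 \sup_{\lambda \ge 0}\, [E_2(\lambda) - E_1(\lambda)],
\qquad E_m(\lambda) = \max_{I_1, \dots, I_m \text{ disjoint}}
\sum_j \big(P_n(I_j) - \lambda\,|I_j|\big),$$

where $E_1$ and $E_2$ are evaluated in $O(K)$ by dynamic programming over
the $K$ distinct sample values and the supremum is located exactly by
enumerating the breakpoints of the two convex piecewise-linear envelopes.
Ties are handled through the ECDF-with-ties formulation (integer disperser
counts make them routine); constant samples return the lower bound
$1/(2n)$.  The implementation is validated in the test suite against an
independent brute-force oracle that solves the defining minimisation
directly: small linear programmes over every mode configuration of a
convex-then-concave distribution function (including the jump permitted at
the mode and the slope constraints where the convex and concave pieces
meet), exhaustively for all samples of size up to 8 over a small value
alphabet and on random tied and continuous samples.  One property worth
stating because it is often mis-stated: the dip is invariant under affine
maps and reflection but *not* under general monotone transforms —
unimodality of a distribution function is a metric property — which is
precisely why the Monte Carlo null must be simulated (from the
least-favorable uniform distribution) rather than obtained distribution
free.

`dip_test()` draws `n_mc` null samples of the observed size from the
uniform distribution and reports $p = (1 + \#\{D_{\text{null}} \ge D\}) /
(n_{mc} + 1)$, never exactly zero; 10,000 draws resolve $p < 10^{-3}$
comfortably.  A computed null set can be reused across tests of equal-sized
samples (`dip_null_distribution()`), which the calibration test exploits to
verify the nominal 5% size without re-simulating a null per trial.

## Synthetic pseudo-experimental data

`generate_selection_data()` and `generate_cross_data()` build tables with
the statistical structure the analysis layer assumes — model predictions
plus Normal line (or line-pair) intercepts plus residual noise, truncated
to the bounded response scales, with binomial sampling as an alternative
noise family.  Default noise magnitudes follow the printed random-effect
scales (line SD 0.05 for selection; pair SD 10.78 for crosses; residual SD
5 for counts near 50 of 100, the binomial sampling scale).  With all noise
at zero the tables equal the predictions exactly, so round trips through
`fit_selection_model()` / `fit_cross_model()` must return the printed
coefficients to machine precision — the strongest available check that the
generator, the basis and the fitting layer agree.  What these generators
deliberately do *not* emulate: individual-level behaviour, density
dependence, temporal block confounds, or inbreeding depression.  Passing
round-trip and coverage tests therefore certifies the evaluation machinery,
not the biological realism of any particular noise model.

## Randomness and reproducibility

Every top-level run (`run_parameter_scan()`, `run_cross_experiment()`,
`run_inbreeding_experiment()`, `run_pipeline()`, the synthetic generators)
takes one seed and derives an independent substream per (scenario,
replicate, regime) through an exact integer-mixing recurrence, so any
single replicate can be regenerated in isolation — the scan stores nothing
that cannot be rebuilt from (seed, scenario index, replicate index,
regime).  Two runs with the same configuration and seed produce
byte-identical output tables; the pipeline writes a JSON manifest of its
full configuration alongside the per-stage TSVs.

## Problem sizes and numerical choices

The shipped tests run the full study-scale designs where the science needs
them — the complete 400-scenario autosomal scan at 50 repeats, 50-replicate
cross experiments, 250 inbred lines per architecture, 10,000-draw dip
nulls — and scaled-down designs (fewer repeats, smaller grids) where only
the machinery is under test.  Other conventions: R-squared is undefined for
constant observations (an error, not NA); singular cross-model designs
raise an error naming the aliased terms rather than silently dropping them;
the selected-parent fallback adds exactly one closest individual of a
missing sex; single-sex sibships are redrawn; predictions outside response
bounds are truncated and counted in the synthetic generators.

## Limitations

The simulator answers a deliberately narrow question — which *additive*
architectures are consistent with the published summaries — and inherits
the corresponding limits: no epistasis (so it cannot arbitrate claims that
epistatic variance dominates), no genotype-environment interaction, no
maintenance-phase generations beyond the five tracked ones, and coefficient
sets consumed as printed values without their sampling uncertainty (the
random-effect variances are used only to set realistic noise scales in the
synthetic generator).  The dip test's Monte Carlo null is the uniform
distribution, the conventional least-favorable choice; alternative nulls
are out of scope.
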