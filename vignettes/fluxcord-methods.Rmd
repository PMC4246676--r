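---
title: "Methods: transcript-flux concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-flux concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcord)
```

## Scientific question and model

The package asks how far transcript abundance predicts metabolic flux when
two genotypes of the same species are compared — here two oilseed accessions
with contrasting seed composition, labelled **A** (high lipid) and **B**
(high starch). Both data layers are reduced to a common three-letter
vocabulary:

* **T** — higher in the high-lipid accession A,
* **S** — higher in the high-starch accession B,
* **N** — no difference (and **X** — no call possible / conflicting
  evidence, ignored when aggregating).

Concordance is then the agreement of these calls, reaction by reaction,
between the expression side and the flux side.

### Flux side: FBA/FVA under flux-ratio constraints

Fluxes come from a stoichiometric model at steady state. Flux balance
analysis (FBA) solves the linear program

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\;
  lb \le v \le ub,\; v_{num} - r\, v_{den} = 0,$$

where the last family encodes measured flux ratios (e.g. a fixed split
between parallel routes) as extra homogeneous equality rows. Flux
variability analysis (FVA) then fixes the objective at its optimum (the
`optimality_fraction` argument of `fva()`, default `1.0`, relaxes this to a
fraction of the optimum) and minimizes/maximizes every flux in turn, giving
an interval $[v^{min}_i, v^{max}_i]$ per reaction and accession.

A reaction's **flux responsiveness** compares the two accessions bound-wise
on absolute values: a bound is T if $|v_A| > |v_B| + \varepsilon$, S if the
reverse, N if within $\varepsilon$ (`eps = 1e-7` µmol/h; magnitudes below
`1e-9` are snapped to zero first). The two bound calls are combined
stringently: agreement keeps the call, T-with-S conflicts give X, and N is
ignored against a directional call.

### Expression side: exact negative-binomial test

Counts are normalized by **median-of-ratios** size factors (geometric-mean
reference; when no transcript is positive in every sample, the reference
falls back to geometric means over positive counts only, opt-in via
`pseudo_reference = TRUE`). Per-transcript dispersions are method-of-moments
estimates shrunk 50/50 toward a log-log trend fitted to binned means of the
raw estimates (`n_bins = 20`), floored at `1e-8`. The per-transcript test is
the **conditioned exact NB test**: given the total of the two per-condition
sums, the two-sided p-value sums the probabilities of all tables at most as
likely as the observed one. Benjamini-Hochberg adjustment plus a fold filter
gives transcript calls: T/S requires `padj < 0.01` *and* a
more-than-2-fold normalized mean difference (both thresholds are
`pipeline_config()` arguments).

Why the binned trend rather than a per-transcript least-squares fit on
positive raw log-dispersions: dropping non-positive raw estimates before
taking logs selects against low-dispersion transcripts and the log transform
adds Jensen bias, which together understate dispersion and inflate the null
false-positive rate well above nominal. Binning first, with negative raw
estimates included in the bin means, removes the selection effect; the
acceptance suite verifies the resulting type-I rate at nominal 0.05 stays
inside [0.02, 0.07] on 5000-transcript null simulations.

### Aggregation and congruence

Transcript calls are combined **stringently** upward: within a gene, all-T
gives T, all-S gives S, any T/S mixture gives N (conflict); gene calls
combine to reaction calls the same way, with X entries ignored. The
concordance summary counts, over reactions with both a directional
expression call and a directional flux call, how many agree in each
direction.

At transcript-reaction pair level, the **flux-change value**

$$\mathrm{fcv} = \tfrac12\left[(|v^{min}_A| - |v^{min}_B|) +
  (|v^{max}_A| - |v^{max}_B|)\right]$$

is paired with each associated transcript's log2 fold change (transcripts
selected at raw `p < 0.01`); the **congruence score** is $+1$ when the two
signs agree (and the fold change is nonzero), $-1$ otherwise. `export_map()`
writes these as a GML graph grouped by pathway and compartment, with
per-reaction congruence lists and flux directions as node attributes.

A useful invariance: swapping the accessions end to end flips every T/S
call and negates every fold change and flux-change value, but leaves each
pair's ±1 congruence unchanged (both factors negate). Negating the flux
side *alone* flips every congruence sign. Both properties are exercised in
the test suite.

### Metabolite pools

Metabolite measurements are averaged over technical replicates, summed into
pools matching the flux-level grouping, and compared between accessions by
per-pool Welch t-tests at `alpha = 0.05` (no multiplicity correction,
matching the per-compound asterisk convention). `crosstab_flux_metabolite()`
reports the fraction of flux-changed reactions whose linked pool also
shifted.

## Synthetic data generator

`scenario_config()` fixes the study design; all generators are deterministic
given its `seed` (internally offset per generator so the streams are
independent). Defaults and rationale:

| parameter | default | rationale |
|---|---|---|
| `n_reactions` | 200 | enough directional reactions (quota 80%) for stable recovery statistics |
| `n_replicates` | 3 | the two-accession, three-biological-replicate design |
| `transcripts_per_gene_mean` | 4.7 | polyploid genome: several transcript isoforms per gene identifier |
| `n_genes_per_reaction` | 1–3 | typical GPR association breadth |
| `flux_response_fraction` | 0.8 | planted share of T/S-direction reactions (exact quota, `floor`) |
| `concordance_fraction` | 0.8 | planted share β of responsive reactions whose transcripts move congruently |
| `nb_dispersion` | 0.1 | moderate biological overdispersion; `0` gives Poisson counts |
| `effect_log2fc` | 2 | planted 4-fold expression effects, comfortably above the call threshold |
| `metab_cv` | 0.2 | log-normal replicate noise for metabolite values |

`make_model_pair()` re-parameterizes the built-in toy seed-metabolism
network (21 reactions, cytosol/plastid/mitochondrion compartments, 8
pathway groups) with accession-specific biomass compositions, so accession A
genuinely drains more through the lipid route and B through the starch
route; the pair is solved by real FBA/FVA. `simulate_flux_bounds()`
emulates FVA *output* directly at arbitrary scale (interval pairs with the
planted T/S/N direction), because solving hundreds of LP pairs in pure R
for every property run would be disproportionate; the downstream pipeline
is agnostic to which source produced the bounds. `plant_concordance()`
plants congruent expression directions for exactly `floor(β·K)` of the K
responsive reactions and anti-congruent ones for the rest, so β is
recoverable as the +1 share of congruence scores.

Scope and limits: the generator produces two-accession designs only, with
balanced replicates, shared dispersion across accessions, and
gene-level (not isoform-level) planted effects; library-size factors are
drawn near 1. It is built for calibrating and stress-testing this pipeline,
not as a general RNA-seq or kinetic-model simulator.

## Numerical choices

* **LP solver.** `fba()`/`fva()` use the package's own dense two-phase
  primal simplex with Bland's anti-cycling rule (`R/lp.R`). Bounds are
  shifted so all variables are nonnegative, finite upper bounds become slack
  rows, and infinite bounds are capped at `1e6`; a solution pinned at the
  cap with a nonzero objective coefficient is reported unbounded.
  Feasibility tolerance is `1e-9`. The solver is validated in the test suite
  against an independent vertex-enumeration oracle on all small models.
* **Tolerances.** Flux comparisons use `eps = 1e-7` µmol/h with a `1e-9`
  zero-snap; FVA pins the objective row to within `1e-9` of the optimum.
* **Exact test.** The conditioned NB test sums the exact conditional
  probability mass (no saddlepoint or normal approximation); with
  `size = Inf` it reduces to the conditioned binomial (Poisson limit), which
  the tests compare against an independent oracle at `1e-6`.

## Problem sizes

The shipped configuration runs comfortably on a laptop: the toy model (21
reactions) solves by FBA in milliseconds and by full FVA in ~1 s; the
default 200-reaction / ~1800-transcript / 6-sample scenario runs the whole
pipeline in a few seconds; the complete test suite, including the
property-based acceptance criteria, finishes in well under a minute. Pure-R
simplex is the binding constraint: models beyond a few hundred reactions
per FVA call would want a compiled LP backend.

## Workflow

The numbered scripts under `analysis/` reproduce the full study on
synthetic data (`01_simulate.R` → `05_reference_tables.R`, writing
`results/`); `scripts/acceptance.R` recomputes the reference statistics
from the fixture tables shipped under `inst/extdata`. A minimal in-memory
run:

```{r pipeline, eval = requireNamespace("fluxcord", quietly = TRUE)}
cfg <- scenario_config(seed = 42)
sim <- simulate_flux_bounds(cfg)
gpr <- make_gpr(cfg, sim$truth$reaction_id)
truth <- plant_concordance(sim$truth, cfg$concordance_fraction, gpr, cfg)
counts <- simulate_counts(gpr, truth, cfg)
res <- run_pipeline(pipeline_config(sim$bounds_a, sim$bounds_b,
                                    counts$counts, gpr, seed = 42,
                                    outdir = tempfile()))
res$concordance$summary
mean(res$congruence$congruence == 1L)  # recovers the planted 0.8 closely
```

## Limitations

* Steady-state FBA/FVA only — no kinetics, no thermodynamic constraints
  beyond bounds, no integer constraints (no gene-deletion MILP).
* The stringent aggregation discards information by design: one discordant
  transcript silences a gene, one discordant gene silences a reaction.
* The exact NB test conditions on per-condition sums and assumes a shared
  dispersion per transcript across accessions.
* Metabolite tests are per-pool Welch t-tests without multiplicity
  correction, following the field's per-compound significance convention.
* The SBML reader covers the Level-3 `fbc` subset needed for bound/objective
  round-trips, not the full standard.
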