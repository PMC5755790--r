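---
title: "Expression-constrained flux screening of drug therapeutic windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-constrained flux screening of drug therapeutic windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxwindow)
library(dplyr)
```

## The model

A genome-scale metabolic model (GSMM) collects every enzymatic reaction
of an organism with its stoichiometry and gene associations. Assuming
internal metabolites are at steady state, a flux vector $v$ is feasible
when

$$S v = 0, \qquad b^{\min}_j \le v_j \le b^{\max}_j,$$

where $S$ is the stoichiometric matrix over internal metabolites.
Maximizing the flux of the biomass pseudo-reaction over this polytope
(flux balance analysis, FBA) predicts the maximal growth rate. This
package ties three layers on top of plain FBA:

1. **Expression-derived bounds.** The maximal rate of each reaction is
   assumed proportional to the transcript abundance of its most
   abundant associated enzyme. RPKM values are rounded **up** to the
   next multiple of 10 and multiplied by 0.0027 mmol gDW$^{-1}$
   h$^{-1}$ per RPKM, so a 10-RPKM enzyme caps its reaction at 0.027
   mmol gDW$^{-1}$ h$^{-1}$. The constant is the value calibrated
   against the measured growth rate of the A549 lung-adenocarcinoma
   line; the 10-RPKM quantum keeps every bound an exact multiple of one
   constant, which we found (as others have) markedly improves the
   numerical conditioning of the linear programs. Exact multiples stay
   put (10 maps to 10, not 20): the alternative reading would
   contradict the calibrated 10-RPKM value itself.
2. **Competitive-inhibition simulation.** A drug structurally similar
   to a metabolite is assumed to competitively inhibit the enzymes
   that process that metabolite. Given a *relative inhibition* $i$,
   every target reaction's bound is reduced to $(1-i)$ times its
   baseline rate; *relative growth* is the ratio of the re-optimized
   growth rate to the uninhibited one. Scaling the baseline solution
   by $(1-i)$ always remains feasible, so relative growth lies in
   $[1-i, 1]$: 1 means full compensation by alternative pathways,
   $1-i$ means none exist.
3. **Therapeutic-window statistics.** Screening a drug library across
   cancer and healthy expression profiles at fixed $i = 0.9$ yields a
   drug × profile relative-growth matrix; per drug, a two-tailed
   pooled-variance Student t-test contrasts the groups, and
   Benjamini–Hochberg q-values rank candidate windows (drugs that
   impair the cancer profiles more).

## Drug–metabolite analogy

Structural similarity is scored by the Tanimoto coefficient
$|A \cap B| / |A \cup B|$ over substructure-key fingerprints. The key
set is a pinned table of FP4-style SMARTS patterns shipped with the
package (`fp_patterns()`); matching runs through OpenBabel but the
pattern table is versioned here, so fingerprints cannot drift with
toolkit releases. Pairs scoring strictly above 0.9 are analog
candidates, excluding trivial pairs whose canonical SMILES coincide —
a drug that *is* the metabolite cannot act as its competitive analog.
Canonical-string identity is used for that exclusion rather than a
score of 1.0, because distinct molecules can share every key under a
substructure fingerprint.

The biological premise — analogs tend to bind the metabolite's enzymes
— is quantified by shared EC-number counting on annotated pairs,
against a bootstrap null of uniformly random drug–metabolite pairs
(4000 pairs × 1000 replicates by default, drawn with replacement; the
sharing fraction is computed among annotated draws). A Fisher exact
test on the resulting 2×2 table reports both the sample odds ratio
$ad/bc$ and the conditional-MLE odds ratio. EC matching is exact at
all four levels, with dash wildcards (`1.1.1.-`) matching any
completion, since curated sources mix both forms.

## Worked example

The package's synthetic fixtures are first-class, tested code that
emulate the structures the method exploits. The parallel-pathway model
has a nutrient uptake (0.1), an efficient conversion route capped at
0.05, and a backup route consuming two nutrients per product:

```{r}
m <- toy_parallel_model()
fba_max(m)$objective_value
relative_growth(m, "P1", i = 0.9, mode = "single_lp")
```

The optimum routes 0.05 through the efficient pathway and 0.025
through the backup (0.075 total). Inhibiting the efficient route by
90% leaves $0.005 + 0.0475 = 0.0525$, i.e. relative growth 0.70 — the
signature of a partially compensating, less efficient alternative.

```{r, fig.width = 5, fig.height = 3.5}
sweep <- inhibition_sweep(m, "P1", mode = "single_lp")
autoplot(sweep)
```

## Alternative optima

The FBA optimum is almost always degenerate. Following the
random-corner approach, `sample_optimal_vertices()` fixes the biomass
flux at its optimum (relative slack $10^{-6}$, to survive solver
tolerance) and maximizes independent random costs uniform on
$[-1, 1]$, one LP per sample; per-reaction means and standard
deviations summarize the optimal face, and `flux_mse()` scores
predictions against measured fluxes. This realizes "corners of the
optimal face" directly; Markov-chain interior samplers are out of
scope. The exact cost distribution and sample count are knobs, since
the approach is an approximation of the published corner-sampling
algorithms rather than a reimplementation of one.

Baseline rates for inhibition default to the mean absolute flux over
100 sampled vertices (`vertex_mean`), because "the rate in absence of
the drug" is ambiguous under degeneracy; `single_lp` reproduces the
cheapest interpretation (one arbitrary optimal solution). Targets with
zero baseline flux are pinned to zero under any positive inhibition,
avoiding division artifacts.

## The synthetic study conditions

`make_toy_model()` generates networks with $K$ parallel pathways of
unequal stoichiometric efficiency, an optional direct transporter
route for the product, and a housekeeping co-substrate.
`make_profiles()` plants the therapeutic window: cancer-labeled
profiles silence the transporter gene (0 RPKM) — the synthetic
analogue of tumour lines that fail to express a nutrient transporter
and must synthesize the product — while healthy profiles express it
at 20 RPKM. Other genes sit at 10–40 RPKM with Gaussian jitter of
sd 2 RPKM truncated at zero, a modest replicate-to-replicate
variability chosen so that profiles differ without erasing the
planted structure; group sizes default to 4 + 4. These conditions are
fixed: they are what the screening tests and the acceptance script
run on.

What the fixtures deliberately do **not** emulate: genome-scale
network size, realistic transcriptome covariance between genes, and
annotation noise in EC assignments. Passing tests therefore
demonstrate correctness of the algorithms under the planted
structure, not predictive accuracy on real transcriptomes.

Ground truth for every fixture comes from `brute_force_lp()`, an
exhaustive basic-feasible-solution enumeration that never touches the
package's LP path — fixtures are sized at ≤ 8 reactions so
enumeration is instantaneous, with a larger generated model (no
oracle) exercising scaling.

## Numerical choices

* Linear programs are solved by a simplex method behind a wrapper
  that shifts fluxes to non-negative variables, encodes finite bounds
  as inequality rows, and pins the solver's internal randomized pivot
  tie-breaking to a fixed RNG state so identical inputs always give
  identical solutions. Infinite bounds are capped at $10^6$; an
  optimum escaping to that scale on a capped variable is reported as
  `unbounded`.
* The optimal-face slack is relative ($10^{-6}$); assertions on
  relative-growth floors and monotonicity use tolerances of
  $10^{-6}$–$10^{-4}$ accordingly.
* Gene association logic from SBML is flattened to a plain gene set:
  the bound rule only ever consults the most abundant associated
  enzyme, so AND/OR structure would be dead weight. This is a
  documented simplification; complexes whose limiting subunit is not
  the most abundant transcript will be over-bounded.
* Genes present in the model but absent from a profile count as
  0 RPKM, so unmeasured enzymes block their reactions unless another
  associated gene is expressed. Reactions with no gene association
  keep their model bounds by default (`no_gene_policy = "keep"`);
  `"block"` closes them except for a user-supplied exchange
  whitelist, mirroring the restriction of uptake/secretion to
  experimentally measured compounds.
* Reversible reactions get the negated expression bound as lower
  bound by default (both directions are enzyme-limited);
  `reversible_policy = "upper_only"` restores the upper-bounds-only
  reading.
* Drug-target mapping uses both sides of a reaction (substrates and
  products) since a competitive inhibitor blocks the enzyme
  regardless of direction; `substrate_only = TRUE` narrows it. A
  configurable currency-metabolite list (water, protons, ATP-like
  hubs) is excluded from analogy mapping so that hub analogs do not
  target half the network.
* Both entry points for the enrichment table are exposed — a single
  random draw or the bootstrap mean — because either could have
  produced a published 2×2; `fisher_enrichment()` takes plain counts.
* Student's pooled t-test (not Welch) is the default group contrast;
  degenerate zero-variance comparisons return $p = 1$ on equal means
  and $p = 0$ otherwise. BH correction is attached because a real
  screen covers thousands of drugs; raw p-values are kept alongside,
  and `use_raw_p = TRUE` restores uncorrected flagging.

## Problem sizes

The shipped tests and the acceptance script run on the fixture scale:
models of 3–8 reactions (one ~15-reaction generated model for
scaling), 6–8 profiles, a 8-compound library, sweeps of 101–1001 grid
points, vertex samples of 10–100, and bootstrap nulls of a few
hundred replicates. These sizes make exhaustive enumeration and a
dense-matrix simplex entirely adequate; genome-scale models (tens of
thousands of reactions) would need a sparse LP backend, which is a
known limitation, not a design constraint of the method.

## Limitations

* The proportionality constant is assumed equal for all reactions;
  per-reaction constants are a structural extension the `bound_rule`
  container leaves room for.
* Predicting the relative inhibition achieved by a given drug dose is
  out of scope — the simulation quantifies the consequence of a given
  inhibition level, not binding affinity.
* Fingerprints are functional-group keys: homologous molecules score
  1.0. That is adequate (and intended) for analog detection, but the
  score is not a general-purpose chemical distance.
* The SBML layer covers the subset needed here (L3+FBC bounds, gene
  associations, KEGG annotations, L2 kinetic-law bounds and notes);
  it is not an annotation-faithful curation round-tripper.
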