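# habstatus

Plot-level conservation-status assessment of Natura 2000 habitat types,
and tools to evaluate the quality of citizen-science survey data against
expert data.

## The problem

Under Article 17 of the EU Habitats Directive, the conservation status of
protected habitat types is assessed from field criteria recorded on
sample plots (typically 100 m²): a habitat-specific checklist of
**specific structures and functions**, a weighted list of **typical
species** recorded with abundance and vitality classes, and the
**pressures and threats** acting on the plot with their intensity. Each
criterion maps to one of the classes **FV** (Favourable),
**U1** (Unfavourable–Inadequate) or **U2** (Unfavourable–Bad):

* structures & functions: FV if the fraction of checklist items present
  exceeds 1/2, U1 on [1/4, 1/2], U2 below 1/4;
* typical species: a weighted normalized score
  s = Σ w·a·v / Σ w ∈ [0, 1] (ordinal multipliers for abundance and
  vitality), classified with the same thresholds;
* pressures & threats: FV for none or a single low/medium activity, U1
  for up to three low/medium activities, U2 for any high-intensity
  activity or more than three;
* overall plot status: the worst of the three (one-out-all-out).

The monitoring that feeds these assessments is usually done by experts.
When volunteers (citizen scientists) complete the same protocols, their
data must be screened for **accuracy** (are non-expert records
corroborated?), **completeness** (per-plot and as a pooled group — the
"wisdom of the crowds"), low-support outliers (records no second observer
repeated), and **spatial edge bias** (volunteers tend to place plots near
the patch margin, where conditions are degraded). Inference on per-plot
counts uses **permutational ANOVA** (one-way and two-way main effects,
add-one p-values, 5000 permutations by default), which suits the small,
unbalanced designs of such surveys.

Because field data of this kind are rarely shareable, the package ships a
fully deterministic synthetic survey generator — latent condition
gradient towards the patch edge, observer-specific detection
probabilities, seasonal herb detectability, rare false positives,
edge-biased plot placement — so every stage of the pipeline is testable
end to end.

## Worked example

Simulate a default survey (6 expert plots by 2 experts, 30 non-expert
plots by 30 volunteers, in a 100 m square patch) and compare the groups:

```r
library(habstatus)
cfg <- simulation_config(seed = 5)
ds  <- simulate_survey(cfg)

tab <- build_incidence(ds, "structure_function")
perm_anova(per_plot_richness(tab), tab$observer_status,
           n_permutations = 5000, seed = 5)
#> Permutational ANOVA (5000 permutations of plots)
#>  factor df      F p_value
#>  status  1 27.195   2e-04
#> residual df: 34
#> group means: expert 8.500, non_expert 3.967

compare_groups(ds, "typical_species")
#> Expert vs non-expert quality report (typical_species)
#>   plots: 6 expert, 30 non-expert
#>   mean per-plot richness: expert 7.17, non-expert 2.77
#>   completeness: per-plot 0.386, pooled 1.000
#>   accuracy of non-expert records: 1.000
#>   pooled items: 8 shared, 0 expert-only, 0 non-expert-only
#>   flagged (support < 2 observers): none

compare_edge_distance(ds, cfg$polygon, n_permutations = 5000, seed = 5)
#> Edge-distance comparison (permutation test, 5000 permutations)
#>   mean distance to edge: experts 21.38 m, non-experts 2.91 m
#>   observed difference: 18.47 m (two.sided), p = 0.0002
```

The pattern is the signature of volunteer data: individually, non-expert
plots capture far less than expert plots (per-plot completeness 0.39,
status p = 2e-4), yet pooled over thirty observers the group recovers
everything the experts found (pooled completeness 1.0, accuracy 1.0) —
and the volunteers sited their plots an order of magnitude closer to the
patch edge. Per-plot status classes come from `assess_survey(ds)`, one
row per plot with the three criterion classes and the overall class;
`run_pipeline()` runs the whole analysis from a protocol YAML, a
plot-records CSV and a patch GeoJSON, writing CSV/JSON reports plus a
plain-text summary (see the vignette, and `inst/scripts/habstatus.R` for
a command-line wrapper).

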