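# osteostage

Staging analysis for mesenchymal stromal cell (MSC) osteogenic
differentiation time courses, combining three layers of evidence:

- **Metabolic phases.** Extracellular metabolite concentrations sampled
  from spent medium are converted to hourly uptake/secretion rates
  (secretion positive, uptake negative, mmol/L/h) and segmented by
  multivariate **E-divisive** change-point detection: divisive hierarchical
  splitting by the energy-statistic divergence
  `E(A,B) = 2/(mn) Σ‖x−y‖^α − C(m,2)⁻¹ Σ‖x−x′‖^α − C(n,2)⁻¹ Σ‖y−y′‖^α`
  (α = 1, split statistic `Q = mn/(m+n)·E`), with within-segment permutation
  tests at significance level 0.05. Phases are summarized by flux ratios
  (glucose/lactate, glutamine/glutamate, glutamine/ammonia) compared with
  their stoichiometric **expected perfect ratios** (−0.5, −1, −1).
- **Isotope tracing.** Raw ¹³C isotopologue intensities are corrected for
  natural abundance (binomial convolution matrix
  `M[i,j] = C(n−j, i−j) p^(i−j) (1−p)^(n−i)`, inverted by non-negative
  least squares) and reported as corrected distributions and mean label
  enrichment `Σ i·xᵢ/n`, protein-normalized.
- **Regulatory switch.** Differential-expression tables are filtered to a
  response-gene set (p < 0.05 and BH-adjusted p < 0.1, ≥ 2 TPM, |log2FC| ≥ 1,
  relative SEM ≤ 1/2, consistent in ≥ 2 of 3 donors); up- and downregulated
  sets are clustered (Ward, consensus k over silhouette /
  Calinski–Harabasz / Davies–Bouldin), clusters are tested for
  regulator→target prior enrichment (hypergeometric, BH α = 0.1), merged by
  regulator, gated at Pearson r > 0.8 between regulator and mean target
  profile, classified as up/down/transient switches, and assembled into a
  directed TF–TF influence network (SIF / GraphML).

Donor-level data of this kind are typically unavailable, so the package
includes seeded synthetic-data generators for every input with known ground
truth (planted phase boundaries, true isotopologue distributions, planted
regulons with decoy regulators); the test suite validates the pipeline by
recovery against that truth.

## Worked example

The `analysis/` scripts run the whole workflow on synthetic data
(`results/` is created on the fly):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_metabolic_phases.R
Rscript analysis/03_isotope_tracing.R
Rscript analysis/04_response_genes.R
Rscript analysis/05_regulons.R
```

`02_metabolic_phases.R` prints (seed 42):

```
Change points detected at days: 5, 16 (planted: 5, 16 )
Permutation p-values: 0.01, 0.005

Phase flux ratios (vs expected perfect ratio):
 phase               ratio       value expected_perfect_ratio
     1     glucose_lactate  -0.7362792                   -0.5
     ...
```

The two detected change days split the 27-day course into three metabolic
phases exactly at the planted boundaries, each accepted at the given
permutation p-value; flux ratios are phase means of normalized rates, whose
deviation from the expected perfect ratio measures how far the culture is
from complete stoichiometric conversion (e.g. pure anaerobic glycolysis
would give glucose/lactate = −0.5 exactly).

`04_response_genes.R` reports `Response genes: 138 (63 up, 75 down)` with
all 138 planted effect genes recovered and no false positives, and
`05_regulons.R` lists the retained regulons, e.g.

```
    name n_targets correlation direction deg_direction
  TF01.7         7       0.983        up            up
 TF02.10        10       0.987        up            up
 ...
Regulator precision: 1.00 | recall: 0.90
```

Regulon names follow the `<regulator>.<n targets>` convention; every
retained regulon passes the r > 0.8 correlation gate and its switch
direction matches the planted truth. In the same run,
`03_isotope_tracing.R` recovers planted mean ¹³C enrichments to within
0.005 and shows the UDP-glucose M+6 fraction rising (0.36 → 0.55) while
M+11 falls (0.18 → 0.06), the planted glycolysis-up / pentose-phosphate-
down pattern.

Equivalent programmatic entry points: `run_pipeline(pipeline_config(...))`
for the orchestrated run, or the individual functions
(`simulate_metabolite_panel()`, `empirical_rate_panel()`, `edivisive()`,
`phase_summary()`, `build_correction_matrix()`, `correct_distribution()`,
`call_response_genes()`, `select_partition()`, `infer_regulons()`,
`build_tf_network()`, …). See the vignette
`vignettes/osteogenic-staging.Rmd` for the methods.

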