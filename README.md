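# chromacontact

Differential enrichment and contact-region mapping for chromatin
proteomics.

Formaldehyde crosslinking followed by silica-bead chromatin purification
lets a quantitative proteomics experiment ask two questions: *which
proteins* are enriched on chromatin relative to a non-crosslinked
control, and *which parts* of those proteins touch chromatin. The second
question is answered at peptide level: after a first tryptic digestion,
peptides still crosslinked to DNA (the crosslinked fraction) are
separated from peptides released by the digestion (the released
fraction), and the crosslinked-enriched peptides are mapped back onto
protein domains and intrinsically disordered regions (IDRs). This
package implements the downstream analysis for both questions, for
SILAC forward/reverse designs as well as label-free two-group designs,
together with a seeded synthetic-data generator so every stage can be
validated against planted ground truth without the deposited
mass-spectrometry data.

## The statistics at the core

For each feature (protein or peptide) with sample variance s² on d
residual degrees of freedom, an empirical-Bayes prior
σ² ~ scaled-inv-χ²(d₀, s₀²) is fitted by closed-form moment matching on
log s² (the trigamma inverse is solved by Newton iteration). The
moderated t statistic uses the posterior variance

    s̃² = (d₀·s₀² + d·s²) / (d₀ + d),   t = estimate / (s̃·√v),

with v = 1/n for one-sample tests on assembled SILAC log-ratios (forward
experiments contribute log₂(H/L), reverse experiments −log₂(H/L)) and
v = 1/n₁ + 1/n₂ for two-group tests on log-intensities; p-values come
from the t distribution on d₀ + d degrees of freedom and are
Benjamini–Hochberg adjusted. Enrichment calls use two strict tiers:
log₂FC > 1 with adjusted p < 0.01 (highly significant) and adjusted
p < 0.1 (significant). Upstream, intensities are quantile-normalized
separately within each condition group and missing values are imputed by
the rule set appropriate to the design (mean of replicates when at most
two of five are missing; per-column observed minima when a whole
condition is absent). Peptide-to-region mapping counts a peptide as
matching a domain or IDR when it overlaps it or lies at most 10 residues
away.

## Worked example

The packaged scenario plants 50 chromatin binders among 500 synthetic
proteins (log₂ effect size 2), with contact regions inside IDRs, and
runs both analysis levels:

```r
library(chromacontact)
run <- run_pipeline(default_pipeline_config("spacemap", seed = 1))
print(run)
#> <pipeline_run> mode=spacemap seed=1
#>   generate_proteome               500 ->    500
#>   filter_quant_records            500 ->    500
#>   filter_min_evidence             500 ->    492
#>   moderated_t_test_protein        492 ->    492
#>   digest_proteome                 500 ->  51043
#>   filter_min_evidence_peptide   51043 ->  51043
#>   moderated_t_test_peptide      51043 ->  51043
#>   match_peptide_to_regions        971 ->    968

report <- make_report(run)
report$tier_counts
#>     level               tier     n
#> 1 protein highly_significant    49
#> 2 protein        significant     2
#> 3 protein    not_significant   441
#> 4 peptide highly_significant   709
#> 5 peptide        significant   262
#> 6 peptide    not_significant 50072
```

49 + 2 proteins pass the enrichment tiers — the 50 planted binders plus
noise-level stragglers — and 971 peptides are crosslinked-enriched. Of
those peptides, 93% map to an annotated region, overwhelmingly to IDRs
(where the contacts were planted):

```r
report$contact_fractions
#>                    quantity   fraction
#> 1      frac_peptides_mapped 0.92790937
#> 2 frac_peptides_domain_only 0.01029866
#> 3    frac_peptides_idr_only 0.86302781
#> 4        frac_peptides_both 0.05458290
#> 5  frac_proteins_idr_mapped 0.44881890

head(report$composition[order(-report$composition$log2_enrichment), ], 4)
#>    aa freq_query freq_reference log2_enrichment
#> 6   G 0.10871260     0.06738046       0.6901169
#> 4   E 0.10655394     0.06761370       0.6561964
#> 16  S 0.12436290     0.07934074       0.6484223
#> 13  P 0.07921089     0.05805211       0.4483504
```

The amino-acid composition of the crosslinked, IDR-mapped peptides is
shifted toward the disorder-promoting residues (G, E, S, P) relative to
the released peptides — recovering the composition bias the generator
planted in its IDRs.

A bundled worked example of the mapping rule uses the printed
pluripotency-factor coordinates (Oct4 POU-specific domain 131–205,
Nanog homeodomain 96–155, Sox2 HMG box 43–111) in
`inst/extdata/pluripotency_*.tsv`; see `match_peptide_to_regions()`.

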