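---
title: "Models and methods behind chromacontact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromacontact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromacontact)
```

# The analysis problem

Formaldehyde-crosslinked chromatin purified on silica beads yields two
complementary quantitative comparisons. At **protein level**, crosslinked
samples are compared with non-crosslinked controls — by SILAC heavy/light
ratios in a forward/reverse label-swap design, or by label-free iBAQ
intensities — to call chromatin-enriched proteins. At **peptide level**, a
two-step digestion separates peptides that stay crosslinked to DNA from
peptides released by the first digestion; peptides enriched in the
crosslinked fraction localize a protein's chromatin-contact regions,
which are then interpreted against domain and intrinsically disordered
region (IDR) annotations. Both levels share one statistical engine; the
mapping, classification and reporting layers sit on top of it.

# The enrichment model

## Ratio assembly and evidence filtering

In a forward experiment the heavy channel is crosslinked, so the
per-experiment enrichment is $\log_2(\mathrm{H/L})$; in a reverse
experiment the labels swap and the contribution is
$-\log_2(\mathrm{H/L})$. Missing ratios stay missing. The default
evidence rule for the label-swap design keeps proteins quantified in at
least one forward **and** one reverse experiment (at least two assays in
total), which guards against label-specific artefacts; replicated
label-free designs instead use a minimum-replicate rule (default
$k = 2$).

## Normalization and imputation

Label-free intensity matrices are quantile-normalized **separately
within each condition group** (crosslinked columns together, control
columns together), so the normalization never transfers signal between
conditions. Missing cells remain missing and each column keeps its rank
order.

Two imputation rule sets operate on the normalized intensity scale:

* **Protein-level iBAQ rule** — per row and condition, if at most two of
  five replicates are missing they are filled with the mean of the
  observed replicates; if *all* control replicates are missing, each
  missing cell gets its **column's** observed minimum (a per-sample
  detection floor — the column-specific choice mirrors per-run
  sensitivity; a global minimum would ignore run-to-run depth
  differences). Intermediate missingness (3–4 of 5) is left alone and
  such rows fall to the evidence filter.
* **Peptide-fraction rule** — only a fraction whose replicates are *all*
  missing is imputed, again with per-column minima; partial missingness
  is left to the moderated test, which handles unbalanced group sizes.

Imputation runs **after** quantile normalization: imputed minima are
artificial values and should not influence the reference distribution
the observed values are mapped onto.

## The moderated t-test

Per feature with sample variance $s^2$ on $d$ residual degrees of
freedom, the prior $\sigma^2 \sim s_0^2\,d_0/\chi^2_{d_0}$ gives the
posterior variance and statistic

$$\tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d}, \qquad
  t = \frac{\hat\beta}{\tilde s \sqrt{v}},$$

with $v = 1/n$ (one-sample on log-ratios, null mean 0) or
$v = 1/n_1 + 1/n_2$ (two-group on log-intensities), and a t reference
distribution on $d_0 + d$ degrees of freedom. The hyperparameters are
estimated by moment matching on $\log s^2$: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the mean of $e$
determines $s_0^2$ and its excess variance beyond the sampling term
$\psi'(d/2)$ determines $d_0$ through the trigamma inverse, solved by
Newton iteration (tolerance $10^{-8}$, at most 50 steps; in practice
3–6 iterations). Numerical edges are handled explicitly:

* zero or negative excess dispersion gives $d_0 = \infty$, a point-mass
  prior with $s_0^2$ the mean sample variance, and a standard-normal
  reference;
* $d_0 = 0$ recovers the ordinary t-test (useful for comparison, never a
  fitted outcome);
* features with $s^2 = 0$ (e.g. fully imputed rows) remain testable
  because $\tilde s^2 > 0$ whenever $d_0 s_0^2 > 0$;
* a feature with fewer than two informative observations (one-sample),
  or an empty group (two-group), is reported untested with `p = NA`
  rather than dropped silently.

P-values are Benjamini–Hochberg adjusted (`stats::p.adjust`; missing
p-values are excluded from the ranking). Significance uses two strict
tiers — $\log_2\mathrm{FC} > 1$ with adjusted $p < 0.01$, and with
adjusted $p < 0.1$ — so a fold-change of exactly 1 is never called.
Comparative configurations (culture-condition SILAC comparisons,
RNase-treated vs untreated immunoprecipitations) are the same engine
with single-tier calling at the relaxed threshold.

# Mapping peptides to domains and IDRs

All coordinates are 1-based inclusive residue positions. The gap
between a peptide $[p_1, p_2]$ and a region $[r_1, r_2]$ is

$$\mathrm{gap} = \max(0,\; r_1 - p_2,\; p_1 - r_2),$$

i.e. the number of residues separating the closest boundaries; a region
matches a peptide when $\mathrm{gap} \le 10$. The proximity allowance
exists because many DNA-binding domains are rich in lysine and
arginine, so their tryptic peptides are too short to observe and the
observable evidence sits just outside the domain. A peptide may match a
domain and an IDR simultaneously; proteins are summarized as
`domain_only`, `IDR_only`, `both` or `unmapped`, and a peptide matching
both classes counts in `both` rather than being prioritized to either —
near-domain peptides that also sit in an adjacent IDR (the Nanog
situation in the bundled fixture) therefore surface in both views
rather than being silently assigned.

Before matching, same-class annotation matches on the same protein are
merged to consensus regions when their overlap covers at least 0.7 of
the shorter region (iterated to a fixed point, names concatenated). The
0.7 threshold is a package choice — large enough that a short domain
nested inside a long weak match is not swallowed unless they genuinely
coincide — and is configurable. Domain-type ranking counts **distinct
proteins** per general type, with types formed by case-folding and
stripping numeric suffixes (`RRM_1`, `RRM_2` → `rrm`); an explicit
name-to-type map can replace this for ontology-driven grouping.
Amino-acid composition enrichment is computed over residues
(length-weighted, so a 30-mer counts more than a 7-mer) with a
pseudocount of 1 per amino acid per set, and reported as
$\log_2(f_\mathrm{query}/f_\mathrm{reference})$.

# Keyword classification

The three-way category is assigned with strict precedence — known
DNA/chromatin binder if any chromatin keyword hits, else nuclear if any
nucleus keyword hits, else unexpected — mirroring mutually exclusive
reporting categories. Potential true positives (PTP) are proteins with
chromatin-related annotations; potential false positives (PFP) are
proteins whose only hits are in a fixed list of non-chromatin processes
(translation, metabolic process, cell adhesion, protein folding,
protein transport). RBP flagging is independent of the three-way split.
The shipped keyword lists are deliberately compact editable defaults:
published analyses of this kind rely on curated supplementary keyword
lists, and this package does not claim to reproduce any particular one.
Abundance-weighted summaries use relative iBAQ (each protein's share of
summed iBAQ); chromatin-to-proteome ratio classes are quartile bins of
the log iBAQ ratio with stable protein-id tie-breaking, so the
partition is deterministic.

# The synthetic-data generator

The generator exists so that every downstream stage has a recovery
oracle. Its defaults are the packaged study conditions:

| Parameter | Default | Why |
|---|---|---|
| proteins | 500 | enough for stable tier counts, runs in seconds |
| planted chromatin binders | 10% | minority class, as in real chromatomes |
| effect size | log₂FC = 2 | a four-fold enrichment, typical of a strong purification |
| SILAC design | 2 forward + 6 reverse | the asymmetric label-swap layout of the protein-level experiments |
| peptide fractions | 3 + 3 replicates | the crosslinked/released design |
| noise variance | scaled-inv-χ²(d₀ = 4, s₀² = 0.25) | heavy-tailed per-feature variances, the regime moderation is for |
| protein length | log-normal, mean 450 sd 180 | vertebrate-like length distribution |
| peptide length bounds | 7–35 residues | typical MS detectability window |
| missingness | logistic in −log₂ intensity (midpoint 21, scale 1) | low-abundance features go missing more often, matching the minimum-value imputation rationale |

IDR segments are drawn with P/E/S/G boosted 2.5× and hydrophobics
suppressed; domains the reverse — so composition-enrichment recovery is
a falsifiable check. Digestion follows Trypsin/P (cleavage after K/R,
proline not blocking) with up to two missed cleavages; LysC adds no
sites beyond Trypsin/P (K ⊂ {K, R}) and is implemented as that no-op
union, with a LysC-only mode for completeness. One master seed derives
fixed-offset child seeds per stage, so each stage is independently
reproducible.

Because every generated IDR shares one composition profile, the
crosslinked IDR-mapped peptides differ compositionally from the
*released peptide set as a whole*, not from the IDR-mapped subset of it;
the pipeline's composition contrast is defined accordingly. Real IDRs
are heterogeneous, and a real analysis can meaningfully contrast
IDR-mapped crosslinked against IDR-mapped released peptides — the
generator cannot test that finer contrast.

What passing the synthetic suite does **not** show about real data: the
generator plants one contact region per protein, maps every peptide to
one protein (no shared peptides or protein-inference ambiguity),
simulates no ratio compression, requantification artefacts or
between-replicate batch structure, and its annotations are
noise-free — keyword recovery of planted binders is a configuration
sanity check, not a biological claim.

# Problem sizes and calibration checks

The test suite and the acceptance script use sizes chosen to make the
statistical checks sharp while staying desk-scale: a 10,000-feature
null (3 forward + 3 reverse) for the type-I error of the moderated
test (expected 0.05 ± 0.01 at p < 0.05); five independent 10,000-protein
simulations with 10% planted four-fold effects for the realized
false-discovery proportion at adjusted p < 0.1 (expected ≤ 0.15 —
BH controls the *expected* FDP, so single-run values fluctuate and the
check averages over seeds); and 2,000 variances from a known
scaled-inv-χ²(4, 1) prior for d₀ recovery within ±20%. Oracle
equivalence is exhaustive at small scale: digestion against brute-force
substring enumeration on 100 random sequences, interval matching
against an all-residue-pairs check on 1,000 random pairs, BH and
Fisher's exact test against direct-formula/hypergeometric enumeration.

# Known limitations

* The keyword configuration is a default, not a curated resource;
  category fractions on real data depend entirely on the supplied lists.
* The engine covers one-sample and two-group designs only — no general
  design matrices, variance trends, or permutation tests.
* Consensus merging with a fractional threshold is order-stable but the
  0.7 value is a convention; very long low-quality matches can still
  absorb short domains above it.
* The mapping rule treats the ≤10-residue proximity as exact interval
  arithmetic; it does not model crosslink chemistry or distinguish
  direct from bridged contacts.
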