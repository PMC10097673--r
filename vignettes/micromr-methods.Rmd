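---
title: "Methods and design notes for micromr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for micromr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromr)
```

## The model

Two-sample Mendelian randomization estimates the causal effect of an
exposure X (here a gut microbial trait) on an outcome Y (colorectal
cancer risk) using genetic variants Z as instruments, with SNP–exposure
and SNP–outcome associations taken from two independent, non-overlapping
GWASs. The single-SNP estimator is the Wald ratio
$\hat\beta_{XY} = \hat\beta_{ZY} / \hat\beta_{ZX}$; multi-SNP instruments
are combined by fixed-effects inverse-variance weighting, which equals a
zero-intercept weighted regression of outcome betas on exposure betas
with weights $1/se_{ZY}^2$.

Validity rests on three assumptions: the instrument associates with the
exposure (relevance, graded by $R^2$ and F), shares no common cause with
the outcome (independence), and affects the outcome only through the
exposure (exclusion restriction). Microbial traits are an unusually
fragile exposure class — host variants associated with taxon abundance
are few, of modest effect, and plausibly pleiotropic — so the package
treats the sensitivity battery (Egger intercept, weighted median/mode,
heterogeneity, leave-one-out, colocalisation, catalogue screening,
reverse MR) as a first-class part of the design rather than an
afterthought.

Exposure units follow the hurdle convention for zero-inflated 16S taxa:
abundance traits (AB) are zero-truncated, rank-normal transformed, so
effects are per SD; presence/absence traits (P/A) are analysed by
logistic regression, and causal estimates are rescaled by $\ln 2$ to read
as the OR per approximate doubling of the liability to presence.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| genome-wide selection threshold | 2.5e-8 | p-value | mGWAS meta-analysis genome-wide level for the main instruments |
| lenient threshold | 1e-5 | p-value | multi-SNP sensitivity instruments; must be paired with cross-cohort directional consistency |
| palindromic MAF limit | 0.42 | frequency | above this, allele frequency cannot resolve strand ambiguity; applied to both datasets |
| clumping | r² ≤ 0.001, 10 Mb window | — | near-independence for reverse-MR disease instruments |
| coloc priors | p1 = p2 = 1e-4, p12 = 1e-5 | probability | standard single-variant association priors |
| coloc effect priors | 0.15·sd_y (quant), 0.2 (log-OR) | effect SD | standard defaults; sd_y = 1 for rank-normalized traits |
| coloc window | ±1 Mb, inclusive | bp | regional definition around the lead SNP |
| coloc verdict | PP(H4) ≥ 0.80 | probability | conventional evidence bar for a shared causal variant |
| screen threshold | 1e-4 | p-value | 10% Bonferroni over 1000 catalogue results (`derive_threshold()`) |
| screen verdict cutoff | > 10 complex-trait hits | count | explicit knob; the underlying judgement is qualitative |
| bootstrap | 5000 draws, explicit seed | — | SE for weighted median/mode; parametric over per-SNP betas |
| mode bandwidth | phi = 1 × modified Silverman | ratio units | cluster resolution of the weighted mode |
| power | α = 0.05 two-sided | — | asymptotic binary-outcome approximation (below) |

Power uses
$\Phi\big(|\ln OR|\sqrt{N R^2 K(1-K)} - z_{1-\alpha/2}\big)$ with case
fraction $K$. No formula is canonical for this quantity; this standard
asymptotic choice reproduces the design's printed 89% (α = 0.05,
R² = 0.01, OR 1.2, 55,168 cases / 65,160 controls) within a point, which
the acceptance suite checks at ±2 points.

## Harmonization rules

Non-palindromic variants are matched directly, with swapped allele roles
(outcome beta negated, EAF reflected), or after strand complementing; a
complement-plus-swap match is recorded as `outcome_sign_flipped`, since
the sign flip is the consequential act. Palindromic variants are resolved
by frequency alone: concordant if both EAFs fall on the same side of 0.5,
flipped otherwise, and dropped as non-inferable when the MAF exceeds 0.42
in *either* dataset or when either EAF is missing (ambiguity anywhere
invalidates the inference — a deliberately conservative reading). Every
surviving palindromic pair is labelled `palindromic_inferred`, because
frequency inference is always what aligned it; consequently a second
harmonization pass is value-stable and returns `kept` for every
non-palindromic survivor (the property suite asserts exactly this).
Where both datasets report frequencies that disagree beyond what the
0.42 rule resolves, the package does not guess which is right; pairs are
aligned by the stated rule and the frequencies remain visible in the
output for inspection.

## Estimator details

- **Wald ratio SE** is first-order: $se_{ZY}/|\hat\beta_{ZX}|$,
  ignoring exposure-side uncertainty. With the synthetic world's
  meta-analysed instrument (z ≈ 17) this under-covers mildly; the
  acceptance suite measures 95% CI coverage and requires it in
  [0.93, 0.97].
- **IVW** is fixed-effects, as the design specifies; a multiplicative
  random-effects SE inflation is available behind `random_effects =
  TRUE` but off by default.
- **MR-Egger** orients exposure betas non-negative first (required for
  identification), fits weighted least squares with a free intercept,
  and reports t-based p-values on k − 2 df since two parameters are
  estimated. Wald/IVW p-values use the normal reference.
- **Weighted median** interpolates the per-SNP ratio at cumulative
  normalized weight 0.5 (weights $\beta_{ZX}^2/se_{ZY}^2$); with equal
  weights it is exactly the sample median.
- **Weighted mode** maximizes an inverse-variance-weighted gaussian
  kernel density over a 1024-point grid spanning the ratios ±3
  bandwidths; bandwidth is `phi` × 0.9·min(sd, mad)·k^(−1/5), falling
  back to the sd when the mad degenerates to zero, and returning the
  common ratio directly when all ratios coincide.
- **Cochran's Q** uses first-order ratio weights and a χ²(k−1)
  reference.

## Colocalisation numerics

Per-variant log-ABFs, $\tfrac12[\log(1-r) + r z^2]$ with
$r = sd_{prior}^2/(sd_{prior}^2 + se^2)$, are accumulated exclusively in
log space (log-sum-exp), so regions with |z| up to 50 over 10,000
variants do not overflow. H3's sum over discordant variant pairs is
computed as $S_1 S_2 - S_4$ via `log1p(-exp(d))`; if round-off drives the
difference negative it is clamped to zero, with a warning when the
violation exceeds 1e-9 (for a one-variant region the clamp is exact:
there is no discordant pair). Window boundaries are inclusive at exactly
±1 Mb. P/A microbial traits may be declared `cc` or `quant` per region —
both are exposed because the correct choice depends on how the source
scan was run; the pipeline defaults to `cc` for P/A exposures.

## The synthetic world

The generator emulates the study's stated conditions, not a convenient
test fixture: three cohorts (discovery plus two replications) sharing a
true effect; single-SNP instruments calibrated to R² ≈ 0.01 (the study's
instruments explained 0.8–1.6%); hurdle traits with configurable
prevalence (default 0.6); a case-control outcome with case fraction 0.46
(55,168/120,328, scaled down to desk size); a true OR of 1.4 per SD in
causal scenarios; colocalisation regions of 200 variants in LD blocks
(size 10, within-block r 0.8) with causal z = 8. Scenario labels — null,
forward_causal, pleiotropic, reverse_causal, shared/distinct_causal_region
— fully determine which effects are non-zero.

Genotypes use an allele-copying model within LD blocks: each allele copy
either copies the block lead (probability ρ) or is drawn fresh, giving
expected within-block genotype correlation exactly ρ when MAFs match
within a block. The rank-normal transform uses Blom offsets
(rank − 3/8)/(n + 1/4) with first-occurrence tie-breaking.

Two backends exist by design. The individual-level backend simulates
genotypes, traits and outcomes and runs real linear/logistic scans, so
scale conventions (SD units, log-OR, EAF, N semantics) are exercised end
to end; the closed-form backend draws summary estimates directly from
their sampling distributions for large replicate sweeps (parameter
recovery, type-I error, reverse-MR coverage). When the configuration
specifies several cohorts the closed-form exposure estimate is the
fixed-effects meta-analysis of per-cohort draws, mirroring the
meta-supported instrument selection in the pipeline proper.

What the generator does *not* emulate — and therefore what a green test
does not establish: microbiome compositionality and between-taxon
correlation; 16S read-level noise and the DADA2 step; the mGWAS
covariate structure (plates, principal components); population
stratification or assortative mating as confounders; realistic LD decay
(blocks are compound-symmetric); non-collapsibility subtleties of the
logistic outcome model beyond what the calibration tests capture.

## Seeding policy

Every public generator takes a seed and restores the caller's RNG state
on exit, so nested seeded calls compose. Replicate sweeps in tests use a
single seeded stream rather than per-replicate sequential seeds:
sequential `set.seed(base + i)` streams are measurably correlated and
over-disperse block means, which was observed directly during
development and is why `seed = NULL` (continue the ambient stream) is
supported.

## Known limitations

- The liability-scale R² uses the logistic→probit π/√3 factor; accuracy
  degrades at extreme prevalence, where the logistic and probit links
  diverge. The test suite verifies agreement with a threshold-liability
  generative oracle at moderate prevalence (±15%).
- The first-order Wald SE understates uncertainty for weak instruments
  (the acceptance suite bounds the resulting 95% CI coverage within
  [0.93, 0.97] under the stated world); this is why instrument strength
  (F ≳ 10) is graded before estimation.
- The pleiotropy screen is only as complete as the local catalogue file;
  it cannot discover associations the catalogue lacks.
- Reverse MR here shares the forward machinery; it does not model sample
  overlap or winner's curse in the disease instruments.
- Plan configuration files are JSON (via jsonlite) rather than YAML; the
  R API is the primary interface.
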