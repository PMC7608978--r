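---
title: "Simple Sum colocalization: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simple Sum colocalization: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sscoloc` tests whether a GWAS association signal at a locus colocalizes
with secondary SNP-level association signals (typically eQTLs per gene and
tissue), using only summary statistics and an LD reference. This vignette
is the package's account of the statistical model, the tunable parameters,
what the synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open.

## The two-stage model

Let $P^G_j$ and $P^E_j$ be the GWAS and secondary p-values of the $j$-th of
$n$ harmonized SNPs in the test region, and $R$ the SNP correlation (LD)
matrix. Secondary evidence is expressed on the chi-square scale,
$T_j = Q_{\chi^2_1}(1 - P^E_j)$, which equals the squared z-score of the
underlying association test whenever the p-value came from a two-sided
normal or 1-df chi-square test.

**Stage 1** asks whether there is *any* secondary signal in the region:
$S_1 = \sum_j T_j$. Under the global null, the vector of secondary
z-scores is $N(0, R)$, so $S_1$ is distributed as
$\sum_i \lambda_i \chi^2_{1,i}$ with $\lambda_i$ the eigenvalues of $R$
(eigenvalues below $10^{-10}$ dropped as numerical noise). The tail
probability is computed by Imhof-type numerical inversion of the
characteristic function (closed forms are used when all eigenvalues
coincide, and a two-moment Satterthwaite approximation is the fallback if
the integrator fails). The stage-1 p-value is gated at $\alpha/m$, where
$m$ counts the secondary datasets submitted in the run — the gate is a
Bonferroni screen across every gene-tissue pair tested, so a run over 49
tissues demands much stronger regional eQTL signal than a single-dataset
run. We use the submitted count, not the count of datasets with data: a
dataset that contributes no rows still consumed a look.

**Stage 2** asks whether the secondary signal aligns with the GWAS
pattern. GWAS evidence enters as weights $g_j = -\log_{10} P^G_j$,
centered to $c_j = g_j - \bar g$ (so a constant shift of GWAS evidence —
e.g. a genomic-control correction — cannot move the statistic). The Simple
Sum statistic is

$$Z_{SS} = \frac{\sum_j c_j T_j}{\sqrt{c^\top \Sigma c}},
\qquad \Sigma_{jk} = 2 r_{jk}^2 + 4\,\hat\delta\, r_{jk},$$

referred to the one-sided upper normal tail: colocalization predicts
*positive* association between $g$ and $T$, and a negative $Z_{SS}$ simply
yields $p > 0.5$. The null covariance comes from modelling the secondary
z-scores as $N(\sqrt{\hat\delta}\,\mathbf 1, R)$: a region that passed
stage 1 contains signal, and $\hat\delta = \max(\bar T - 1, 0)$ attributes
that signal as a *common* noncentrality rather than assuming where it
sits. For bivariate normal $(z_j, z_k)$ with correlation $r$ and common
mean $\sqrt\delta$, $\mathrm{Cov}(z_j^2, z_k^2) = 2r^2 + 4\delta r$, which
is the expression above.

## Parameters that matter

* `alpha` (default 0.05): nominal level of the stage-1 gate, divided by
  `m`.
* `min_snps` (default 5): stage 2 needs enough SNPs for the region-wide
  calibration to mean anything; fewer harmonized SNPs yields the `-3`
  ("test failed") sentinel rather than a shaky p-value.
* The Simple Sum region defaults to 0.1 Mbp on each side of the lead SNP,
  clipped to the viewing region (which itself is capped at 2 Mbp,
  inclusive of both endpoints). The lead SNP is the smallest-p GWAS
  variant present in the LD panel — when the smallest-p variant is absent
  from the panel we walk down the p-value ordering, ties broken by smaller
  position.
* Trace windows for the minimum-p line summaries are
  `(region size / 1e6) * factor` bp wide with `factor = 150` by default;
  the 150-kbp example region gives 22.5-bp windows. Region size is the
  coordinate extent `end - start`, which is what makes the worked example
  come out at exactly 22.5. The fractional width is kept exact in the
  boundary arithmetic (a SNP falls in window
  `floor((pos - start) * 1e6 / (size * factor))`), so window assignment
  does not drift over a 2 Mbp region.
* LD colour bins follow the LocusZoom convention, half-open $[lo, hi)$
  with the top bin closed: lead, $r^2 \ge 0.8$, $[0.6, 0.8)$, $[0.4,
  0.6)$, $[0.2, 0.4)$, $< 0.2$, missing. Published descriptions of such
  binning schemes are often internally inconsistent about which side of
  the boundary is closed; this partition is total and unambiguous.

## Harmonization and LD input

Variants join on (chromosome, position, ref, alt). A secondary or LD
variant with swapped ref/alt still matches, because the Simple Sum uses
p-values only and p-values are allele-order invariant; strand flips are
*not* attempted, since strand inference without allele frequencies is
unsafe. Duplicate variants within a file keep the smallest p-value
(logged). p-values of exactly 0 are clamped to 1e-300 to keep
$-\log_{10}$ finite; rows with p outside $(0,1]$ are dropped and counted.
rsID markers are resolved through an optional user-supplied lookup table;
no network service is consulted.

LD can be given as a PLINK-style square matrix file or computed from a
VCF genotype panel as pairwise-complete Pearson correlation of dosages
(the PLINK `--r square` definition; monomorphic SNPs are excluded rather
than producing NaN rows). When the file contains only values in $[0,1]$
it is taken to be $r^2$ and $\sqrt{r^2}$ is stored with a prominent log
message: the signs are unrecoverable, and since the $4\hat\delta r$ cross
terms of $\Sigma$ are then all nonnegative, the null variance is
upper-bounded — the stage-2 test becomes conservative in the cross terms
rather than anticonservative. Supplying signed `--r square` output (or a
VCF) is preferable.

## The synthetic-locus generator

`simulate_summary_stats()` draws z-scores as $N(\mu, R)$ per dataset with
$R$ an AR(1) ($r_{jk} = \rho^{|j-k|}$, default $\rho = 0.8$) or block
structure over 50 SNPs spaced 3 kbp apart (a 150-kbp locus). Scenarios
fix $\mu$: "A" null in both datasets; "B" an eQTL causal SNP with the GWAS
null; "C" one shared causal SNP; "D" distinct causal SNPs. The causal SNP
carries mean z-score `effect_size` (default 6, a strong molecular-QTL
association) and correlated SNPs inherit it as
$\mu = \text{effect} \times R[, \text{causal}]$ — the single-causal-variant
signature under LD. Genotype panels (default 1,000 samples) are realized
by thresholding latent Gaussian haplotypes at the Hardy–Weinberg quantile
of the configured MAF (default 0.3), a Gaussian copula: simple,
reproducible, and adequate for correlation-structure checks, though the
dichotomization attenuates dosage correlations relative to the latent
$R$ (the fixture tests bound the mean absolute deviation by 0.1 at 1,000
samples). The generator does **not** emulate realistic allele-frequency
spectra, recombination maps, imputation uncertainty, or sample overlap
between GWAS and eQTL studies — passing calibration tests on these
fixtures shows the machinery is correct under the stated model, not that
the test is calibrated on arbitrary real data.

Problem sizes used by the shipped calibration checks: 2,000 replicates
for the type-I rate, 200 per scenario for power, $10^6$ Monte-Carlo draws
times 20 eigenvalue sets for the quadratic-form oracle, 20 SNPs times
400–500 samples for the LD oracle. These sizes give binomial/Monte-Carlo
noise comfortably below the decision margins involved.

## Numerical choices

* Quadratic-form tails: Imhof integration via adaptive quadrature
  (relative tolerance $10^{-10}$, absolute $10^{-9}$), result clipped to
  $(10^{-300}, 1]$; exact chi-square forms for one or equal eigenvalues.
* `ss_p` is clipped to $\ge 10^{-300}$ before $-\log_{10}$.
* Degenerate inputs are statuses, not crashes: constant GWAS p-values
  (all-zero weights), non-positive null variance, or non-finite
  statistics give the `-3` sentinel; an empty harmonized intersection
  gives `-1`.
* The heatmap grid is always rectangular: a gene with no entry for a
  dataset is rendered `-1`, matching the gray-square convention of
  interactive heatmaps.
* The pipeline is deterministic given its inputs; the CLI accepts a
  `--seed` for interface completeness and records it in the run log.

## Known limitations

The stage-2 null attributes the region's secondary signal to a *common*
noncentrality $\hat\delta$. When the true secondary signal is strongly
concentrated on one SNP (large single-SNP effects) and the GWAS weights
are uninformative noise — exactly the generator's scenario "B" with the
default effect size 6 — the realized mean of $\sum_j c_j T_j$ fluctuates
with the placement of the weights relative to the signal, a variance
component the conditional-on-weights null does not carry. The empirical
sd of $Z_{SS}$ under that scenario is near 2 rather than 1, and the
empirical rejection rate at nominal 0.05 (computed by
`scripts/acceptance.R` and the acceptance test suite) is several-fold
above nominal. Replacing the normal tail by the exact noncentral
quadratic-form distribution under the same common-$\hat\delta$ null does
not change this, because the defect is in the null's mean/variance
accounting, not in the tail shape. In practice the test is meant to be
run at loci where the *GWAS* signal is real and concentrated (weights far
from noise), where the conditional calibration is the relevant one; the
scenario-"B" rate is reported honestly rather than tuned away, and
strongly anticonservative behaviour should be expected if the test is
applied at loci with no GWAS signal. The stage-1 gate offers no
protection against this, since it screens the secondary dataset, not the
GWAS.

Other limitations: no liftover (build tags are pass-through labels), no
strand-flip matching, no handling conventions for multi-allelic sites
beyond exact or swapped allele-string matching, and the unsigned-LD route
loses the sign information discussed above.
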