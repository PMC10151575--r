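---
title: "Models and methods for the genetic analysis of sow pelvic organ prolapse"
author: "swinePOP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for the genetic analysis of sow pelvic organ prolapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The trait and its coding

Culling for pelvic organ prolapse (POP) is a binary event on a sow's
life-history timeline.  `swinePOP` codes it two ways, which answer slightly
different questions:

* **Across-parity**: among sows that were culled or died with removal
  parity 2–6, the phenotype is 1 if the stated removal reason was POP and 0
  otherwise.  This conditions on culling, so the contrast is "culled for
  POP versus culled for something else"; the contemporary group (herd ×
  year × quarter, HYQ) is taken from the insemination of the removal
  parity, and removal parity itself enters as a fixed effect.
* **By-parity**: among all sows with a record for parity *k* (2–6), the
  phenotype is 1 if the sow was removed for POP in that parity and 0 if she
  survived it or was culled for another reason.  Each parity gives a
  partially independent dataset; a sow removed in parity *k* contributes to
  parities up to *k* only.

Parity-1 records are generated and parsed but excluded from analysis:
incidence in first-parity sows is too low to support estimation, and
mixing it in would dilute the contemporary-group structure.  Sows removed
after parity 6 still contribute phenotype-0 records to the by-parity
datasets of parities they completed; the QC report counts them.

Quality control removes whole sows, not records: a died flag without a
removal date, any insemination-to-farrowing interval over 116 days, and
inaccurate pedigree entries.  "Inaccurate" is operationalized as
self-parenting or, when parent birth dates are supplied, chronologically
impossible parentage; each rule is individually switchable and its removals
are counted separately in the QC report, since the underlying data-cleaning
conventions differ between herd-book systems.  Missing sire ids are *not*
grounds for removal — pooled-semen insemination legitimately produces them —
and total number born is carried through the record type but deliberately
excluded from the default models.

Calendar quarters (Jan–Mar = Q1) define the Q in HYQ.  Any other cut would
do; what matters is that sows culled before farrowing still carry the
insemination-based label of that parity, because a large fraction of POP
culls happen between insemination and farrowing.

# Threshold marker-effects models

The genome scan uses a probit threshold model with marker effects:

$$\mathrm{Probit}(y_{ij}) = \mathrm{HYQ}_{ij} + \sum_{n=1}^{p} m_{ijn}\,
\beta_{jn}\,\delta_{jn} + e_{ij}, \qquad e_{ij} \sim N(0, 1).$$

The residual variance is fixed at 1 because it is not identifiable in a
threshold model.  Doses $m$ are centred by twice the allele frequency
(centring only shifts the contemporary-group effects).  The Gibbs sampler
augments latent liabilities with truncated-normal draws consistent with the
observed 0/1 outcome, updates each marker effect from its conditional
normal, and updates the inclusion indicator $\delta_n$ from the marginal
likelihood ratio with the effect integrated out.

Priors, and why:

* **Bayes-B**: point mass at zero with probability $\pi$ and
  marker-specific variances $\sigma^2_n \sim$ scaled-inv-$\chi^2(\nu, S)$,
  $\nu = 4$.  The scale $S$ is set from a user-supplied prior heritability
  (default 0.3) spread over the markers expected to be in the model:
  $S \propto \frac{h^2_{prior}/(1-h^2_{prior})}{(1-\pi)\sum_k 2p_kq_k}$.
* **Bayes-Cπ**: common effect variance, $\pi$ uniform a priori with a
  beta–binomial Gibbs update.  Its posterior mean is the plug-in $\pi$ for
  the Bayes-B scan, mirroring the two-stage practice in livestock GWAS.
* **Bayes-C0**: every marker in the model with a common variance — the
  marker-effects equivalent of GBLUP, used for the bivariate model and as
  an internal consistency check (the Bayes-C0 heritability must agree with
  the G-matrix animal model on the same data; the test suite asserts
  agreement within 0.05).

Fixed effects get a weak normal prior with variance 4 (sd 2 on the latent
scale) rather than a flat one.  This is not cosmetic: at realistic
incidences, a contemporary group of ~20 sows has all-zero outcomes roughly
once in seven cells, and under a flat prior such a cell's effect performs a
random walk on the latent scale (the extreme-category problem), which
inflates the genetic variance.  A sd-2 prior is far wider than any
plausible seasonal contrast yet anchors empty cells; `fixedPriorVar = Inf`
restores the flat prior.  Markers with zero dose variance are skipped with
$\delta$ forced to 0.

# Animal models and heritability scales

Liability-scale heritability uses a threshold animal model
$l = Xb + a + e$, $a \sim N(0, K\sigma^2_a)$ with $K$ either the pedigree
A-matrix (tabular method; unknown parents contribute zero) or the VanRaden
method-1 genomic matrix $G = WW'/(2\sum_k p_k q_k)$ with observed allele
frequencies.  $K$ is stabilized as $0.99K + 0.01I$ before factorization.
Breeding values are sampled in the eigenbasis of $K$, where — with one
record per sow — their full conditional is diagonal, so one iteration costs
two dense matrix–vector products.

The LOGIT link is implemented as probit-style augmentation with the latent
residual variance fixed at $\pi^2/3$, the logistic variance.  This is an
approximation (exact logistic augmentation would use Polya-Gamma draws);
it reproduces logit-scale variance conventions with the same machinery and
one augmentation scheme, and is reported as such.  Heritability per sample
is $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)$ with
$\sigma^2_e \in \{1, \pi^2/3\}$ fixed by the link.

The observed-scale conversion is Dempster–Lerner:
$h^2_{obs} = h^2_u\, z^2 / (p(1-p))$ with $p$ the incidence, $t$ the
upper-$p$ normal quantile and $z = \phi(t)$.  The normal-liability $z$ is
used for logit-scale inputs as well — that is the convention required to
reproduce the standard published conversions (e.g. 0.35 → 0.12 and
0.21 → 0.07 at 10.1 % incidence), which the acceptance suite checks.
Posterior sd is reported where REML software reports an SE; they are
analogous but not identical summaries.

# Bivariate model and genetic correlations

The same trait in two parities is analysed with a bivariate *linear*
Bayes-C0 model on the 0/1 outcomes.  Linear, because with all markers
included the model is the bivariate GBLUP workhorse and the genetic
correlation — a ratio of covariances — is robust to the scale distortion of
treating a binary outcome linearly.  Sows observed in one parity only have
the missing residual drawn from the conditional normal implied by the 2×2
residual covariance R (data augmentation), so every marker update sees
complete data; a complete-case mode exists for testing.  G₀ and R get
inverse-Wishart updates ($\nu = 4$, diagonal scale).

Per saved sample the *genome-wide genetic covariance* is computed as the
2×2 covariance across individuals of the marker-based genomic values
$\{M\beta_1, M\beta_2\}$ — realized covariance, not $2\sum p q$ times the
effect covariance — and the genetic correlation sample is
$r_g = \mathrm{cov}_g / (\sigma_{g,1}\sigma_{g,2})$.  Samples with either
genetic variance below $10^{-12}$ are dropped and counted.  The 95 % HPD is
the shortest contiguous interval containing $\lceil 0.95 n\rceil$ sorted
samples; the suite cross-checks it against an exhaustive window search and
against `coda`.

# Window decomposition, WPPA and significance

Windows are non-overlapping 1 Mb bins: window $k$ covers base-pair
positions $[k\cdot 10^6, (k+1)\cdot 10^6)$ (0-based half-open internally;
1-based bim positions converted on read; window labelled by the Mb
integer).  For every saved sample, each window's genomic values are
$\sum_{n \in \mathrm{window}} m\beta\delta$ per individual, its variance is
taken across individuals, and its *proportion* is that variance over the
genome-wide genetic variance of the same sample — ratio first, then
averaged (the alternative, ratio of posterior means, understates sampling
variability in the denominator).  WPPA is the fraction of samples in which
the proportion exceeds $\rho$, by default $1/(\text{number of non-empty
windows})$ — the share expected under a uniformly spread architecture.
Significant windows are those whose posterior mean share strictly exceeds
1 %; regional confirmation sums shares over the anchor window ± 2 Mb on the
same chromosome, truncated at chromosome ends.

Two properties of WPPA deserve emphasis.  First, it is a statement about
*proportions*: if total genetic variance is near zero, whichever window
contains an occasionally included marker takes a large share of almost
nothing.  Second, under a permissive $\pi$, the strongest chance
association among $p$ markers on a fixed binary phenotype (|z| around
3.5–4 for $p = 1000$) legitimately earns a posterior inclusion probability
of the same order as its frequentist surprise, and the window containing it
inherits that as WPPA.  Null-architecture calibration runs therefore fix
$\pi$ at the architecture's true sparsity ($1 - 10^{-9}$ when no marker is
causal), and WPPA values from permissive-$\pi$ scans should always be read
alongside the per-SNP inclusion probabilities.

# The synthetic cohort generator

The generator is first-class, tested code: every downstream claim is
validated against cohorts whose truth is known.

* **Genotypes**: haplotypes follow a first-order Markov chain along each
  chromosome with adjacent-allele correlation `ldRho` (default 0.5) and
  stationary frequencies uniform on [0.05, 0.5]; doses are sums of two
  haplotypes; markers sit on a uniform grid (default 25 kb).  Conditional
  transition probabilities are clamped to [0, 1], so realized correlation
  can fall slightly short of `ldRho` where adjacent frequencies differ
  strongly.
* **Pedigree and gene dropping**: founder sires and dams get simulated
  haplotypes; descendants receive recombinant gametes with crossovers
  placed as a Poisson process at 1 cM/Mb.  This makes genomic and pedigree
  relationships agree in expectation, a property the test suite checks by
  watching mean |G − A| shrink as marker count grows.
* **Records**: per parity $j$, liability $l_{ij} = g_{ij} + \mathrm{hyq} +
  e_{ij}$.  Marker effects at the QTL follow an AR(1) across parities with
  parameter 0.7 — so the genetic correlation decays as $0.7^{|k-l|}$,
  matching the bivariate model's marker-level assumption rather than a
  sow-level repeatability structure — with innovations orthogonalized so
  the realized adjacent-parity correlation equals the target rather than
  merely averaging to it.  Genetic values are rescaled so realized
  liability heritability matches the per-parity targets (defaults 0.41,
  0.41, 0.35, 0.28, 0.22, 0.15 for parities 1–6).  A sow develops POP in
  the first parity where liability exceeds that parity's threshold, set at
  the empirical quantile matching the target incidence among sows at risk
  (defaults rising from 0.35 % to 3 %), so realized incidence is exact up
  to rounding.  Other-reason culling is an independent hazard of 9× the
  POP incidence, making POP ≈ 10 % of culls; culled sows generate no later
  records; 2 % of sows get a blank sire.  HYQ effects are N(0, 0.2²) on
  the liability scale.
* **Not emulated**: secular and seasonal incidence trends, confounding
  between culling reasons and liability (a confounded mode exists but is
  off by default), pooled-semen paternity beyond blanking the sire, and
  genotyping artefacts (the generator emits complete genotypes, so the
  mean-imputation path is a convenience, not a tested imputation method).
  Passing tests on these cohorts therefore demonstrate correctness of the
  estimation machinery under the liability-threshold data-generating
  process, not robustness to the full messiness of field data.

Benchmark traits for parameter-recovery runs use a case fraction of 0.5
(the information-maximizing choice for a binary trait) and Gaussian
phenotypes for the bivariate benchmark (the model is linear; using its own
distributional assumption isolates estimation error from coding error).
The engineered-window benchmark places a single causal variant at the
centre of the target window — central so its LD support stays inside the
window — and rescales it against the polygenic background so the window's
share of realized genetic variance is *exactly* the target (default 2 %).
Even so, dichotomizing the liability leaves the window's marginal evidence
with substantial draw-to-draw variation (its observed-scale |z| has sd
about 1 around roughly 4), so single-cohort WPPA near the 0.8 convention
varies between simulated cohorts; the acceptance script reports the median
over three cohorts.

# Chain settings and numerical choices

Full-scale analysis conventions are 50,000 iterations / 5,000 burn-in /
thin 100 for genome scans and 120,000 / 20,000 / 100 for bivariate runs.
The test suite and acceptance script run the same models at benchmark
sizes — 3,000 sows × 1,000 markers with chains of 2,500–8,000 iterations,
thin 10 — chosen so the whole validation battery completes on a single CPU
in minutes while posterior means are stable to well within the asserted
tolerances.  All randomness flows through R's RNG (the C++ kernels draw via
R's API), so a seed fixes every result bit-for-bit.

Other numerical conventions: relationship matrices are blended with 1 % of
the identity before factorization; eigenvalues are floored at $10^{-8}$;
2×2 covariance draws use Bartlett-factor inverse-Wisharts; truncated
normals are drawn by inverse-CDF with the uniform clamped to
$[10^{-15}, 1-10^{-15}]$; monomorphic markers are dropped from G and
skipped by the samplers; HPD intervals require at least two finite
samples; dose matrices may hold fractional entries after mean imputation.

# Known limitations

* The logit-scale animal model is an approximation (π²/3 residual with
  probit augmentation), adequate for scale conversion but not an exact
  logistic threshold model.
* Heritability from across-parity data conditions on culling; it is a
  pooled quantity over parities 2–6 and not identical to any single
  parity's liability heritability.
* With many small contemporary groups the threshold model still biases
  h² upward somewhat even with the weak fixed-effect prior; coarser
  grouping is advisable when cells fall below ~20 observations.
* WPPA under permissive π reflects chance-association inclusion
  probabilities (see above); it is a ranking and evidence summary, not a
  familywise-error-controlled test.
* The bivariate model treats 0/1 outcomes linearly; genetic correlations
  are robust to this, but its variance components are on the observed
  scale and are not converted.
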