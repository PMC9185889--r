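---
title: "Methods: steady-state perturbation-response modeling and screen scoring"
author: "persignal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state perturbation-response modeling and screen scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persignal)
```

This vignette is the package's own account of its models and of the design
choices that were genuinely open: what is computed, under which assumptions,
with which defaults, and what the synthetic-data experiments do and do not
demonstrate about real data.

## The steady-state signaling model

Perturbation-response experiments expose serum-starved cells to a kinase
inhibitor, then to a growth-factor stimulus, and read out phospho-levels of
downstream kinases as log2 fold-changes against an unperturbed control. At
a single time point long after stimulation, the network can be treated as
having relaxed to a new steady state, and — in the spirit of modular
response analysis — responses can be modeled as *linear in log2 space*:
each node's log2 fold-change is a strength-weighted sum of the transmitted
activities of its upstream neighbours plus any external input,

$$ x \;=\; R\,(x - \beta \circ \delta_\mathrm{inh}) + p_\mathrm{stim}, $$

solved directly as $(I - R)\,x = p - R\,b$. Here $R_{ij}$ is the response
strength of edge $j \to i$ (negative for inhibitory feedback), $\beta_k \ge 0$
is the log2 attenuation an inhibitor imposes on its target node, and
$p_\mathrm{stim}$ carries stimulus strengths at their receptor entry nodes.

Three modeling assumptions deserve emphasis:

* **Inhibitors act on transmission, not on the measured level.** The
  inhibited kinase's own phospho-level responds only to its upstream input.
  This is the only arrangement consistent with the well-known accumulation
  of phosphorylated MEK under MEK inhibitor treatment: blocking MEK's
  catalytic output silences ERK, which relieves the ERK→RAF negative
  feedback, which *raises* phospho-MEK. In the model this appears as
  $x_\mathrm{MEK}(\mathrm{EGF{+}MEKi}) > x_\mathrm{MEK}(\mathrm{EGF})$
  whenever the feedback strength is negative, with the rebound growing
  monotonically in the feedback magnitude and vanishing exactly when the
  feedback is zero — the package's model-level statement of the
  feedback-relief phenotype, asserted in the test suite.
* **The unperturbed state is the reference.** Data are fold-changes, so the
  control condition maps to the zero vector and no basal-activity
  parameters exist.
* **Stability.** The linear fixed point is the limit of the signal-relay
  iteration only when the spectral radius of $R$ is below 1;
  `stability_check()` enforces $\rho(R) < 1 - 10^{-9}$, the generators
  refuse unstable ground truths, and the fitter rejects converged restarts
  that land in the unstable region (the best *stable* restart is reported,
  and it is an error if none exists).

`fixed_point_oracle()` exists purely as an implementation-independent
cross-check: it iterates the relay map from zero until convergence and must
agree with the direct solve, which the tests verify on hundreds of random
stable networks.

All fold-changes are log base 2 throughout the package, even where other
tools report an unqualified "log fold-change".

## Fitting and the likelihood

`fit_model()` minimizes the residual sum of squares between measured and
predicted log2 fold-changes (replicates enter individually) by
Levenberg–Marquardt. The residual Jacobian is analytic, obtained by
implicit differentiation of $(I-R)X = P - RB$ — one extra multi-right-hand-side
linear solve per evaluation — with a finite-difference cross-check in the
tests. Random
restarts draw edge strengths uniformly inside their declared signs
(U(0,1), U(−1,0), or U(−1,1) for free signs) and stimulus/inhibitor
strengths from U(0,3); the exported default is 100 restarts, though the
objective is smooth enough that the in-repo experiments use 4–10.

The likelihood is Gaussian with a single noise variance profiled out,
$\ell = -\tfrac{n}{2}\left(\ln(2\pi\,\mathrm{RSS}/n) + 1\right)$, with the
RSS floored at $10^{-12}$ so noise-free fits remain finite. Two nested fits
therefore compare as $D = n \ln(\mathrm{RSS}_0/\mathrm{RSS}_1)$.

`profile_ci()` walks a grid away from the estimate, re-optimizing all other
parameters at each point (warm-started from the neighbouring point), and
brackets the value where $2\Delta\ell$ crosses the $\chi^2_1$ quantile. A
profile that stays flat to the grid edge flags the parameter
non-identifiable — with unmeasured intermediate nodes only products of
chain strengths are determined, which is expected and reported rather than
hidden.

## Linking parameters across isogenic cell lines

Isogenic knockout clones differ from their parental line by a single
genetic lesion, so the biologically minimal hypothesis is that *all* model
parameters are shared. `comparative_fit()` starts there and proceeds
greedily: at each step, every still-shared parameter is tentatively freed
per line (candidate fits are warm-started from the current optimum with the
freed parameter duplicated, which guarantees freeing never increases the
RSS), the improvement is scored by a likelihood-ratio test with
$n_\mathrm{lines} - 1$ degrees of freedom, and the smallest p-value is
compared to `alpha` after Bonferroni correction over that step's
candidates. The first non-significant step stops the search.

Open choices resolved here, since the linking principle fixes neither the
search order nor the multiplicity handling: greedy forward selection with
per-step Bonferroni at `alpha = 0.05`; inhibitor strengths are shared by
default and eligible for unlinking like any other parameter (the drugs are
the same molecules in every line, but drug export or target mutations could
still diverge); an unlinking step always splits a parameter fully into
per-line values.

Two simulation experiments characterize the procedure at the study's
conditions (full stimulus × inhibitor panel, 3 replicates, 0.1 log2-unit
Gaussian noise): planting a 0.8 weakening of the ERK→RAF feedback in one of
two lines is detected — with the correct parameter named — in ≥ 90% of 100
simulated datasets, and under the all-shared null the family-wise rate of
*any* false unlinking stays within the nominal 5% (binomial margin, 200
simulations). Both are re-run by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`.

`scaled_heatmap()` prepares the customary display: within each scaling
group of lines, parameters are divided by the maximum absolute value of
their class (edge, stimulus, or inhibitor strengths), preserving sign so
negative feedback stays negative.

## The canonical network fixture

`default_network()` houses every analyte and drug target of a multiplexed
phospho-panel under ALK/MEK/PI3K/mTOR inhibition and EGF/IGF1 stimulation:
receptors EGFR/IGF1R/ALK feeding RAS, the RAF–MEK–ERK cascade with ERK→RAF
negative feedback, and RAS/IGF1R/ALK input into PI3K–AKT–mTOR–S6K, with
P-MEK, P-ERK, P-AKT and P-S6K measured. `default_true_params()` assigns
stable, plausible strengths (MAPK cycle gain 0.65 in magnitude, spectral
radius 0.87); the feedback default of −0.9 is the "parental" phenotype and
`make_isogenic_pair(params, "ERK->RAF", 0.8)` creates the matched
weakened-feedback clone. Because only four nodes are measured, some
individual edges of the full fixture are non-identifiable (their products
are); the parameter-recovery assertions therefore use a fully measured
MAPK-core network, while power/calibration experiments — which only need
the LRT to localize the divergent parameter — use the full fixture.

## Synthetic data: what is emulated, and what is not

**Screens** (`generate_screen_counts()`): negative-binomial counts with
variance $\mu + \alpha\mu^2$, defaults $\alpha = 0.2$ between arms,
4 guides/gene, 2 technical replicates per arm, geometric-mean coverage of
500 reads/guide, and a lognormal per-guide abundance profile
(`abundance_sdlog = 2.0`, drawn once and shared across samples). The
abundance spread matters: after two weeks of selection a library spans
roughly three orders of magnitude, and it is this shared profile — against
a much smaller technical dispersion of $\alpha = 0.05$ between sequencing
replicates — that makes replicate correlations of r ≈ 0.98–0.99 the
expected QC outcome. Effect genes multiply treated-arm means by
$2^\mathrm{effect}$. Not emulated: guide-efficiency differences,
copy-number artifacts, PCR jackpotting, or bottlenecking beyond the NB
dispersion.

**Dose-response** (`generate_dose_response()`): 4PL curves with
multiplicative lognormal noise of specified CV (mean-preserving). Not
emulated: plate-position effects or drug-interaction surfaces.

**Perturbation panels** (`generate_perturbation_data()`): model steady
state plus additive Gaussian noise on log2 fold-changes, default sd 0.15
and 3 replicates (0.1 is used in the divergence experiments). Not emulated:
incomplete steady state, saturation/nonlinearity of strong stimuli, or
analyte cross-reactivity. Passing tests on these generators demonstrate
the *procedures* (estimator calibration, detection power, recovery) under
the generative model, not that any particular biological dataset satisfies
that model.

## Screen scoring choices

The gene score is the mean log2 fold-change of a gene's guides on
size-factor-normalized counts (pseudocount 1), preserving the
negative-is-depletion / positive-is-enrichment convention of MLE-based
β-scores while remaining fully specified in-repo; it is a deliberate,
documented substitute for an external MLE pipeline, of which only the
sign/ranking semantics are mirrored. Because screens often have only two
technical replicates, significance comes from permuting *guides* rather
than sample labels: each gene's null is the mean of a same-size random
guide set, drawn independently per gene (with replacement, so p-values are
exactly uniform and independent under the null — shared null draws would
make a uniformity test anti-conservative), floored at $1/(n_\mathrm{perm}+1)$,
with BH FDR across genes. Note the permutation floor bounds the achievable
FDR at roughly $n_\mathrm{genes}/(n_\mathrm{perm}+1)$ divided by the hit
rank, so genome-scale analyses should raise `n_perm` well above the
default minimum. Replicate log2 fold-changes are combined by averaging
normalized counts within arms before forming the ratio.

## Dose-response choices

"Absolute IC50" is the concentration where the *fitted* curve crosses 50%
of untreated control (y = 50 on the 0–100 scale), computed in closed form;
it is undefined (NA, not an error) when the curve never crosses 50. The
alternative reading — 50% of the fitted top — is deliberately not used, but
`absolute_ic50(curve, target =)` exposes the crossing level. GI50 follows
the NCI-60 convention, scaling by net control growth above the day-0
baseline and by the baseline itself in the cytotoxic regime. The 4PL fit
multi-starts over ec50 decades spanning the tested range and hill slopes
of both signs, then canonicalizes to top > bottom; flat data return an
explicit non-converged, ec50-unidentifiable result. Viability is expected
normalized to control (≈100%) before fitting, as is conventional when the
raw normalization is not stated.

## Problem sizes and numerics

The in-repo experiments are sized for a single CPU: 500 random networks for
the oracle-equivalence sweep, 100/200 simulations for power and null
calibration (about two minutes each), 500–5000 genes per simulated screen,
and 200 seeds for 4PL recovery. Tolerances: steady-state vs oracle
agreement to $10^{-8}$ (oracle tolerance $10^{-10}$); noise-free parameter
recovery to $10^{-4}$; MIDAS round-trips to $10^{-9}$. Ties in the greedy
unlinking step are broken toward the larger LRT statistic; degenerate
inputs (flat dose-response data, genes without guides, schemes without a
control, unstable parameter sets) produce flagged results, warnings, or
errors as documented on each function.

## Known limitations

* The linear-in-log2 steady-state form is a first-order description; it
  reproduces directions and interaction structure (feedback relief,
  pathway crosstalk) but strong saturating responses would require a
  nonlinear extension. Numerical equality with any specific external
  modeling pipeline is not claimed.
* With partially measured networks, only parameter combinations are
  identifiable; `profile_ci()` reports this per parameter rather than
  regularizing it away.
* The greedy unlinking search is sequential; two parameters whose
  divergences compensate each other almost exactly could mask one another.
* Gene scores ignore guide-level weights; a handful of inefficient guides
  dilutes a true signal proportionally.
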