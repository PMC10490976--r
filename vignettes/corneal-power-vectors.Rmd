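---
title: "Corneal power vectors, confidence ellipses, and prediction of postoperative corneal power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corneal power vectors, confidence ellipses, and prediction of postoperative corneal power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 6)
library(cornvec)
```

## The problem

Toric intraocular lens (tIOL) calculation needs the *total* corneal
astigmatism of the pseudophakic eye, but what is routinely measured before
surgery is front-surface keratometry of the phakic eye. Keratometry converts
front-surface radii into "keratometric power" through a fictitious index
(here the Zeiss index 1.332) that hides a fixed front-to-back surface ratio;
the real corneal back surface, however, is usually steeper vertically than
horizontally and contributes extra against-the-rule astigmatism that a
keratometer cannot see, and cataract surgery itself changes the cornea.
`cornvec` implements the analysis chain for a cohort measured with an
optical biometer (IOLM, preoperatively) and an anterior-segment OCT (CASIA,
pre- and postoperatively): decomposition into power vectors, device/time
difference panels, double-angle confidence ellipses, and two predictors of
the postoperative real-power astigmatism from preoperative keratometry.

## Power vectors

A spherocylindrical power (flat meridian $P_1$ at axis $A_1$, steep
meridian $P_2$) is represented by the power vector

$$\mathrm{EQ} = \tfrac12 (P_1 + P_2), \qquad
  C_0 = (P_2 - P_1)\cos 2A_1, \qquad
  C_{45} = (P_2 - P_1)\sin 2A_1 .$$

For surfaces measured as radii (mm), the meridional power is the paraxial
$P = 1000\,(n_2 - n_1)/R$ dioptres, giving
$\mathrm{EQ} = 500\,\Delta n\,(1/R_2 + 1/R_1)$ and cylinder
$1000\,\Delta n\,(1/R_2 - 1/R_1)$. The factor 1000 (mm to m) applies to the
cylinder exactly as to the equivalent power; this choice is pinned by the
schematic-eye anchor values below. Index steps follow the Liou–Brennan
schematic eye ($+0.376$ front, $-0.040$ back) and the keratometer index
($+0.332$):

```{r anchors}
power_from_radius(7.77, "front")   # 48.3912 dpt
power_from_radius(6.4, "back")     # -6.25 dpt -> ratio -7.7426
radii_to_power_vector(7.82, 0, 7.72, "front")          # 0.6228 dpt cylinder
radii_to_power_vector(7.82 / (7.77/6.4), 0, 7.72 / (7.77/6.4), "back")
```

The double-angle representation makes astigmatism additive: differences
between devices or time points are componentwise (`pv_subtract`), and the
surgically induced astigmatism is simply postoperative minus preoperative.
Under a mirror-symmetry assumption, left-eye $C_{45}$ components are
sign-reversed (`mirror_for_left_eye`) so both eyes pool in right-eye
orientation; the operation is an involution and preserves EQ, $C_0$ and the
cylinder magnitude.

Conventions that required a decision:

* axes live in $[0, 180)$ degrees and the *flat* axis drives the double
  angle; records with mislabelled flat/steep meridians are swapped (axis
  rotated by 90°) with a warning rather than rejected;
* a zero cylinder has no axis; polar output reports 0° and flags it;
* internal cylinders are signed steep-minus-flat, so with-the-rule
  astigmatism has $C_0 > 0$.

## Cohort pipeline

`read_cohort_csv()` reads one eye per row in the device vocabulary
(`IOLMR1a`, `IOLMA1a`, …, `CASIAP1r_pre`), with a user-overridable column
map; unparseable cells become `NA`, never zeros. `apply_exclusions()` drops
records with `Failed`/`Warning` quality flags (case-insensitive; any other
string passes, flags are opaque), missing measurements or biometry,
mydriatic pupils (strictly $> 5.5$ mm at either visit — the conservative
reading, since the underlying rule does not say which visit it applies to)
or a pupil change strictly $> 1.5$ mm, and then keeps one random eye per
patient. That draw has its own seed, deliberately independent of the
train/validation/test split seed, so the two randomisations are separately
reproducible. `decompose_cohort()` then yields the panel of power vectors
per device (IOLM, CASIA pre, CASIA post) and layer (front, back,
keratometric, total), where "total" is total keratometry for the biometer
and real power for the OCT.

`summarize_panel()` reports mean, SD (n−1), median and the empirical
2.5th/97.5th percentiles. The percentile bounds are what the field's
summary tables label a "95% confidence interval"; they are computed with
the linear-interpolation quantile rule (`type = 7`), fixed and documented,
not as mean ± 1.96 SD.

## Confidence ellipses

`confidence_ellipse()` eigendecomposes the sample covariance of a
$(C_0, C_{45})$ cloud; half-axes are $\sqrt{\lambda_i\, q}$ with
$q = \chi^2_2(\text{level}) = -2\ln(1-\text{level})$, so the 90% ellipse of
a unit-covariance cloud has half-axes $\sqrt{4.605} \approx 2.146$ dpt.
This is the large-sample (population-coverage) scaling; because the
published analysis names only "eigenvalue decomposition", the small-sample
F-based factor $2(n-1)/(n-2)\,F_{2,n-2}$ is offered behind
`small_sample = TRUE` as a sensitivity check rather than a default. Monte
Carlo coverage for bivariate normal data at $n = 10^5$ falls in
$[0.88, 0.92]$ (tested). `double_angle_plot()` draws the clouds with
0.25/0.5/1.0 dpt reference rings, centroids, ellipse outlines and axes, and
wtr/atr annotations.

```{r ellipse, fig.alt = "Double-angle plot with 90% confidence ellipse"}
co <- generate_cohort(synthetic_config(n_eyes = 88, seed = 7))
panel <- decompose_cohort(apply_exclusions(co$records, seed = 1)$retained)
pts <- panel_block(panel, "CASIA_post", "total", c("C0", "C45"))
e <- confidence_ellipse(pts)
e
double_angle_plot(list(`real power (post)` = pts), e)
```

## Predicting postoperative real-power astigmatism

Both predictors map the two preoperative keratometric components
$(C_0, C_{45})$ — equivalent power is deliberately excluded from the
inputs — to the postoperative real-power components, minimising the mean
squared prediction error per eye,
$\tfrac12\left(\Delta C_0^2 + \Delta C_{45}^2\right)$, averaged over eyes.
The cohort is split 70/15/15 into training/validation/test; the training
size is `round(0.7 n)` and the remainder is divided validation-first, which
reproduces 62/13/13 for $n = 88$.

**Multivariate regression.** `fit_pv_regression()` fits
$y = A x + b$ by least squares and stores the bivariate Gaussian
log-likelihood of its residuals (ML covariance). Because left eyes are
mirrored, a fitted right-eye model converts to the left-eye model by
negating both off-diagonal entries of $A$ and the second intercept
component (`mirror_model_for_eye`), an exact equivariance that is tested.
An iteratively-reweighted bisquare variant (`robust = TRUE`) is available;
the default remains ordinary least squares, which is the objective the
error metric defines. Published coefficient sets (IOLM- and CASIA-based, OD
and OS) ship with the package:

```{r refmodels}
mods <- reference_models()
mods$iolm_od
apply_regression(mods$iolm_od, c(0, 0))  # the published intercept
```

**Network.** `train_network_lm()` trains a 2→10→8→2 feedforward network —
deliberately small, matching the published architecture — with
Levenberg–Marquardt over the full weight vector. Design choices where the
source is silent: tanh hidden activations with a linear output and
training-set z-scoring of inputs (the standard recipe for LM-trained
shallow regression networks); damping $\lambda_0 = 10^{-3}$, divided by 10
on an accepted step and multiplied by 10 on a rejected one, with
$\lambda \cdot \mathrm{diag}(J^\top J)$ scaling so the damping is invariant
to parameter scale; weights initialised $N(0, 1/\text{fan-in})$ with zero
biases. A step is accepted only if it decreases the training objective, so
the recorded training curve is strictly decreasing; "back-projection with
the validation set" is interpreted as validation-based early stopping
(patience 6, consistent with single-digit best epochs), and the returned
weights are those of the validation-optimal epoch. The analytic Jacobian
is verified against finite differences in the tests.

```{r predict}
x <- panel_block(panel, "IOLM", "keratometric", c("C0", "C45"))
y <- panel_block(panel, "CASIA_post", "total", c("C0", "C45"))
sp <- split_dataset(nrow(x), seed = 7)
fit <- fit_pv_regression(x[sp$train, ], y[sp$train, ])
net <- train_network_lm(init_network(seed = 7), x, y, sp)
c(regression = mean_squared_pe(predict(fit, x[sp$test, ]), y[sp$test, ]),
  network = mean_squared_pe(predict(net, x[sp$test, ]), y[sp$test, ]))
plot(net)
```

`prediction_error_stats()` assembles the fit-error table (observed minus
predicted per component per model) and the error-cloud ellipses for
double-angle display.

## The synthetic cohort generator

No clinical dataset is distributed, so `generate_cohort()` emulates one.
The truth model is specified in power-vector space, where the analysis is
linear — axis distributions *emerge* from the Gaussian $(C_0, C_{45})$
model rather than being sampled directly:

* front surface: Gaussian (EQ, $C_0$, $C_{45}$) with the published
  preoperative OCT marginals (means 48.67/0.81/0.03 dpt, SDs
  1.76/1.59/0.83 dpt); N = 88 eyes, 39 of them left, by default;
* back surface: front radii divided by a front-to-back ratio
  $1.1939 \pm 0.03$ — chosen so the mean front/back EQ ratio is the
  published $\approx -7.87$ — with 1.2% per-meridian log-normal jitter and
  an extra $-0.20$ dpt against-the-rule $C_0$ offset. Jitter plus offset
  make back astigmatism correlated with, but not proportional to, front
  astigmatism, which is precisely the phenomenon that defeats fixed-ratio
  keratometer indices (tested: the generated back $C_0$ mean exceeds twice
  the fixed-ratio prediction);
* devices: readings are truth plus a bias vector plus Gaussian noise. The
  published difference tables constrain only sums of variances, so the
  split is a modelling choice: the surgical change receives half of the
  post-minus-pre difference variance and each OCT reading a quarter, and
  the biometer noise absorbs the remainder of the post-minus-IOLM variance.
  Bias defaults derive from the published difference means (e.g. the
  biometer under-reads the negative back-surface power by 0.40 dpt, giving
  the $-8.38$ front/back ratio);
* composite layers: total keratometry / real power are the sums of the
  measured surfaces plus small equivalent-power offsets (0.11/0.20 dpt)
  matching the published composite means;
* teacher: by default the postoperative real-power $(C_0, C_{45})$ follow
  the published OD IOLM-based coefficients applied to the measured
  preoperative keratometry plus $N(0, 0.3^2)$ residuals, so regression and
  network recovery tests have a known answer;
* raw columns are produced by inverting the decomposition at full
  precision; with all noise, bias and surgical change set to zero,
  `decompose_cohort()` reproduces the configured truth to $10^{-9}$
  (tested). Infeasible radii are resampled with a warning (bounded
  retries).

What the generator does **not** emulate: between-device correlation beyond
the shared truth (no correlated device errors), age/axial-length/power
correlations (biometry columns are independent Gaussians), repeated-measure
variability, and instrument physics. Passing tests therefore demonstrate
the correctness of the estimators under the stated generative model, not
clinical performance on real corneas.

`inject_quality_issues()` plants known fractions of `Warning`/`Failed`
flags, missing cells, mydriatic pupils and large pupil changes, recording
the affected ids so the exclusion filter can be checked for exact
bookkeeping.

## Numerical choices and problem sizes

Tolerances: round-trip identities are asserted at $10^{-9}$; noiseless
regression recovery at $10^{-8}$; noisy recovery at $\pm 0.05$ per
coefficient for a 2000-eye cohort with 0.3 dpt residuals. Degenerate
inputs: singular covariances raise errors (no silent pseudo-inverses), a
perfect regression fit raises a degenerate-likelihood error, constant
predictors reduce the regression to column means. The test suite uses
cohorts of 10–2000 eyes and a $10^5$-point Monte Carlo for ellipse
coverage, sizes at which every check runs in seconds on a single core.

## Known limitations

The published per-cohort tables (means/SDs of a specific clinical
population), the printed log-likelihoods and the exact training curves
depend on the unavailable clinical dataset and are therefore replayed from
the bundled coefficient sets or replaced by property-based checks, not
re-estimated. The thin-lens tIOL model ignores lens geometry; no vergence
propagation or raytracing is attempted; and the published summary tables
are themselves mutually inconsistent at the $10^{-2}$ dpt level for paired
differences, so the generator's defaults reproduce the difference tables
rather than both simultaneously.
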