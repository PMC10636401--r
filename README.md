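# anchordecomp

Decomposing perceptual anchoring effects into response-bias and sensitivity
components, with a reaction-time analysis of perceived uncertainty.

## The problem

In a two-phase anchoring paradigm an observer views an image and first judges
whether the percentage of a visual feature is **below or above a numeric
anchor** (a relative judgment), then types an **absolute estimate** of that
percentage. With 7 anchor levels crossed with 7 true feature percentages
(20%–80% in 10-point steps, 7 exemplars per cell, 343 two-phase trials per
participant), both responses can be analysed psychophysically, per
participant and per anchor:

- **Relative judgments.** The proportion of "larger" responses against the
  true percentage x follows a logistic psychometric function
  p(x) = Λ((x − μ)/s). The **PSE** (point of subjective equality, = μ) is the
  stimulus level where "larger" and "smaller" are equally likely and indexes
  *response bias*; the **DL** (difference limen) is half the distance between
  the 25% and 75% points, DL = s·ln 3, and indexes *sensitivity* (larger DL =
  poorer discrimination). Anchors that shift the PSE bias the decision;
  anchors that change the DL change perceptual sensitivity.
- **Absolute estimates.** The mean estimate is linear in x; the fitted line
  gives the analogous indices PSE = (50 − intercept)/slope (level judged as
  50%) and DL = 25/slope (shallower slope ⇔ larger DL ⇔ poorer sensitivity).
- **Reaction times.** Mean log RT against x forms an inverted-U whose peak —
  the **point of maximal uncertainty (PMU)** — is located by waveform-moment
  (centroid) analysis of the baseline-shifted curve, with a quadratic-vertex
  estimate as cross-check.

The inferential layer is a 7×7 within-subject ANOVA (with partial η² and
Greenhouse–Geisser ε), one-way repeated-measures ANOVAs of the per-anchor
indices, and the ordered linear anchor contrast (−3,−2,−1,0,+1,+2,+3), which
can be stratified by feature percentage to locate where anchoring is
strongest.

Because the package is exercised on a **synthetic observer cohort** whose
generative model mirrors the design (assimilative PSE bias, anchor-modulated
DL, anchor-dependent PMU shift), every stage is testable by parameter
recovery without any external dataset.

## Worked example

The `analysis/` directory is a numbered workflow over the package functions;
run the stages in order from the repository root:

```sh
Rscript analysis/01_simulate.R          # 75 participants x 343 trials, seed 1
Rscript analysis/02_preprocess.R        # 3-SD RT exclusion, 49-cell summaries
Rscript analysis/03_psychometric_fits.R # logistic + linear fits, PSE/DL
Rscript analysis/04_rt_uncertainty.R    # PMU by waveform centroid
Rscript analysis/05_inference.R         # RM-ANOVAs + linear contrast
```

Stage 3 prints (seed 1):

```
Mean relative PSE by anchor (20..80): 53.7 51.8 51.3 48.9 48.3 46.9 45.4
Mean relative DL  by anchor (20..80): 5.9 6.6 6.4 7.4 8.4 8.9 9.2
Mean absolute DL  by anchor (20..80): 27.8 30.0 32.6 35.5 32.5 29.9 27.6
Fitted PSE-vs-anchor slope -0.135 (generative mean -0.149)
```

Higher anchors pull the PSE down (more "larger" responses — an assimilative
bias of about −0.14 percentage points of PSE per anchor point, recovering the
generative −0.15) while the relative DL grows (sensitivity loss); the
absolute DL instead peaks at the moderate anchor (50). Stage 4 shows the
uncertainty peak moving up with the anchor for relative judgments
(43.4 → 56.2) and down for absolute estimates (55.7 → 43.5), and stage 5
reports the within-subject tests in the conventional style, e.g.

```
relative_pse   anchor   F(6, 444) = 57.28, p < .001, eta_p^2 = 0.44
Largest anchoring magnitude at the 40% level
```

with the stratified linear contrast confirming that anchoring is strongest
where the stimulus is most ambiguous (near 50%).

The same pipeline runs as a single call: `run_pipeline(run_config(mode =
"full", seed = 1), "results/run")` writes every stage table, a text report
with directional-pattern checks, and a run log.

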