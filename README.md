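# synthrs

Can a **synthesized** MR contrast replace an **acquired** one inside a
radiomics-based survival classifier for glioblastoma? `synthrs` implements
the full machinery to ask that question quantitatively, end to end, on
synthetic relaxometry phantoms — no external data required.

## What it does

**Physics-constrained self-supervised synthesis.** A compact convolutional
network with two encoders (one per input contrast, e.g. T1w + T2w), a
pixel-wise max fusion of the latents, and three decoders predicting
quantitative relaxometry maps — longitudinal relaxation T1, transverse
relaxation T2 and proton density PD. A *non-trainable physics layer* then
evaluates the ideal signal equations on the predicted maps to synthesize
the target contrast (e.g. FLAIR):

* spin echo: `S = PD · (1 − exp(−TR/T1)) · exp(−TE/T2)`
* inversion-recovery spin echo (magnitude):
  `S = PD · |1 − 2·exp(−TI/T1) + exp(−TR/T1)| · exp(−TE/T2)`

Training minimizes `L_syn`, the batch-average mean absolute error between
acquired and synthesized images — self-supervised: no map ground truth is
ever read. A leave-one-out protocol trains one model per held-out subject
(remaining subjects split ~80/20 for early stopping, e.g. 18/5/1 at
cohort size 24).

**A radiomic survival system.** Contralateral-white-matter intensity
normalization; a handcrafted feature bank where each column carries its
provenance `contrast.ROI.family.feature` (first-order, gray-level
co-occurrence and shape features over tumor sub-regions ET, NET, ED and
their unions TC, WT); greedy mRMR feature selection; nested
cross-validation (Brier loss in the inner loop, AUC in the outer loop)
over five classifier families; survival dichotomized at 480 days
(16 months) with a strict `>` rule and a principled censoring policy.

**The replacement protocol.** Three experiments on a common test cohort:
(I) all four channels acquired; (II) one channel replaced by its
leave-one-out synthesized version — same trained classifier, hard audit
that no test subject entered its own synthesis fold; (III) a classifier
trained from scratch without that channel. Agreement between experiments
is quantified by identity-regression R², the absolute-agreement ICC and
probability-difference summaries, and synthesis quality by MSE/SSIM/PSNR
on the smallest foreground box.

**A phantom cohort generator.** Seeded brain-like T1/T2/PD phantoms with
tissue classes (WM/GM/CSF), nested tumor sub-regions, four simulated
contrasts with Rician noise, and log-normal survival times linked to
lesion volume and to a planted FLAIR-dominant texture covariate
(proteinaceous microcysts in edema, nulled by the FLAIR inversion time).

## A worked example

```r
library(synthrs)

report <- run_replacement_study(
  seed = 7, n_train = 100, n_test = 8, grid_shape = c(32, 32, 12),
  replaced_contrast = "FLAIR", noise_sigma = 0.01,
  radius_range = c(0.50, 0.70), families = c("lr", "xgb", "rf"),
  k_values = 8, outer_folds = 5, inner_folds = 5,
  synth_width = 8, synth_epochs = 26, synth_batch = 2)
print(report)
```

```
Replacement study (replaced contrast: FLAIR )
  experiment_I    AUC 0.867  acc 0.750  prec 0.733  rec 0.733  F1 0.733
  experiment_II   AUC 0.933  acc 0.750  prec 0.733  rec 0.733  F1 0.733
  experiment_III  AUC 0.933  acc 0.875  prec 0.875  rec 0.900  F1 0.873
  agreement I-II : R2 0.591  ICC 0.826
  agreement I-III: R2 -0.261  ICC 0.657
  synth mse   mean 0.9401 (sd 0.8472)
  synth ssim  mean 0.2838 (sd 0.3287)
  synth psnr  mean 10.7703 (sd 6.3524)
```

Reading it: with the acquired FLAIR replaced by its leave-one-out
synthesized version (II), the classifier performs on par with the
all-acquired baseline (I) and its per-subject survival probabilities
agree with it more closely (ICC 0.83) than those of the system that never
had the channel (III, ICC 0.66). A word of caution that applies to every
run at this scale: an 8-subject test cohort makes individual AUCs and
quality metrics noisy, so single-seed numbers carry little information —
the acceptance suite therefore compares experiments by averaging over ten
cohort seeds (where replacement beats ablation, mean AUC 0.65 vs 0.61,
and stays within 0.08 of the acquired baseline), and the methods vignette
discusses how much of the replaced channel's information physically leaks
into the remaining channels.

Individual pieces are exposed too: `generate_cohort()`,
`train_self_supervised()`, `leave_one_out_synthesize()`,
`parameter_recovery_experiment()` (trains on raw intensities with a
multi-contrast loss and measures map-recovery error on held-out
phantoms), `nested_cv_select()`, `evaluate_rs()`, and the metric
primitives (`ssim_metric()`, `icc_agreement()`, `r2_identity()`, ...).
A thin CLI wraps the pipeline: `inst/cli/synthrs simulate-cohort ...` and
`inst/cli/synthrs run-experiments --replace flair --seed 7 --out run1`.

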