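# stdgnn

Forecasting post-chemoembolization DCE-MRI of hepatocellular carcinoma
with a spatio-temporal discriminant graph neural network.

## The problem

Transarterial chemoembolization (TACE) helps only a fraction of the
hepatocellular carcinoma (HCC) patients who receive it, and response is
only known weeks later from a follow-up exam. Dynamic contrast-enhanced
MRI (DCE-MRI) — T volumetric acquisitions during contrast passage, here on
the phase grid 10 / 60 / 100 / 145 / 320 s post-injection — carries the
perfusion signature of the tumor's viability. Given only the
*pre*-treatment sequence and the tumor annotation, `stdgnn`:

1. classifies the future viability class — viable (V), equivocal (E),
   non-viable (NV);
2. generates the expected *post*-treatment sequence and tumor mask;
3. extracts standard perfusion measures from any sequence + ROI.

## The model

Pooled patch features from each phase become nodes of discriminant graphs:
`W_w` links each node to its nearest same-class neighbours, `W_b` to its
nearest other-class neighbours, both normalized as
`W_hat = D^(-1/2)(W + I)D^(-1/2)`, with Laplacian `L = Diag − W`. A
temporal branch propagates all T×P nodes through K graph-convolution
layers of the between-minus-within form

    X^(k) = W_bt_hat X^(k-1) B_k − W_wt_hat X^(k-1) B_k

(BatchNorm + LeakyReLU per layer, residual shortcuts from layer 2), a
structural branch runs an M-layer version per volume, and a global
generator branch pools per-phase patch projections. The fused features
drive a viability softmax and a decoder that emits the follow-up phase
volumes and a voxelwise tumor-mask softmax; a convolutional discriminator
provides the adversarial term

    E_adv = −E[log D(real)] − E[(φc + ξ) log(1 − D(fake))]

whose transport weight `c` is the mean pairwise sliced-Wasserstein
distance between the class-conditional feature distributions of the batch.
Per training step the losses combine exactly as

    E_triplet_global = E_tumor + λ_w E_weight + λ_a E_adv
    E_overall = E_triplet_global + E_triplet_t + E_triplet_s + E_softmax

with λ_w = 0.2, λ_a = 0.5, φ = 30, ξ = 0.35, batch-hard triplet losses on
the branch embeddings, and the graph-weight cosine divergence `E_weight`.

The kinetic side uses the dual-input single-compartment model
`dC/dt = Ka·AIF(t) + Kp·PIF(t) − K2·C(t)` with arterial fraction
`ART = Ka/(Ka+Kp)` and distribution volume `DV = 100(Ka+Kp)/K2`, plus the
non-parametric descriptors T0, TTP, ΔS, PER, nMITR and wash-in/wash-out
slopes.

Real TACE cohorts are IRB-restricted, so the package ships a phantom
module: spherical tumors with class-specific kinetics (viable tumors
strongly arterialized, non-viable hypovascular), class-specific
post-treatment shrinkage/devascularization, gamma-variate vascular input
functions, smooth texture and configurable noise. Every downstream stage
is validated against this known ground truth; see the methods vignette
(`vignettes/stdgnn-methods.Rmd`) for what that does and does not show
about clinical data.

## Worked example

```r
library(stdgnn)

# a small cohort of synthetic pre/post pairs (ground truth known)
cohort <- generate_cohort(4, phantom_spec(), seed = 42)
cohort[[1]]$pre
#> <dce_sequence 'phantom_V_1230326049'> pre, T=5 phases at t=[10, 60, 100, 145, 320] s,
#>   48x48x16 voxels, spacing 1.9x1.9x2.5 mm, mask 467 vox, label V

# non-parametric perfusion descriptors of the annotated tumor
pf <- perfusion_analysis(cohort[[1]]$pre, cohort[[1]]$truth$mask_pre)
round(unlist(pf[c("T0", "TTP", "PER", "nMITR", "wash_in", "wash_out")]), 4)
#>       T0      TTP      PER    nMITR  wash_in wash_out
#>  60.0000  60.0000   0.4906   0.0082   0.0098   0.0019
# times in s, slopes in 1/s on S0-normalized intensity: a fast-enhancing
# lesion peaking at the 60 s phase with a 49% peak enhancement ratio

# parametric inversion of the kinetic model (densely sampled curve;
# ROI fits on the 5-phase clinical grid are weakly identifiable)
times <- c(seq(5, 150, by = 10), seq(170, 320, by = 30))
inp <- make_input_functions(times)
C <- simulate_tissue_curve(0.005, 0.010, 0.008, inp$aif, inp$pif, times)
round(unlist(fit_dual_input_model(C, inp$aif, inp$pif, times)[
  c("Ka", "Kp", "K2", "DV", "ART")]), 4)
#>       Ka       Kp       K2       DV      ART
#>   0.0050   0.0100   0.0080 187.4965   0.3333
# exact recovery of the simulated (Ka, Kp, K2) = (0.005, 0.010, 0.008) 1/s

# train a small model (5 epochs for illustration) and predict a follow-up
cfg <- desk_config(seed = 1)
state <- train_stdgnn(cohort, cfg, epochs = 5, verbose = FALSE)
pred <- predict_sequence(cohort[[1]]$pre, state)
pred$viability_class
#> [1] "V"
round(pred$class_probabilities, 2)
#>    V    E   NV
#> 0.38 0.37 0.25
round(tail(state$history[, c("E_tumor", "E_adv", "E_softmax", "E_overall")], 1), 3)
#>    E_tumor E_adv E_softmax E_overall
#> 10   0.165 0.934     0.234     0.867
```

`train_stdgnn()` logs every loss component per step (`state$history`), so
the printed decomposition above can be checked on any run. The reference
experiment of the package (30 phantom pairs per class, 100 epochs, desk
profile) reaches >80 % held-out 3-class accuracy, >0.6 mean post-mask
Dice, and shrinking predicted tumors for at least 80 % of non-viable cases.

## Command line

A thin CLI over the package functions lives at `inst/cli/stdgnn.R`:

```sh
Rscript inst/cli/stdgnn.R simulate --n-per-class 10 --out cohort/ --seed 7
Rscript inst/cli/stdgnn.R train --data cohort/ --out run/ --seed 7
Rscript inst/cli/stdgnn.R predict --seq cohort/case_001_pre --model run/checkpoint.rds --out pred/
Rscript inst/cli/stdgnn.R perfusion --seq cohort/case_001_pre --roi cohort/case_001_pre/mask.nii.gz --out perfusion.csv
```
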