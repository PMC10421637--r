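# spinbench

Benchmarking **direct coupling analysis (DCA)** against **local
correlation thresholding** for reconstructing pairwise interaction
networks from equilibrium samples of spin models, across the
order–disorder phase transition.

## The scientific problem

Given K configurations sampled from a pairwise model — a ferromagnetic
Ising model

&nbsp;&nbsp;&nbsp;&nbsp;H(σ) = −Σ_{i<j} J_ij σ_i σ_j − Σ_i h_i σ_i,&nbsp;&nbsp;σ_i ∈ {−1, +1},&nbsp;&nbsp;P(σ) ∝ e^{−H/T}

or its q-state Potts generalisation with Kronecker-delta interactions —
which vertex pairs carry a true interaction J_ij = 1?  Two families of
methods compete:

* **local inference** scores each pair by its raw empirical correlation
  ⟨σ_i σ_j⟩ — cheap, data-efficient, but blind to whether a correlation
  is direct or mediated through other spins;
* **global inference** (mean-field DCA) estimates couplings by naive
  mean-field inversion, **βĴ = −C⁻¹** (off-diagonal), with C the
  connected correlation matrix, and scores each pair by the *direct
  correlation* of a two-spin model with coupling βĴ_ij and fields matched
  to the empirical marginals.

The ground truth here is a synthetic world drawn exactly as specified:
couplings J_ij ~ Bernoulli(λ/n) (an Erdős–Rényi graph with mean degree λ,
mean-field critical temperature T_c = λ), zero field, and Boltzmann
samples from an exact coupling-from-the-past sampler or a
symmetry-relabelled Gibbs chain.  Because everything is known, one can
measure ROC discriminability (AUC), rms coupling error, the topology of
false positives, and even how informative the data are about the graph at
all — via an importance-sampling estimator of the f-divergence
(Jensen–Shannon by default) between models on different graphs, with the
closed mean-field form D ∝ ‖ΔJ‖₁ (1 − Δ(T)⁴)/T² peaking at T/T_c ≈ 0.83.

The headline phenomenology the package reproduces: inference is best at
*intermediate* temperature (thermal noise above, macroscopic order below);
local correlations beat DCA whenever data are scarce; DCA wins in the
ordered phase once data are plentiful.

## Worked example

```r
library(spinbench)

J <- generate_er_couplings(n = 100, mean_degree = 40, seed = 1)
model <- spin_model(J, temperature = 0.85 * critical_temperature(40))
samples <- sample_gibbs(model, K = 1e4, seed = 2)

mom <- estimate_moments(samples)
inv <- mean_field_inversion(mom, temperature = model$temperature)
roc_curve(local_scores(mom, truth = J))$auc     # 0.7031767
roc_curve(global_scores(inv, mom, truth = J))$auc  # 0.9424406
rmse_report(inv, J)
#> rmse_report: rmse = 0.4916
#>   class 0: mean 0.0449, var 0.23282 (n = 3021)
#>   class 1: mean 1.1261, var 0.23636 (n = 1929)
```

At T = 0.85 T_c with K = 10⁴ samples, DCA (AUC 0.94) clearly beats raw
correlations (AUC 0.70): macroscopic order induces strong indirect
correlations that the global model discounts.  The rms report shows the
inferred couplings clustering near the true values 0 and 1.  Starve the
same run of data and the ordering flips:

```r
small <- subset_samples(samples, 500)
ms <- estimate_moments(small)
is <- mean_field_inversion(ms, temperature = model$temperature)
roc_curve(local_scores(ms, truth = J))$auc      # 0.6341849
roc_curve(global_scores(is, ms, truth = J))$auc # 0.6218091
```

Experiment drivers wrap the full sweeps
(`run_discriminability()`, `run_threshold_topology()`, `run_rmse_sweep()`,
`run_potts_comparison()`, with figure-style parameter `preset()`s), and
`mean_field_curve()` / `divergence_sweep()` cover the mean-field theory
and the f-divergence analysis.  A command-line dispatcher lives at
`inst/cli/spinbench.R` (`graph`, `sample`, `meanfield`, `infer`,
`evaluate`, `diverge`).

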