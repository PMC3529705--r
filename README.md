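# zirbayes

Bayesian model selection for compartmental biokinetic models of zirconium
processing in humans.

After ingestion, a zirconium tracer moves through the gastrointestinal
tract, is partly absorbed into blood plasma, exchanges with soft tissue and
bone, and leaves the body through urine and feces. Two competing linear
compartmental structures describe this: an ICRP-type model (11 compartments,
15 first-order transfer rates, two bone-surface pools with direct transfers
to the excretion pathway) and an HMGU-type model (10 compartments, 12
rates, one combined bone pool exchanging with plasma). Which structure
better explains plasma-concentration and urine-excretion measurements is a
Bayesian model-selection question, and its answer matters for internal
dosimetry: the two models predict different bone retention of radioactive
$^{95}$Zr and different retrospective intake estimates from urine bioassays.

`zirbayes` is for researchers in internal dosimetry and, more broadly,
anyone doing ODE-based Bayesian model comparison. It implements the full
workflow:

* **kinetics** — exact trajectories $y(t) = e^{A t}\,y(0)$ by
  eigendecomposition of the system matrix (mass-balance structure, column
  sums zero), analytic urine excretion rates, $^{95}$Zr decay correction
  (half-life 64.032 d);
* **likelihood** — two-channel Gaussian:
  $L(x) = \prod_\alpha \Phi(y_1^{(\alpha)} | c^b_x(t_\alpha), \sigma_b)
  \prod_\beta \Phi(\dot y_7^{(\beta)} | \tfrac{d}{dt}c^u_x(t_\beta), \sigma_u)$,
  with noise SDs fitted per investigation by simulated annealing
  ($\sigma$ profiled out in closed form);
* **priors** — independent lognormal / normal / triangular priors per rate,
  truncated at zero (bundled hyperparameters are documented placeholders);
* **evidence** — thermodynamic integration over the power posterior
  $p_\tau \propto L^\tau p$ on the fifth-power ladder
  $\tau_n = ((n-1)/(N-1))^5$, $N = 30$, trapezoidal rule, with Monte Carlo
  standard errors;
* **sampling** — independence Metropolis–Hastings with a copula proposal:
  prior-CDF marginal conversion, Gaussian dependence fitted on an adaptive
  prerun, MAP initialisation, autocorrelation-based effective sample size
  and thinning;
* **model selection** — Bayes factors $B_{k,k'} = p(D|k)/p(D|k')$ on
  Jeffreys' scale ($>3$ substantial, $>100$ decisive), per investigation
  and for the concatenated study, for both channels jointly or each alone;
* **dosimetry** — posterior bone-retention credible bands and retrospective
  intake estimation from a urine measurement by linear inversion, including
  an extrapolation-factor table (6–60 h);
* **synthetic data** — a generator emulating the underlying human study
  (16 investigations, dense day-1 plasma sampling out to 100 d, pooled
  urine collections, up to ~50-fold between-investigation peak spread),
  which stands in for the undeposited original dataset.

## Worked example

Simulate one investigation from the HMGU structure, fit the noise SDs and
the MAP, and compare both models by thermodynamic integration at reduced
desk-scale settings:

```r
library(zirbayes)

model <- zr_model("hmgu")
prior <- zr_prior("hmgu")

set.seed(42)
truth <- rate_vector(model, rprior(prior, 1)[1, ])
inv <- generate_investigation(model, truth, seed = 7)
inv
#> <investigation> inv1: n_b=18 plasma, n_u=13 urine, plasma mass 3 kg (synthetic, truth recorded)

sa  <- sa_control(n_temps = 15, n_iter = 80)
ctl <- sampler_control(n_proposals = 2000, prerun_n = 2500, sa = sa)

fit_h <- fit_noise(model, inv, prior, control = sa, seed = 1)
ev_h  <- estimate_evidence(model, inv, prior, fit_h$noise,
                           schedule = make_schedule(10), control = ctl,
                           seed = 11)

icrp   <- zr_model("icrp"); prior_i <- zr_prior("icrp")
fit_i  <- fit_noise(icrp, inv, prior_i, control = sa, seed = 2)
ev_i   <- estimate_evidence(icrp, inv, prior_i, fit_i$noise,
                            schedule = make_schedule(10), control = ctl,
                            seed = 12)

bayes_factor(ev_h, ev_i)
#> <bayes_factor> B(HMGU,ICRP) = 1.344e+11 (log10 11.13): decisive

ev_h
#> <evidence_result> model HMGU (both): log evidence 84.085 (MC se 0.874)
#>   10 temperatures, 2000 proposals each; acceptance 0.08 +/- 0.03, ESS 19 +/- 6
```

The log evidences are estimated by tempered chains (10 temperatures here;
30 at study scale); a Bayes factor of about $10^{11}$ decisively favours
the structure the data were generated from. At these strongly reduced
settings the run warns about low effective sample sizes at some
mid-ladder temperatures — the per-temperature acceptance rates, ESS and
the Monte Carlo standard error of the log evidence are all carried in the
result so that precision is visible.

Downstream, a posterior sample of rate vectors gives bone retention and
retrospective intake estimates:

```r
post <- rprior(prior, 200)          # posterior stand-in for illustration
bone_retention(model, post, times = c(1, 10, 50), apply_decay = TRUE)
intake_from_urine(post, model, t = 2, measurement = 50)  # 50 ug/d at 2 d
extrapolation_table(post, model)    # lbf/mf/ubf multipliers, 6-60 h
```

## The analysis workflow

The `analysis/` directory holds the study as numbered drivers over the
package (run them in order from the repository root; outputs land under
`results/`):

1. `01_simulate_study.R` — the 16-investigation synthetic study
   (high-variability preset);
2. `02_fit_noise_and_map.R` — per-investigation noise SDs and MAP rate
   estimates under both models;
3. `03_model_selection.R` — evidences and Bayes factors per investigation
   and for the concatenated data (add `--study-scale` for the full
   30 × 30,000 sampler settings);
4. `04_bone_retention.R` — posterior bone-retention bands with and without
   $^{95}$Zr decay correction;
5. `05_dose_assessment.R` — the extrapolation-factor table, a worked
   intake example, and posterior diagnostics (Kolmogorov–Smirnov comparison
   of rate marginals between investigations, Kendall's tau of the
   absorption-rate pair).

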