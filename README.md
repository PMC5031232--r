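# seqmetabias

Quantify the biases that creep into a cumulative meta-analysis when the
trials it pools are not independent of its own interim results.

Evidence-based research practice encourages exactly that dependence: the
existing meta-analysis is consulted to decide *whether* a further trial is
worth running, and to *size* it. `seqmetabias` is for meta-analysts and
trial statisticians who want to know how much bias those two habits
introduce:

* **Sequential decision bias.** If the probability
  `p(theta_hat_1, s_1^2, theta_0)` of conducting the next trial is
  correlated with the current pooled estimate, then with `omega_1` the
  first stage's normalised inverse-variance weight and
  `C = Cov{p(theta_hat_1), theta_hat_1}`,

  ```
  E[theta_(2)]          = theta + (omega_1 - 1) C
  E[theta_(2) | run]    = theta + omega_1 C / E[p]
  E[theta_(2) | stop]   = theta - C / (1 - E[p])
  ```

  so the pooled estimate is biased unconditionally *and* on both branches
  of the decision — typically downward overall, upward in the
  meta-analyses that did get their next trial.

* **Sequential design bias.** If the next trial is sized from the
  estimated effect, `n_2 = c^2 sigma_g^2 / (theta_hat_1 + delta)^2 - w_1
  sigma_g^2` with `c = z_{1-alpha/2} + z_{1-beta}`, then stopping
  (`n_2 <= 0`) selects inflated first-stage estimates (closed-form
  truncated-normal expectations), and continuing gives the new trial a
  weight correlated with `theta_hat_1`, biasing the pooled estimate even
  though every individual estimate is unbiased.

The package provides fixed-effect inverse-variance pooling, four
probability-of-next-trial models (power-law, extreme-value, probit,
power-calculation window), quadrature bias decompositions with a K-step
recurrence, closed-form stopped-trial expectations and a design-bias
bound, a fully seeded Monte-Carlo engine (decision and design simulations,
parameter-grid sweeps), and a packaged worked example. A thin command-line
wrapper lives at `inst/cli/seqbias.R`.

## Worked example

The packaged case is a nine-study meta-analysis of two fluoride
dentifrices (mean-difference dental decay scores). After its first trial
(estimate 0.86, effective size 61.30, variance 19.94), should a second
trial — viable only at 200 to 2000 patients, i.e. effective sizes in
(50, 500] — be run, and what does that rule do to the evidence base?

```r
library(seqmetabias)
power_constant(0.05, 0.2)
#> power constant c = 2.8016 (c^2 = 7.8489) for alpha = 0.05, beta = 0.2

fx <- johnson_fixture()
run_decision_report(fx, reps = 10000, seed = 1)
#>                      quantity    value
#>                             c   2.8016
#>                     c_squared   7.8489
#>                   n2_required 150.3099
#>           p_continue_analytic   0.3455
#>  p_continue_analytic_no_lower   0.4100
#>          p_continue_simulated   0.3443
#>    percent_bias_unconditional -21.2182
#>         percent_bias_continue   6.4909
#>             percent_bias_stop -35.7679
```

Reading the numbers: sizing the second trial from the first estimate asks
for an effective size of about 150 — inside the window, so the trial would
run. Taking the nine-study pooled values (effect 0.28, variance 21.62) as
the truth, quadrature puts the probability of continuation at 0.346
(0.410 with no lower size restriction), and 10 000 simulated repetitions
of the whole procedure agree (0.344). The price of the rule: the pooled
two-trial estimate is biased by about −21% on average, +6 to +8% among
the runs that continued, and −36% among those that stopped — the
completed meta-analyses a reader encounters are the optimistic branch.

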