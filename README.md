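# oneshot

Computational models of one-shot causal learning for trial-based rating
tasks.

When does the brain learn a causal relationship from a single experience
rather than gradually? This package implements, fits and analyses a family of
learning models built around one hypothesis: the learning rate applied to a
stimulus–outcome association is gated by the *relative causal uncertainty*
about that association. It is aimed at computational cognitive scientists who
want to simulate the causal-rating paradigm (rounds of five trials with
16:8:1 stimulus presentation frequencies and a single novel outcome), fit
competing learning models to causal ratings, and reproduce the event-level
analyses that distinguish one-shot from incremental learning.

## The model

The causal-uncertainty learner (BayesU) keeps a Dirichlet belief with
concentrations α over which stimulus causes each outcome type. Causal
strength and causal uncertainty are the posterior mean and variance

    E(θ_i)   = α_i / α_0
    Var(θ_i) = α_i (α_0 − α_i) / (α_0² (α_0 + 1)),   α_0 = Σ_j α_j

and the per-stimulus learning rate is a softmax over uncertainties,

    γ_i = γ_0 · n · exp(τ Var(θ_i)) / Σ_j exp(τ Var(θ_j)),

so the least-resolved stimulus learns fastest. Trial updates add
Δα_i = γ_i (x_i + δ_p·1[first] + δ_r·1[last]) for the delivered outcome type
and subtract it for the other, floored at zero; x_i is the within-trial
presentation count (additive subtype) or a presence indicator (sole).

The competitor zoo covers Rescorla–Wagner, Pearce–Hall, the probabilistic
contrast model, Bayesian causal-structure learning (BDeu-scored DAGs with an
exact enumeration oracle and an MCMC sampler), strength- and constant-rate
Dirichlet variants, a heuristic novelty-pairing rater and a random rater.
Models are fitted by multi-start Nelder–Mead on the sum of squared
differences between causal strengths and normalized ratings, and compared by
round-wise leave-one-out cross-validation.

## Worked example

```r
library(oneshot)

task <- generate_task(40, seed = 7)          # 20 type1 + 20 type2 rounds
task
#> Causal learning task: 40 rounds (20 type1, 20 type2), 5 trials x 5 presentations each

ratings <- simulate_ratings(task, "BayesU", proto_params(tau = 50),
                            noise_sd = 0.5, seed = 1)
head(ratings, 3)
#>   subject round stimulus outcome_type rating
#> 1       1     1        1        novel      1
#> 2       1     1        2        novel      2
#> 3       1     1        3        novel      7

fit <- fit_causal_model("BayesU", task, ratings, n_restarts = 25, seed = 2)
fit
#> Causal learning model fit: BayesU ( additive )
#> parameters:
#>  gamma0     tau delta_p delta_r
#>  0.2025 48.8206  0.2870  0.3253
#> training SSE: 0.2841 over 120 ratings

loocv(fit, seed = 3)
#> Leave-one-out CV of BayesU ( additive ), unit = round
#> 40 folds; mean held-out SSE: 0.007953

traj <- run_bayes_family(task, "BayesU", coef(fit))
classify_events(traj)
#> Event classification at the 90th percentile (threshold 0.2831): 98 OS / 902 IC events
```

The generating parameters (γ₀ = 0.2, τ = 50, δ = 0.35) are recovered almost
exactly, held-out error is two orders of magnitude below the random rater's,
and roughly one stimulus event in ten is classified as a one-shot learning
event, by construction of the 90th-percentile threshold. The mean one-shot
effect index (novel-cue rating minus mean non-novel-cue rating) for this
subject is 7.0 in type2 rounds — the novel cue is blamed for the novel
outcome it accompanied — against 2.9 in type1 rounds.

Other entry points: `compare_causal_models()` for the nine-model LOOCV
table, `simulate_model_suite()` for the 2×2 frequency/outcome-probability
simulation grid with the Granger analysis of uncertainty reduction,
`exact_structure_posterior()` / `mcmc_structure_posterior()` for structure
learning, `gmm_threshold_check()`, `one_shot_effect_index()`,
`build_regressors()` and `regularity_analysis()` for the event-level
analyses, and `run_pipeline()` to run simulate → fit → compare → analyze
end to end from a serialisable config. The methods vignette
(`vignettes/causal-uncertainty-models.Rmd`) documents the model, its
assumptions and every numerical convention.

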