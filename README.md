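# teamnet

Tools for studying the performance of small teams on sequential task
batteries, for researchers in computational social science and teams
research. The package implements a complete analysis pipeline:

1. **Collaboration-network extraction** from timestamped chat logs.
   Message *r* counts as a probable response to *m* when it comes from a
   different sender within a calibrated time window [t₁, t₂] seconds
   (default [1, 17], chosen by maximizing the F₂ score against annotated
   message pairs). Directed edge weights aggregate time-decayed response
   evidence,

   *w(i → j) = Σ exp(−ρ · Δt)* over response pairs, ρ = 0.15 s⁻¹,

   plus sparsified unweighted variants S₂₅/S₅₀/S₇₅ that drop the
   25/50/75% lowest-weight edges.
2. **Feature engineering**: degree, reciprocity and spectral network
   features (notably algebraic connectivity — the smallest positive
   Laplacian eigenvalue, a robustness/well-connectedness summary),
   chat-log summaries (turns, delays, volumes, sentiment), and
   score-dynamics features of each team's observed score prefix (moments,
   best-fit-line geometry, change counts).
3. **Performance modeling**: Pearson screening with Benjamini–Hochberg
   FDR control, and elastic-net regression

   *argmin‖y − Xβ‖² + λ₁‖β‖₁ + λ₂‖β‖²*

   with a sparsity-filtered model selection: only models whose top-6
   coefficients carry ≥ 80% of total coefficient weight survive, ranked
   by 10-fold cross-validated RMSE.
4. **Forecasting baselines** (mean oracle, observed mean, naive, least
   squares, ARMA(1,1)) and per-task RMSE comparison tables.
5. **Online workload allocation**: distributing each task's workload
   over teams on the probability simplex to maximize
   *sᵀω − α‖ω‖²* (exploit vs. explore/fairness, α = 0.2), solved
   exactly by water-filling; eight allocation policies evaluated over
   repeated 75/25 team splits, including an elastic-net dynamics-model
   policy with outlier control (estimates clipped within ±ε = 0.3 of
   each team's observed mean).
6. **A synthetic-data generator** that emulates the study inputs (score
   tables with latent team quality, reply-process chat logs with a
   planted member-affinity matrix, baseline team features, response
   annotations), so the whole pipeline is testable end to end.

## Worked example

```r
library(teamnet)

# a chat-log excerpt shipped with the package
log <- read_chat_log(system.file("extdata/example_chat_log.csv",
                                 package = "teamnet"))
W <- build_collaboration_network(log, response_window(1, 17), rho = 0.15)
W$weights["kate", "nick"]
#> [1] 1.035451

# kate's messages at 2220 s and 2231 s are each answered by nick within
# the window (lags 5, 16 and 5 s), so the kate->nick edge accumulates
# exp(-0.75) + exp(-2.4) + exp(-0.75) ~ 1.035: nick responds to kate
# quickly and repeatedly.

sparsify(W, 0.5)
#> <sparse_network> 4 members, 3 edges (50% lowest-weight dropped)

# score-dynamics features of an improving team
dynamics_features(c(0.2, 0.4, 0.6))[c("mean", "fit_slope_rad", "n_increases")]
#>          mean fit_slope_rad   n_increases
#>     0.4000000     0.1973956     2.0000000

# optimal workload split for expected scores (0.8, 0.6, 0.4) at alpha = 0.2:
# the weakest team is priced out, the strongest gets three quarters
optimal_allocation(c(0.8, 0.6, 0.4), alpha = 0.2)
#> [1] 0.75 0.25 0.00

# policy comparison on a synthetic 68-team study
st <- gen_score_table(synth_spec(), seed = 2)
evaluate_policies(st, policies = c("uniform", "oracle", "naive", "mean", "ls"),
                  repeats = 100, seed = 2)
#> <policy_evaluation> 100 splits, alpha = 0.2
#>  policy mean_cumulative  relative
#> uniform        8.634960 0.8480841
#>  oracle       10.182410 1.0000000
#>   naive        9.188943 0.9023087
#>    mean        9.762869 0.9587899
#>      ls        9.194715 0.9028964
```

The relative column scales each policy's cumulative payoff by the
non-causal mean-oracle policy: informed causal policies (observed mean,
naive, least squares) recover 90–96% of the oracle's payoff on this
synthetic table, while the uninformed uniform split trails at 85%.

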