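---
title: "Modeling team performance from collaboration networks and score dynamics"
author: "teamnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling team performance from collaboration networks and score dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teamnet)
```

## The problem

Small teams working through an ordered battery of tasks differ widely in
performance even when their members are individually comparable. Two
observable traces of the *team process* carry predictive signal: the
team's own score history over earlier tasks, and the fine-grained
structure of who-responds-to-whom in the team's communication. `teamnet`
implements a pipeline that turns timestamped chat logs and bounded task
scores into these two feature families, fits penalized regression models
of per-task performance, and applies the resulting predictors to an
online workload-allocation problem.

The pipeline assumes: scores are rescaled task-wise to $[0,1]$ by an
affine map of each task's scale (`normalize_scores()`); every team works
the tasks in the same fixed order; and chat logs record, per message, a
timestamp in seconds from session start, the sender's alias, the text,
and optionally a sentiment value in $[-1,1]$ produced by an external
scorer (the package ships only a neutral stub --- sentiment is an input,
not something `teamnet` computes from text).

## Response detection and the collaboration network

Attribution of responses is purely temporal: message $r$ is counted as a
probable response to $m$ when $r$ comes from a different sender and
arrives within a window $[t_1, t_2]$ seconds after $m$,

$$R(m) = \{\, r \mid m.time < r.time,\; t_1 \le r.time - m.time \le t_2,\;
r.sender \ne m.sender \,\}.$$

The window is calibrated against annotated message pairs by maximizing
the $F_2$ score (recall twice as important as precision --- missing a
true response hurts the network more than an extra edge contribution).
The shipped default is $[1, 17]$ seconds. Ties in the calibration grid
are broken toward the narrowest window (smaller $t_2$, then larger
$t_1$); the default grid crosses $t_1 \in \{0.5, 1, \dots, 5\}$ with
$t_2 \in \{5, 6, \dots, 30\}$ seconds, which brackets plausible chat
reply latencies at sub-second-to-half-minute scale.

The collaboration network weights aggregate time-decayed response
evidence,

$$w_{ij} = \sum_{p.sender = i,\ q \in R(p),\ q.sender = j}
e^{-\rho\,(q.time - p.time)},$$

with decay rate $\rho = 0.15\,\mathrm{s}^{-1}$ by default, so a response
after 5 s contributes $e^{-0.75} \approx 0.47$ and one after 17 s
$e^{-2.55} \approx 0.08$. A count-weighted variant (every term replaced
by 1) is available behind a flag; it discards latency information and
typically yields weaker models. Members who never interact have no
edge. Sparse unweighted networks $S_{25}, S_{50}, S_{75}$ drop the
25/50/75% lowest-weight edges --- the removal count uses `floor` (the
conservative reading of "remove X%" for edge counts not divisible by
four), and ties are ordered deterministically by (weight, source,
target), which makes the three sparse networks nested.

Numerical notes. Equal-timestamp messages are never responses (the
strict inequality plus $t_1 \ge 1$ both exclude them); a message may
respond to several antecedents, since the weight definition sums over
all qualifying pairs; and weights are invariant under shifting all
timestamps, which the tests exercise.

## Features

*Network features* (per team, prefixes `wn_`, `sn25_`, `sn50_`,
`sn75_`): mean and standard deviation of in- and out-strengths and their
differences; mean edge reciprocity (per communicating pair,
$\min(w_{ij}, w_{ji}) / \max(w_{ij}, w_{ji})$, averaged); and algebraic
connectivity. Standard deviations over nodes use the population
convention --- these are descriptive statistics of one team's closed
roster, not estimates from a sample. Algebraic connectivity is the
smallest positive eigenvalue of the Laplacian of the symmetrized weights
$(W + W^\top)/2$; symmetrization is the minimal way to apply an
undirected spectral concept to a directed network, and the
smallest-positive convention equals the Fiedler value on connected
graphs while remaining defined on disconnected ones. Topological
features of the sparse digraphs (density, strong/weak component counts,
directed betweenness with $1/((n-1)(n-2))$ normalization) are computed
on the digraph; distances, diameter and local clustering are computed on
the undirected projection of the largest weak component, because sparse
digraphs are rarely strongly connected yet finite diameters are the
quantity of interest. Nodes of undirected degree $< 2$ contribute
clustering 0.

*Chat-log features* (prefix `log_`): total and per-member character and
word counts (members who never wrote count zero), turns taken (maximal
runs of one sender), delay statistics between adjacent messages, and
sentiment mean/sd where sentiment exists --- never zero-filled, so logs
without sentiment yield missing sentiment features. Characters count the
stored message string as-is, including whitespace.

*Score-dynamics features* (prefix `dyn_`, `dynamics_features()`): first
and last observed scores, mean, median, sd and variance (sample
convention, the usual choice for series statistics), skewness (adjusted
Fisher--Pearson) and excess kurtosis, the least-squares line's ordinates
at the first, middle and last index, its slope in radians, last-minus-first
ordinate difference, counts of increases/decreases, and counts of score
changes above/below the median change. Kurtosis uses the unadjusted
excess estimator $m_4/m_2^2 - 3$, which is defined for the shortest
protocol prefix (three observed tasks); the small-sample-adjusted
variant would leave the first predicted task without a kurtosis value.
Ties with the median change count as neither above nor below, tested to
an absolute tolerance of $10^{-9}$ so that float representation of
equal score changes does not break exact ties. Both variance and
standard deviation are emitted although they are functionally redundant;
model selection is free to use either. The "middle" ordinate for
even-length prefixes is the line's value at the (possibly non-integer)
midpoint abscissa $(1 + \mathrm{len})/2$.

## Screening and the performance model

Pearson correlations between every feature and every task score carry
two-sided p-values corrected by Benjamini--Hochberg at FDR 10% (via
`p.adjust`); the *reported* set additionally requires raw $p < 0.05$.
Both knobs are exposed because they play different roles --- BH controls
the discovery rate, the display threshold limits what is tabulated ---
and their interplay is deliberately kept explicit in the
`screening_report`.

The regression model minimizes

$$\hat\beta = \arg\min_\beta\; \|y - X\beta\|_2^2 +
\lambda_1 \|\beta\|_1 + \lambda_2 \|\beta\|_2^2$$

on standardized features, exactly in this scaling (no $1/2n$ factor), so
the penalties are comparable across the fixed study size. The solver is
cyclic coordinate descent in covariance form with warm starts along the
penalty path, followed by an exact linear solve on the recovered active
set with a KKT check; the pure-ridge/OLS limit is solved directly from
the normal equations. This gives closed-form-exact solutions in the
testable limits (OLS at $\lambda = 0$, soft-thresholding on orthonormal
designs) without a generic optimizer.

Model selection (`select_model()`): for every $(\lambda_1, \lambda_2)$
on a grid --- mixing ratios $\lambda_1{:}\lambda_2$ of 100:0, 75:25,
50:50, 25:75, 0:100 crossed with 20 magnitudes log-spaced in $[10^{-3},
10]$ --- the full-data fit must be sparse enough that its six largest
coefficient magnitudes carry at least 80% of the total weight
$\sum_j |\beta_j|$; "weight" is $|\beta_j|$ on standardized features,
the only scale-free reading. Surviving candidates are ranked by 10-fold
cross-validated RMSE of pooled out-of-fold predictions, with fold
assignment fixed by an explicit seed and per-fold standardization
statistics computed on training folds only (the final reported
coefficients use full-data standardization). If nothing survives, or the
winner is all-zero, a degenerate model predicting $\mathrm{mean}(y)$ is
returned --- the expected behavior on tasks with no usable signal. The
dynamics-based protocol fits one model per target task $t \in \{4,
\dots, 15\}$ using features of tasks $< t$ only; baseline and log-based
protocols fit one model per task over all 15.

## Forecasting baselines

Five per-team extrapolators serve as comparison methods and as policy
predictors: the non-causal mean oracle (full-series mean), observed
mean, naive (previous score), least-squares line, and ARMA(1,1) fitted
by maximum likelihood --- the smallest non-trivial ARMA order, since
nothing longer is estimable on prefixes of a 15-task series. Fallback
rules: least squares needs 2 observations and ARMA 4, otherwise the
observed mean; an empty history yields the uninformative prior 0.5; any
ARMA estimation failure (e.g. constant series) falls back too. Because
scores are bounded, forecasts are clipped to $[0,1]$; clipping can be
disabled and is announced when verbose. Forecast-based RMSE tables are
evaluated from task 4 on, matching the dynamics protocol.

## Workload allocation

A manager splits each task's workload over $n$ teams as $\omega$ on the
probability simplex and receives

$$R(t) = s(t)^\top \omega(t) - \alpha \|\omega(t)\|_2^2,$$

exploitation of expected performers minus a quadratic fairness/
exploration penalty, $\alpha = 0.2$ by default --- strong enough that
pathological all-on-one-team allocations are discouraged, weak enough
that scores dominate. For $\alpha > 0$ the optimum has the
water-filling form $\omega_i = \max(0, (s_i - \mu)/(2\alpha))$ and is
found exactly by sorting scores and scanning support sets; a closed-form
KKT solution gives bit-stable results where a numeric optimizer would
introduce tolerance noise. At $\alpha = 0$ the problem is a linear
program; the uniform split over the argmax scores is the documented
tie-break. Note that a sufficiently dominant score estimate can
legitimately receive the entire workload (e.g. estimates $(1,0,0,0)$ at
$\alpha = 0.2$ yield $\omega = (1,0,0,0)$): the penalty is quadratic,
not a hard cap.

Policies differ only in their score estimates: uniform; mean oracle
(full-series means, the scaling baseline); naive / observed mean / least
squares / ARMA extrapolation; the dynamics-model policy (elastic-net
models trained per task on a separate training split's score table); and
its outlier-controlled variant, which clips estimates into
$[(1-\epsilon)\,\overline{s}_k, (1+\epsilon)\,\overline{s}_k]$ around
each team's observed mean with $\epsilon = 0.3$ --- the allocation
step is non-robust to outlier predictions, and the clip bounds their
influence. The observed mean divides by the number of observed tasks
$t - 1$. Insufficient history falls back to the observed-mean policy,
which at task 1 falls back to uniform. Evaluation repeats random
75%/25% train/managed splits (default 100), runs each policy on the
managed teams, and reports cumulative payoffs relative to the mean
oracle --- the ratio is formed per split and then averaged. A
clairvoyant allocation (true scores as estimates) maximizes the payoff
task-wise and serves as an upper bound in the tests.

## The synthetic study generator

The generator exists so that every stage is testable without the
original study data, and its defaults are fixed at the study conditions
the analyses assume: 68 four-member teams, 15 tasks, hour-long chat
sessions, true response window $[1, 17]$ s. Scores follow
$s_i(t) = \mathrm{clip}(q_i + \mathrm{slope}_i (t-1) + \varepsilon,
0, 1)$ with latent quality $q_i \sim U(0.25, 0.85)$, noise sd 0.1, and a
slope negatively coupled to quality
($\mathrm{slope}_i = 0.8\,(0.6 - q_i)/14$), reproducing the
qualitative pattern that strong teams start strong and stay consistent
while weak teams start low and improve. Chat logs superimpose a Poisson
base process (default 0.04 messages/s, a realistic pace for an engaged
four-person text chat) with planted replies: after a message by $i$,
each $j \ne i$ replies with probability $\mathrm{reply\_prob} \cdot
A_{ij}$ at a lag uniform in the true window, at most once per
(antecedent, member) pair so the planted relation stays well-defined,
and replies do not recurse. Baseline features are drawn from Gaussian
latents at target correlations with quality (social perceptiveness 0.4,
proportion female 0.35, communication amount 0.3, communication
distribution $-0.3$, agreeableness $-0.2$) and mapped to natural scales
(probit for proportions, log-normal for communication volumes).

Annotation generation labels planted pairs as responses and other
cross-sender pairs within a 40 s horizon as non-responses, flipping each
label with a configurable noise probability. By default the *ambiguous*
negatives --- non-planted pairs whose lag falls inside the true window,
indistinguishable from true replies by timing alone --- are excluded
from the candidate set; this makes noise-free calibration recover the
planted window exactly with $F_2 = 1$, which is the property the
calibration tests need. `include_ambiguous = TRUE` restores the fully
realistic candidate set, under which even the true window scores
$F_2 < 1$.

The planted-affinity recovery experiment
(`affinity_recovery_experiment()`) pools the networks of 60 sparse
sessions (0.01 messages/s, reply scale 0.25) of one team whose planted
affinities are a permutation of twelve evenly spaced values, and reports
the Spearman correlation between planted and recovered edge weights.
The sparse pooled regime is chosen for identifiability: coincidental
same-window message pairs carry no affinity signal and scale with the
square of the message rate, while planted replies scale linearly, so a
low base rate observed over many sessions cleanly exposes the planted
ordering (the correlation exceeds 0.8 across seeds). A single dense
one-hour session recovers the ordering only noisily --- a caution that
applies equally to real single-session chat data.

What the generator does *not* emulate: natural-language content (texts
are placeholder tokens, so content-based features beyond counts are
meaningless on synthetic logs), bursty conversation dynamics
(threading, topic shifts), non-stationary message rates, and
face-to-face communication. Passing tests on synthetic data therefore
demonstrate correctness of the pipeline's computations and
identifiability under the generator's assumptions, not predictive
validity on real teams.

## Problem sizes and numerical choices in the checks

The shipped verification suite uses: 200 random allocation instances
($n \le 4$, grid resolution $10^{-3}$, payoff agreement within
$10^{-5}$); 100 random logs of up to 100 messages for brute-force
weight agreement at $10^{-12}$; 1000 random p-vectors ($n \le 20$) for
the BH step-up; spectral closed forms ($K_n$, $P_4$) at $10^{-9}$; 50
planted-signal datasets ($n = 68$, $p = 30$, 3 informative features)
for the model-selection recovery rate; and 100 random 75/25 splits of a
68-team synthetic table for the policy harness, with the
dynamics-model policy evaluated at 5 splits on a 25-point penalty grid
since it retrains 12 models per split. Coordinate descent runs at most
250 sweeps at relative tolerance $10^{-9}$ before the exact active-set
polish; the eigen-solver tolerance for "positive" eigenvalues is
$10^{-9}$; simplex membership is enforced at $10^{-9}$.

## Known limitations

Sessions are modeled as a single homogeneous process; the pipeline
builds one network per team per session, not sliding-window or per-task
networks. The reciprocity estimator is the pairwise min/max ratio
(a correlation-style estimator is a documented alternative). Elastic-net
inference (coefficient uncertainty) is out of scope, as are non-linear
regressors and content-based response attribution. The published
RMSE table of the original study's deterministic forecasting baselines
can only be reproduced from that study's deposited score table, which
is not redistributed here; the corresponding check states this
explicitly rather than substituting synthetic numbers.
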