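# remfear

Simulation of context fear conditioning and its systems consolidation —
how fear learned about a recently encoded place (a hippocampal memory)
becomes remote (a cortical memory), and what that does to generalization,
hippocampus-dependence, and the "reminder" effect.

The package is for computational neuroscientists and behavioral
researchers who want a runnable, testable implementation of a Bayesian
account of context fear: every published-style protocol (immediate shock
deficit, pre-exposure effect, hyper-generalization of remote fear and the
conditions that abolish it, Stage II competition, reminder-driven return
of specificity) is a scripted experiment over a synthetic context world.

## The model in brief

A context is a set of `N_atr = 100` attributes (20 categorical, shared by
all contexts of a category; 80 particular) from a universe of
`N_ctx = 1000`. The agent samples one attribute per computational
interval and scores every candidate representation by the Bayesian weight
of evidence

```
B = log10 [ P(Z_com | same context) / P(Z_com | random place) ]
```

where both likelihoods are hypergeometric: `Z_cur` draws without
replacement, `Z_rec` recalled attributes, `Z_com` matches; the null draws
from the full attribute universe. Thresholds on `B` drive everything:
new-representation creation (`B < B_new = -5` with a margin `delta = 5`
over the runner-up), conditionability (`Cnd = linsig(B, 2, 12)`), fear
expression (`fear = A_F * linsig(B, 0, 4)`), and end-of-session updating
(`B > B_add = 15`).

Hippocampal representations are sparse top-`K` DG/CA3 codes (`K = 60` of
`N_dg = 100000`, strong pattern separation). Consolidation (Stage I → II
→ III) builds a localist cortical representation that gains all known
attributes of the context's identified category but keeps only a capped
random subset of the rest (`ceiling = kappa + (1-kappa) (Z_rec/N_atr)^
epsilon`), transfers the conditioned amygdala weight, and erases the
hippocampal trace — the CA3 links to the cortical cell survive and carry
cross-stage generalization. Remote–remote generalization uses the
similarity `S = gamma * O_ptc + (1-gamma) * O_cat` through a tabulated
overlap function `G`.

## Worked example

The hyper-generalization experiment conditions context A (shock at
interval 75 of a 76-interval session), then tests fear in A and in an
unfamiliar same-category context B (60% particular overlap), recent
(Stage I) versus remote (Stage III), intact versus
hippocampus-inactivated:

```r
library(remfear)
r <- run_experiment("hyper_generalization", fear_params(), seed = 1)
print(r$arms[, c("arm", "mean_fear", "rep_created_at")], digits = 2)
#>              arm mean_fear rep_created_at
#> 1       recent-A      0.97             NA
#> 2       remote-A      0.94             NA
#> 3 recent-A-inact      0.00             NA
#> 4 remote-A-inact      0.94             NA
#> 5       recent-B      0.52             70
#> 6       remote-B      0.79             86
#> 7 recent-B-inact      0.00             NA
#> 8 remote-B-inact      0.78             NA
cat("decline onset in recent B test:", r$events$recent_B_decline_onset, "\n")
#> decline onset in recent B test: 47
```

Reading the numbers: fear of the conditioned context is near maximal at
both stages (0.97 / 0.94) and survives hippocampal inactivation only when
remote (rows 3–4: the recent memory is hippocampal, the remote one is
not). Generalization to the unfamiliar similar context B is moderate when
recent (0.52) — the agent "realizes" it is not in A once the evidence for
A starts declining at interval 47, and creates an unfeared representation
of B at interval 70 — but near the fear of A itself when remote (0.79,
with B's representation created only at interval 86): the remote
representation, rich in shared categorical attributes and poor in
distinguishing particulars, is hard to reject. That is
hyper-generalization.

Other experiments: `list_experiments()` returns the nine protocols,
including `reminder` (a 60-interval re-exposure to A restores specificity
and hippocampus-dependence) and `stage2_similarity` (the hippocampal
version wins in similar test contexts, the cortical in dissimilar ones).
A thin CLI wraps the same calls:

```sh
Rscript inst/cli/remfear.R run reminder --seed 1 --out results/reminder
```

writing `summary.json` and per-session `trace_*.csv` files. Parameters
can be overridden in code (`fear_params(kappa = 0.4)`) or via a YAML file
(`--config`, keys named as in `fear_params()`).

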