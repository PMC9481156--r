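# fatecoord

Inference of cell-fate coordination rules from spatiotemporal cell graphs.

In homeostatic epithelia (the epidermal basal layer is the motivating
system) cell divisions and delaminations balance on average, and a central
question is whether individual fate decisions are *coordinated between
neighbors* — does a delamination trigger a nearby division, or the
reverse? `fatecoord` addresses this for anyone with cell-tracking tables
(per frame: cell id, parent id, fate, per-cell features) and cell-contact
networks: it assembles them into spatiotemporal graphs, trains
message-passing neural models to predict each cell's next fate
(NB = no behavior, Del = delaminate, Div = divide), and extracts the
learned rules with integrated-gradients attribution.

## The model

Cells are nodes over frames; contact edges connect cells within a frame,
lineage edges connect frames (continuations and division forks). For a
window of *N*<sub>t</sub> frames, node states *x*<sub>i,α</sub> ∈ ℝ⁶
(area, G1 reporter, next-frame-behavior one-hot, a deliberately
uninformative uniform-random feature) are updated by three synchronous
message-passing stages, each a pair of learned MLPs:

* backward temporal: A<sub>(i,α)⇐(i+1,β)</sub> = Φ<sup>B,edge</sup>(a<sub>i,α</sub>, a<sub>i+1,β</sub>), summed over the daughter set D(i,α), node update by Φ<sup>B,node</sup>;
* spatial: H<sub>(i,α)⇐(i,β)</sub> = φ<sup>edge</sup>(b<sub>i,α</sub>, b<sub>i,β</sub>), aggregated over contact neighbors N(i,α) by sum or mean, node update by φ<sup>node</sup>, repeated N<sub>s</sub> times;
* forward temporal: one message per parent edge via Φ<sup>F,edge</sup>, node update by Φ<sup>F,node</sup>;

followed by a decoder ψ<sup>dec</sup> giving softmax fate scores for every
final-frame cell. Variants: bidirectional (all stages), unidirectional (no
backward stage), **cell-external** (the target's own ancestor-chain
features are nulled, so predictions can use only the surroundings), and
contact-free. Training minimizes a class-weighted softmax cross-entropy
interleaved with a neutral-baseline MSE loss that pins the all-zero "null
graph" at scores (⅓, ⅓, ⅓); the null graph is the integrated-gradients
baseline, and pooled attributions are judged against a significance band
spanned by the attributions of the random feature.

An agent-based simulator of a homeostatic cell layer (overdamped repulsive
particles, stochastic paired division/delamination rules, Voronoi contact
networks, central-crop censoring) provides ground-truth data with
implanted coordination rules — delamination-induced division,
division-induced delamination, or a mixture — and a neighbor fate
net-imbalance statistic offers a model-free cross-check.

## Worked example

Simulate the delamination-induced-division tissue at study scale
(~500 cells, ~210 per cropped frame), train two replicate cell-external
models, and look for the implanted rule. About 10 minutes on one CPU; the
same computation at the full defaults (2000 epochs, six replicates) runs
via `inst/cli/fatecoord all`.

```r
library(fatecoord)
set.seed(1)
lam <- calibrate_rate(sim_config("del_induced_div", seed = 101), target = 0.07,
                      pilot_burnin = 120, pilot_production = 120)
cat(sprintf("calibrated lambda: %.5f per cell per hour\n", as.numeric(lam)))
train <- simulate_dataset(sim_config("del_induced_div", seed = 301,
                                     lambda_rate = as.numeric(lam)))
test  <- simulate_dataset(sim_config("del_induced_div", seed = 401,
                                     production_steps = 200,
                                     lambda_rate = as.numeric(lam)))
fc  <- feature_config(c("nfb", "random"))
wtr <- extract_windows(train$graph, 4)
wte <- extract_windows(test$graph, 4)
fit <- replicate_train(wtr, wte,
                       model_config("cell_external", "mean"),
                       train_config(epochs = 700, eval_every = 10, seed = 211),
                       fc, n_replicates = 2)
print(round(fit$summary$auc_mean, 3))
tabs <- lapply(fit$fits, function(f)
  attribution_table(f$model, wte, fc, M = 16, max_targets_per_window = 50))
agg  <- aggregate_attributions(tabs)
band <- random_baseline_band(agg)
print(agg[feature == "nfb_del" & rel == -2 & role == "neighbor",
          .(feature, rel, role, NB = round(NB, 3), Del = round(Del, 3), Div = round(Div, 3))])
print(round(band, 4))
```

Output from this exact script:

```
calibrated lambda: 0.00386 per cell per hour
   NB   Del   Div
0.617 0.555 0.818
   feature   rel     role     NB    Del   Div
1: nfb_del    -2 neighbor -0.154 -0.155 0.309
     lo      hi
-0.0048  0.0093
```

Reading: the model predicts divisions far above chance (AUC 0.82) while
delaminations stay near chance (0.56) — in this setup delaminations are
spontaneous and divisions are induced, so only divisions are predictable
from the surroundings. The pooled attribution of a *neighbor's* NFB = Del
flag two frames back toward the target dividing (+0.309) lies far above
the random-feature significance band [−0.005, 0.009], and its attribution
toward the target delaminating is negative (−0.155, below the band): the
model has localized the implanted rule — a delaminating neighbor, about
48 h (two frames) earlier, makes a division likely now.

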