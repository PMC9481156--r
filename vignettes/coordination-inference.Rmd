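---
title: "Inferring cell-fate coordination from spatiotemporal cell graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-fate coordination from spatiotemporal cell graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In a homeostatic epithelium such as the epidermal basal layer, cell
divisions and delaminations (departures to the suprabasal layer) must
balance. Whether individual fate decisions are coordinated between
neighboring cells — a delamination triggering a nearby division, or the
reverse — is hard to read off tracking data directly, because the events
are sparse, stochastic, and embedded in a changing contact network.
`fatecoord` treats this as a supervised learning problem on
*spatiotemporal cell graphs*: if a model that sees only a cell's recent
neighborhood can predict the cell's next fate, the neighborhood carries
fate information, and an attribution method can localize which feature of
which neighbor at which time lag carries it.

# Spatiotemporal graphs

A tracked data set becomes a graph with one node per cell per frame
(`build_graph()`). Nodes in the same frame are connected by contact edges
(from Voronoi tessellation for simulated data, or from shared segmentation
boundaries via `contacts_from_labels()`); nodes in consecutive frames are
connected by lineage edges — a continuation, or a fork into two daughters
at a division. Fates are derived from the lineage structure itself: two
children mean division (`Div`), one means persistence (`NB`), a track that
ends before the last frame means delamination (`Del`), and anything that
cannot be followed (field-of-view or crop boundaries, the final frame) is
censored rather than being turned into a fabricated event.

Each node carries a fixed-length feature vector
`[area, g1, nfb_nb, nfb_del, nfb_div, random]`:

* `area` — cell area (Voronoi cell area in simulations), normalized by the
  global maximum over training *and* test data so the largest value is 1;
* `g1` — a cell-cycle reporter signal (zero in simulations), normalized
  the same way;
* NFB, the *next-frame behavior* — the cell's own fate one-hot
  (`NB` = (1,0,0), `Del` = (0,1,0), `Div` = (0,0,1)), nulled in the final
  frame of each prediction window because it is what the model must
  predict there;
* `random` — one uniform U(0,1) draw per node, fixed at graph-construction
  time. It carries no fate information by construction and anchors the
  attribution significance band.

Deactivating a feature (`feature_config()`) zeroes it everywhere but keeps
the vector length at 6, so model shapes are identical across feature
ablations.

Prediction operates on windows of `Nt` consecutive frames (default 4),
re-indexed `t = -(Nt-1) .. 0`; the prediction targets are the non-censored
cells of the final frame. The receptive field of one target is its
ancestor chain, the `Ns`-step contact neighborhoods of every ancestor, and
the within-window descendants of those neighbors
(`extract_target_subgraph()`). We use the full descendant closure rather
than only first-generation daughters so that the subgraph is exactly the
set of nodes whose features can influence the prediction.

# The model family

One forward pass composes up to three synchronous message-passing stages,
each built from a pair of multilayer perceptrons (an edge model and a node
model; `N_layer` = 1 hidden block of width `N_node` = 50 with ReLU and
dropout `p` = 0.1 by default):

1. **Backward temporal** (`Nt - 1` iterations, future to past): every
   lineage edge computes a message from the states of its two endpoint
   cells; a cell sums the messages from its daughter set `D` (its
   continuation, or both daughters); tracks that end contribute nothing.
   Final-frame states are never updated — they are the information source.
2. **Spatial** (`Ns` iterations, default 1): every directed contact edge
   computes a message; a cell aggregates incoming messages by sum or mean
   (mean over an empty neighbor set is the zero vector) and updates.
3. **Forward temporal** (`Nt - 1` iterations, past to future): each cell
   receives one message along its parent edge (zero if it entered the
   field of view without a recorded parent) and updates.

A decoder maps each target's final-frame state to three fate logits;
softmax gives the fate scores. All edge models take
`concat(state[receiver], state[sender])`.

Variants (`model_config()`): `bidirectional` runs all three stages;
`unidirectional` skips the backward stage (states start from the raw
features); `cell_external` additionally nulls the target's own ancestor
chain at spatial initialization, so the prediction can use *only* the
surroundings — this is the variant that isolates neighbor-driven
coordination; `no_spatial` drops the contact stage.

Two conventions were genuinely underdetermined and are worth recording.
First, a literal reading of the update rules would freeze the *final*
frame in the forward temporal stage as well; that would make the decoded
state independent of the forward models entirely, so the package freezes
the *first* frame (which has no parent) by default, and exposes the
literal behavior behind `forward_freeze = "final"` (a test documents the
degeneracy). Second, the printed argument indices of the forward edge
model do not name the edge's endpoints; we pass the two endpoint states in
receiver-sender order, mirroring the backward edge model. Since the edge
MLP is learned, the order is a labeling choice, not a modeling one.

## Exact fast paths

Training the cell-external variant naively requires one evaluation per
target subgraph. At `Ns = 1` this is unnecessary: an ancestor chain has
one node per frame and contact edges live within frames, so no chain node
neighbors another, and the chain's post-spatial states are
*target-independent* given the zero receiver state. One shared spatial
sweep plus a batch of independent per-target chains reproduces the
per-subgraph evaluation exactly; moreover the spatial edge message then
depends only on the sender, so the edge MLP runs once per node instead of
once per edge. Both identities are asserted against the generic
per-subgraph path in the test suite (equality to floating-point
round-off). Null graphs (all features zero) collapse analogously to the
distinct chain degree signatures. Under dropout the collapsed updates are
unbiased: each collapsed row has the same mask distribution as any of the
rows it represents, so expectations are unchanged; only the sampling
correlation differs.

All gradients (for Adam and for attribution) are reverse-mode sweeps
written against these exact forward paths and verified against central
finite differences.

# Training

Fates are imbalanced (roughly 86% `NB` at a 7% per-fate event rate), so
the loss is the class-weighted softmax cross-entropy with weights equal to
the inverse fate proportions of the training targets. Each epoch iterates
the training windows in a fixed order; per window, one Adam step
(`lr = 1e-4`) on the cross-entropy of the window's targets is followed by
one Adam step on the neutral-baseline loss: the mean squared deviation of
the *null graph's* softmax scores from 1/3. The null graph — identical
topology, all features zero — is the attribution baseline, and the
auxiliary loss makes that baseline neutral. Test metrics (one-vs-rest AUC
per fate, macro-F1, confusion matrix) are recorded on an evaluation
cadence and the parameters with the best test macro-F1 are kept. Model
selection on the test set is a known optimistic-bias choice retained
deliberately for comparability; a separate validation split can be
emulated by passing different window lists.

A practical note on optimization: with these learning-rate and
initialization scales the training loss sits on a plateau (near-uniform
outputs, held there by the baseline loss) for the first few thousand Adam
updates before dropping. This is why the default epoch budget is large
(2000); scaled-down runs need enough epochs that
`epochs x windows` comfortably exceeds the plateau, and the package's own
heavy tests use 700 epochs over ~11 windows (two replicate models), which
was comfortably past the escape point in every run we observed.

# Attribution

For a target subgraph with features `X` and the null graph `X' = 0` as
baseline, the integrated gradient of feature `k` toward fate `f` is
`(X_k - X'_k)` times the path integral of the score gradient along the
straight line from `X'` to `X`, discretized by a midpoint rule with `M`
steps (default 50; completeness — the attributions summing to the score
difference — is verified at `M = 200`). Because the three scores sum to
one, the three attributions of any feature sum to zero, exactly, at every
pooling level.

Per-feature attributions are pooled into (feature type, relative frame,
role) categories, role being the target's own lineage versus the
surrounding cells; descendants of neighbors pool with neighbors at their
own frame. NFB categories average only over the cells carrying that NFB
value (the feature is zero elsewhere, and those zeros carry exactly zero
attribution). Category means are averaged over target subgraphs, then
over replicate models, with the standard error across models. The
*random-feature band* spans from the minimum of (mean - SE) to the
maximum of (mean + SE) over all pooled random-feature categories and
fates: a pooled attribution inside the band is indistinguishable from that
of a feature known to carry no information. On uncoordinated control data
(induction disabled in the simulator) essentially all pooled rows fall
inside the band, which the test suite checks.

# The homeostasis simulator

Because curated epidermal tracking data are not redistributable, the
package ships the agent-based data source used to validate rule recovery
end to end. Cells are points in a unit periodic box under overdamped,
noiseless dynamics with a short-range harmonic repulsion
(`u = K/2 (|r| - l)^2` for `|r| < l`; `K` = 9/h, `l` = 0.125 box units,
`dt` = 1.2 h). Division duplicates a particle at offset `d` = 0.001 L;
delamination removes one instantly. Uncommitted cells commit spontaneously
at rate `lambda` per hour with a remaining lifetime U(32.4, 39.6) h; when
an event fires, one uncommitted cell among the six nearest (periodic
Euclidean metric, ties by id) is committed to the *complementary* fate
with lifetime U(44.4, 51.6) h. The three setups start from 612 / 412 / 512
cells so that the steady-state population is ~500: delamination-induced
division, division-induced delamination, and an equal mixture (spontaneous
commitments split evenly; note that in the mixture every induced event
itself induces, so the commitment rate that matches a given event rate is
well below half the one-directional value — this is why `lambda` is
calibrated, not transcribed). `calibrate_rate()` tunes `lambda` on short
pilot runs sharing one pre-relaxed configuration until ~7% of cells
undergo each fate per 24 h frame, matching the epidermal data; a
committed-pool balance argument (`lambda ~ f / (24 - (T_s + T_i) f)`)
seeds the search, which typically converges in one or two pilots.

**Numerical integration.** At these parameters a literal explicit Euler
step of length `dt` is far outside the stability region of the dynamics:
the pair relaxation rate is `2K` and the jammed steady state (~25
overlapping contacts per cell) has per-cell stiffness of order
`K x contacts`, so `K dt = 10.8` produces divergent oscillations rather
than the intended rapid relaxation to a dispersed state. `run_sim()`
therefore advances the same flow with explicit Euler *substeps* whose
per-particle step length respects the local stability bound
(`0.4 / (K (1 + contacts))`), with an early exit at force balance and a
skin-margin neighbor pair list for speed. `dt` is unchanged as the event
and sampling clock. The single literal step remains available as
`euler_step()`. Energy monotonicity of the substepped flow is asserted in
the tests.

After 100 mechanics-only relaxation steps, 300 burn-in and 300 production
steps, frames are sampled every 20 steps (24 h) and cropped to the central
0.65 L square (~210 cells per frame). Contacts and cell areas come from an
exact periodic Voronoi tessellation (per-site half-plane clipping with a
distance-sorted candidate stream and the standard
twice-max-vertex-distance stopping bound; validated against a brute-force
empty-circumcircle oracle). Export censors everything that cannot be
tracked honestly: crop-boundary crossers, divisions with a daughter
outside the crop, and the final frame.

**Timing of the implanted signal.** The induced lifetime averages 48 h =
two sampled frames, so in the delamination-induced-division setup a
neighbor's `NFB = Del` flag sits predominantly at relative frame `t = -2`
from the induced division (>90% of events; the within-frame jitter moves
a few percent to `t = -1` or `-3`). Rule-recovery checks therefore look at
`t = -2`. The recovered pattern is: division predictable
(AUC well above 0.5), delamination at chance, a strongly positive pooled
attribution of neighbor `NFB = Del` at `t = -2` toward `Div` and a
negative one toward `Del`; mirrored in the reversed setup; both signals at
reduced predictability in the mixture.

## What the generator does and does not emulate

It reproduces the statistical skeleton the method needs: homeostatic
population balance, realistic per-frame event fractions, contact-graph
churn from divisions and delaminations, paired fate events with a delay,
and boundary censoring. It does not emulate cell shape or size regulation
(areas are Voronoi areas of point cells), cell-cycle reporters (`g1` is
zero; the corresponding feature stays inactive), mechanics-driven fate
feedback, measurement noise in segmentation or tracking, or
three-dimensional tissue structure. Passing the recovery tests therefore
shows the *inference machinery* is sound — it does not by itself validate
biological conclusions drawn from real images.

# Desk-scale sizes used by the tests

The test suite regenerates everything from code. The study-condition runs
use the full protocol above; held-out test runs use a 180-step production
phase (9 frames). Training for the recovery checks uses two replicate
models, 700 epochs, evaluation every 10 epochs; attribution uses M = 16
path steps and up to 50 target subgraphs per window. The defaults exposed
to users remain the full-scale values (2000 epochs, six replicates,
M = 50).

# Known limitations

* The message-passing engine is dense-matrix R with compiled MLP kernels;
  it is sized for hundreds of cells per frame, not tens of thousands.
* Calibration targets the per-fate event fraction only; it does not
  enforce a target population trajectory beyond the initial-count choice.
* The imbalance statistic implements the cumulative six-neighbor
  count, with an optional population-rate background subtraction; more
  elaborate background corrections from the tracking literature are out
  of scope.
* With two replicate models the attribution standard errors (and hence
  the random band) are coarse; six replicates are recommended when time
  permits.
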