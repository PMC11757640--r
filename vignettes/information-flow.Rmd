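---
title: "Measuring information flow and weight importance in small recurrent networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring information flow and weight importance in small recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnnflow)
```

## The question

Two very different procedures can train the same recurrent network to
the same performance: gradient-based backpropagation, which nudges
every weight simultaneously along the loss gradient, and
neuroevolution, which mutates a few weights at a time in a population
and lets selection keep what works. `rnnflow` asks whether networks
trained these two ways *process* information differently even when
they *perform* identically. The package trains small Elman networks on
a categorical perception task by both methods and then measures two
complementary per-weight-group quantities:

* **set transfer entropy** -- how much the joint state of a set of
  recurrent nodes tells us about a target node's next state, beyond
  what the target's own state already tells us;
* **perturbation importance** -- how much fitness is lost when the
  recurrent weights from that set onto the target are corrupted by
  one-sided uniform noise during the computation.

## The task

The stimulus space is fully enumerable. A block appears on a 4-pixel
retina; it is small (2 pixels) or large (3), bright (+1) or dark (-1),
and flush left or right -- 8 configurations, hence 8 classes
(`block_configs()`). Each episode lasts 4 timesteps and shows the
block twice on consecutive timesteps, either early (t = 0, 1),
intermediate (t = 1, 2) or late (t = 2, 3); the remaining rows are
blank. The late placement forces the network to *retain* category
information rather than react to it, and the variable onset prevents
rhythmic synchronization. `acp_dataset()` deterministically enumerates
all 8 x 3 = 24 episodes; each label occurs exactly three times. There
is no sampling noise anywhere in the data: the generator *is* the
task, and it emulates nothing beyond itself. What passing tests cannot
tell you is how any of the measures behave on noisy, high-dimensional
or non-stationary data; every conclusion is conditional on this small,
clean, fully balanced stimulus set.

Two conventions are fixed so that results are reproducible across
implementations: left blocks start at pixel 0 and right blocks end at
pixel 3 (the only alignment consistent with "left/right of a 4-wide
field"); and labels follow the bijection `4*size + 2*shade + side`.

## The network and its fitness

The architecture is a 4-16-8 Elman network: 4 sensors, 16 recurrent
tanh nodes whose activations feed back through the 16 x 16 matrix `M`
at the next timestep, and 8 tanh output nodes. Recurrent and output
nodes carry biases; all 472 scalars are trainable. The recurrent state
starts at zero for every episode (the natural choice for episodic
presentation) and the class is read out at t = 3 by the argmax of the
output layer, ties toward the lower index.

Performance on the 24-episode batch is summarized by the squared
error `E = sum((O - A)^2)` between the matrix `O` of final outputs and
the target matrix `A`, the normalized fitness `w = 1 - E/(n m)` with
`n = 24`, `m = 8`, the number of correct classifications `a`, and the
selection fitness

```
W = 1.5^(w * a)
```

which is strictly positive, so fitness-proportional selection is
always well defined.

### Target coding: a calibrated choice

The target matrix's off-class value is not dictated by the
architecture: both `A[i, class] = 1, 0 elsewhere` (one-hot) and
`+1/-1` coding are compatible with tanh outputs. The two behave very
differently under the exponential selection fitness. With `+/-1`
coding a random network has `w` near 0, so `W = 1.5^(w a)` is nearly
flat in `a` and selection has almost no gradient until the squared
error has been substantially reduced; in calibration runs at the
standard hyperparameters only a minority of GA populations reached
perfect classification within several thousand generations. With
one-hot coding a random network already sits at `w ~ 0.9`, accuracy
improvements are rewarded from the first generation, and every
calibration population reached 24/24 within roughly 700 generations --
the training behaviour the method is designed to exhibit.
`acp_dataset(target_coding = "onehot")` is therefore the default;
`"pm1"` remains available for sensitivity analyses.

## The two trainers

**Genetic algorithm** (`evolve()`): a population of 100 networks
(Kaiming-initialized; Xavier selectable -- both fan-in-scaled
Gaussians), scored with `W`; the next generation consists of 100
roulette-wheel draws, each passed through the mutation operator: every
scalar independently gains, with probability 0.01, a
`Normal(0, var = 0.1)` offset (standard deviation `sqrt(0.1)`;
"variance 0.1" is read literally). No elitism, no recombination. A run
stops at the first generation containing a perfect classifier or at
the generation cap.

**Backpropagation through time** (`train_bp()`): full-batch
optimization of the mean squared error of the final-timestep outputs,
`L = mean((O - A)^2)`, with exact gradients through all four timesteps
(`bptt_gradients()`, verified against central finite differences).
One epoch = one full-batch update. The default optimizer is Adam at
its conventional 0.001 rate -- the optimizer the source analysis's own
discussion names as the one actually compared, even though its methods
section mentions plain SGD; both remain selectable. For plain gradient
descent the learning rate is not a published quantity; it was
calibrated once, on pilot seeds disjoint from any seeds used
elsewhere, to the smallest round value at which all pilot runs reached
24/24 comfortably within a 5000-epoch budget: 0.05 (0.01 left a large
fraction of runs unconverged at 5000; 0.1 also works but sits closer
to instability).

Both trainers consume a single integer seed and are bit-reproducible
given it.

## Transfer entropy between node sets

After training, `record_traces()` runs the 24 episodes noise-free and
records the 96 recurrent state vectors and the 72 within-episode
transitions (3 per episode). Transitions never cross episode
boundaries, and the pre-episode zero state is not a sample -- crossing
boundaries would manufacture dynamics the network never produced.
Whether the zero state should contribute a fourth transition per
episode is a convention the source material leaves open; excluding it
is this package's documented choice.

Each node is binarized at its median over all 96 pooled states
(`binarize()`): strictly above the median maps to 1, at-or-below to 0.
For continuous activations this makes each node's marginal entropy
nearly maximal; exact ties (which do occur here, because episodes that
have not yet seen the stimulus produce *identical* states) shift the
split away from 48/48, which is a property of the task, not an error.
A constant node binarizes to all zeros and is flagged.

For a source set S (1-15 nodes) and a single target node j not in S,
the transfer entropy is the plug-in estimate, in bits, of

```
TE(S -> j) = sum p(x'_j, x_j, x_S) log2 [ p(x'_j | x_j, x_S) / p(x'_j | x_j) ]
```

over the 72 transition samples, with Markovian history (one step) and
the convention `0 log 0 = 0`. The target set is restricted to a single
node throughout. No bias correction is applied -- the estimator is the
empirical one, and its small-sample bias is characterized by the test
suite (on independent uniform 72-sample traces the mean spurious TE at
|S| = 1 stays well under 0.15 bits) rather than hidden. Because the
plug-in estimate of conditional mutual information can only grow when
the conditioning source set is refined, TE is monotone in S on any
fixed trace; per-node comparisons across sizes therefore use the
normalization `TE / |S|`.

Subset sampling (`sample_pairs()`) draws S uniformly without
replacement and the target uniformly from the remainder; duplicates
across draws are allowed, matching a simple sub-sampling protocol.

## Perturbation importance

The importance of the weight group connecting S to j is measured by
corrupting exactly those entries of `M` (row j, columns S; `M[i, j]`
is the weight from node j onto node i) with one-sided uniform noise
`U[0, r]`, redrawn at *every* update of every episode, and recording
the fitness `w` relative to the unperturbed `w0`:

```
I = 1 - mean_over_levels_and_repeats( w_perturbed / w0 )
```

The noise bound sweeps 21 levels, 0 to 4.0 in steps of 0.2, with 10
repeated evaluations per level by default (the repeat count is not a
published quantity; 10 keeps the per-level standard error of a
perfect network's relative fitness in the third decimal). The scalar
averages uniformly over levels and repeats -- the aggregation
weighting is a documented convention of this package. `r = 0` is exact
(relative performance 1), not sampled. "The same noise" for a group is
interpreted as the same noise *law* with independent draws per weight
per update, matching the single-weight procedure applied in parallel;
a shared-draw mode (`sharing = "shared"`) is provided for sensitivity
analysis. Only `M` is ever perturbed -- input and output weights are
out of scope.

One subtlety matters for comparing the methods: a GA-trained network
stops the moment it classifies 24/24, typically with `w` far below 1,
while a BP run driven by the MSE loss keeps `w` close to 1 at the
stopping point. Using the *relative* fitness `w/w0` removes this
baseline difference.

## The experiment layer

`run_replicates()` trains independent replicates (seeds `base_seed`,
`base_seed + 1`, ...); only replicates that reach 24/24 enter
analysis, and failures are archived but flagged.
`te_importance_scan()` draws, per network and set size, one batch of
pairs and feeds the *same* draws to both the TE and the importance
computation, so every scatter point is a genuine pairing.
`correlation_by_size()` uses Spearman rank correlation (neither axis
is plausibly normal); raw p-values are reported as in the source
analysis, with a Bonferroni column added for transparency.
`weight_distribution_report()` pools recurrent matrices per method and
compares them with a two-sample Kolmogorov-Smirnov test; rank-sorted
per-network weight curves complement the pooled histogram, which is
otherwise pushed toward universality by aggregation.

### Problem sizes

Two scales are used. The desk scale -- 10 replicates per method, 30
subsets per size, 3-5 noise repeats -- runs in seconds to a couple of
minutes and is what the test suite exercises; at this scale the
per-size means carry visible sampling error, and a statistic as
fragile as the *argmax* of mean TE/|S| (sizes 2 and 3 differ by only
a few percent) can flip between adjacent sizes across replicate
archives, which is why peak locations are always reported as a
majority vote over independent replications. The full analysis scale
-- 50 replicates per method, 100 subsets per size -- is what the
bundled reproduction script uses; at that scale the peak locations
are stable across independent archives. The scans report standard
errors so that runs at the two scales are comparable. Randomness
flows from a single master seed via fixed per-stage derived streams.

## Numerical and degenerate-input choices

* Median ties binarize to 0 (strictly-above rule).
* Zero-probability table cells contribute nothing to TE; the plug-in
  value is clamped at 0 against floating-point cancellation.
* `transfer_entropy()` rejects tables whose probabilities do not sum
  to 1 within 1e-9.
* Importance is undefined when the unperturbed fitness `w0` is not
  positive; this raises an explicit error rather than returning NaN.
* `train_bp()` reports divergence (non-finite loss) as an error naming
  the learning rate as the remedy.
* Argmax ties in classification go to the lowest index, in both the R
  and the compiled evaluation paths.

## Limitations

* All results concern one small architecture on one fully enumerated
  task; nothing here licenses claims about large networks or noisy
  data.
* The plug-in TE estimator is positively biased at 72 samples and the
  bias grows with |S|; comparisons are therefore made *between
  methods at equal |S|*, never across estimators or sample sizes.
* The exact weight-distribution KS statistic and the scatter geometry
  of TE against importance are replicate-dependent; the package
  reproduces the analyses, not any specific published value of them.
* Training-time comparisons between the GA (generations of 100
  evaluations each) and BP (one gradient step per epoch) are not
  wall-clock-fair and are not intended to be.
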