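---
title: "Joint Bayesian inference of homology and phylogeny for morphological characters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint Bayesian inference of homology and phylogeny for morphological characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Phylogenetic analysis of morphology starts from a character-by-taxon matrix,
which is a bundle of *primary homology statements*: conjectures, made from
comparative anatomy, that structures observed in different taxa are "the
same" character. Usually these conjectures are fixed before the analysis.
But sometimes two incompatible primary homology statements are equally
defensible — the canonical case being the upper jaw bones of arthrodire
placoderms, which can be coded either as homologues of the osteichthyan
palatal (vomer–dermopalatine) series or of the marginal (premaxilla–maxilla)
series. Choosing one coding by hand pre-judges part of the question the
analysis is meant to answer.

`dynhom` treats the choice itself as a random variable. The user supplies
one or more *homology blocks*: N alternative codings ("homology
alignments") of the same character subset, indexed by an integer homology
state $h \in \{0, \dots, N-1\}$. The MCMC samples $h$ jointly with the
time-calibrated tree and all model parameters. At any point in the chain,
the data likelihood is the tree likelihood of the *composite alignment*
built from the fixed-homology columns plus coding $h$ — a multiplexer
selects among the per-state tree likelihoods. The chain therefore spends
more time in the homology state whose coding best fits the tree, and the
posterior frequency of $h$ estimates the posterior probability of each
primary homology hypothesis. With a uniform prior over states and
everything else fixed, this posterior is the softmax of the per-state
log-likelihoods,
$P(h) = \exp(\ell_h) / \sum_j \exp(\ell_j)$,
which the package also computes analytically for fixed-tree checks.

# The model

**Substitution model.** Characters evolve under the Mk model: a k-state
symmetric continuous-time Markov chain with uniform stationary frequencies
$1/k$. Transition probabilities have the closed form
$P_{\text{same}} = 1/k + \frac{k-1}{k} e^{-kd/(k-1)}$,
$P_{\text{diff}} = 1/k - \frac{1}{k} e^{-kd/(k-1)}$
at expected substitution distance $d$. Likelihoods are computed by
Felsenstein pruning (compiled kernel, per-node rescaling against
underflow). Missing (`?`) and inapplicable (`-`) cells are distinct in the
data model but both enter the likelihood as full-uncertainty partials, and
polymorphic cells as their literal state sets. Plain Mk is the default; a
conditioning-on-variable-characters (Mkv) switch is provided as a
sensitivity knob, since morphological matrices usually omit invariant
characters.

**Rate variation: homoplasy partitioning.** Instead of gamma rate
heterogeneity, characters are partitioned by (observed state count,
homoplasy) and each partition gets its own mutation-rate multiplier
$r_p$, constrained so the character-count-weighted mean of the rates is 1
and given a normal(1, 2) prior. Homoplasy is the character's extra steps
beyond its minimum, $h_c = \text{steps} - (\text{states}-1)$, measured on
a single reference tree found by an implied-weights parsimony search
(Goloboff fit penalty $\sum_c h_c/(h_c+k)$ with concavity constant
$k = 10$). The search is a seeded heuristic: random-addition starting
trees improved by SPR to convergence, with first-found tie-breaking; on
five-taxon problems it provably attains the exhaustive optimum (tested).
Characters belonging to a homology block are scored under every coding and
assigned the *lower* homoplasy value, so partition membership (and hence
the rate) does not switch with the sampled homology state. Each distinct
homoplasy value is its own partition key by default; a binning width is
configurable.

**Tree prior.** A constant-rate fossilized birth–death process with
sampled ancestors: birth rate $\lambda$, death rate $\mu$, fossil sampling
rate $\psi$, extant sampling probability $\rho$ (0 by default for
all-fossil matrices), conditioned on the origin time. A sampled ancestor
is represented as a tip whose pendant edge has zero duration — the host
branch is bisected — and contributes a $\psi$ factor without a birth term
or extinction integral. The density reduces exactly to the constant-rate
birth–death form as $\psi \to 0$ with extant sampling (tested against the
closed form), and rescaling all times while dividing rates by the same
factor changes the log density by exactly (number of rate events) ×
log(factor) (tested).

**Priors** (the package defaults, which are the study conditions for the
Palaeozoic gnathostome analysis): $\lambda$ lognormal with real-space mean
0.14/Myr and standard deviation 0.9 in log space; $\mu$ and $\psi$
exponential with mean 0.1/Myr; mean clock rate lognormal(−5.5, 2) in log
space (a real-space mean of −5.5 is impossible for a positive rate, so the
log-space reading is forced); relaxed-clock standard deviation exponential
with mean 1; fossil-site ages uniform over their stratigraphic bounds,
with all tips of a site sharing the site's age parameter; uniform prior
over homology states. Both readings of the birth-rate "mean" (real vs log
space) are available behind `birth_mean_space`. The origin time, whose
prior the source analyses keep in their configuration files rather than
their text, is given a uniform prior on [root age, 1000 Ma] here; the
bound is configurable and the posterior is insensitive to it because the
tree density decays rapidly in the origin.

**Clock.** An uncorrelated lognormal relaxed clock: each branch carries an
i.i.d. lognormal multiplier with real-space mean 1 (log-space mean
$-\sigma^2/2$), continuous rather than discretized into categories — the
same model family with one fewer approximation. Multipliers attach to the
node below each branch and follow it through topology moves.

# The sampler

Metropolis–Hastings over (tree topology, node ages, origin, $\lambda$,
$\mu$, $\psi$, clock mean, clock sd, branch multipliers, partition rates,
site ages, homology states). The operator set is chosen for irreducibility
over sampled-ancestor tree space joined with homology space:

* scale moves on all positive scalars, with adaptive tuning toward 23.4%
  acceptance during burn-in, then frozen;
* a delta exchange on partition rates that transfers mass between two
  partitions scaled by inverse weights, conserving the weighted mean
  exactly;
* uniform node-age, root-age and origin moves; a fossil-site age redraw
  that moves all of a site's tips (and their attachment nodes, for sampled
  ancestors) together;
* Wilson–Balding subtree transplantation and narrow exchange, both
  restricted so that sampled-ancestor attachments are never created or
  destroyed as a side effect;
* a dedicated reversible-jump toggle between an ordinary fossil leaf and a
  sampled ancestor (the only move that changes the zero-length flags),
  with the Hastings ratio of the collapsed age dimension;
* a uniform homology-state flip, plus two joint operators that combine a
  tree move with a homology redraw in a single proposal, for correlated
  tree- and homology-space;
* an independence "redraw from the prior" proposal, whose Hastings ratio
  cancels the prior ratio (used mainly for prior-validation chains).

Proposals that violate a monophyly constraint are rejected through a
$-\infty$ prior rather than by constrained proposal construction; this is
simpler and leaves the stationary distribution unchanged. The initial
state is logged as sample 0, so a chain of $G$ generations sampled every
$s$ yields $G/s + 1$ samples; burn-in discards
$\lfloor \text{frac} \times n \rfloor$ samples. Under the production
settings (800 million generations, sampling every 400,000, 10% burn-in)
this is 2001 samples of which 1801 are retained — the arithmetic the
package's counting follows.

**Validation by sampling the prior.** Two prior-sampling modes are
provided. With `likelihood_off`, the chain targets the full prior
including the tree density; homology states must then be uniform by
symmetry (tested). Note that the *marginal* of, say, the birth rate under
the full prior is not its lognormal hyperprior: the tree-conditional
birth–death factor, restricted to trees with the observed number of tips,
reweights it. For exact hyperprior recovery the package therefore also
offers `tree_prior_off` (with a fixed tree), under which the birth rate is
provably lognormal and fossil-site ages uniform — this is the
configuration the prior-recovery tests use, with near-independent draws
obtained from the prior-redraw operator and generous thinning so that
Kolmogorov–Smirnov tests are valid.

**Diagnostics and summaries.** Effective sample sizes are
autocorrelation-time based (via `coda`), clamped to the number of samples
(an anti-correlated chain can otherwise report more independent draws than
exist) and flagged undefined for constant traces. The 50% majority-rule
consensus keeps clades whose frequency strictly exceeds the threshold and
annotates each with its frequency and the mean MRCA age over the trees
containing it; mean heights of nested clades are not forced monotone (the
usual caveat of mean-height annotation — the common-ancestor-height
variant is deliberately out of scope).

# Ancestral phenotypes and phenetics

At every logged sample, a full character-state vector is drawn at the
focal node (the MRCA of a constrained clade — for the motivating analysis,
the apomorphy-defined jawed-vertebrate clade). The draw is *joint across
characters* (one coherent phenotype per posterior sample) rather than a
set of per-character marginal summaries, because the downstream distance
analysis needs whole phenotypes; given the tree, characters are
conditionally independent, so each character is drawn from its conditional
distribution at the node. That conditional is obtained by re-rooting the
pruning pass at the focal node — valid because the Mk model is reversible
with uniform root frequencies — and matches brute-force enumeration
exactly (tested). Characters with no scored cell among the clade's tips
are still drawn (from the node's marginal given the rest of the tree) but
flagged, and summaries report the flagged fraction alongside per-state
posterior probabilities. Each draw records the homology state it was made
under, and downstream distances use the matching composite alignment.

Distances are Maximum Observable Rescaled Distances (MORD): the summed
per-character dissimilarity over mutually scored characters divided by the
maximum possible dissimilarity over those characters, which for fully
unordered data is the Gower coefficient with 0/1 mismatches. Polymorphic
cells count as matching when their state sets intersect (uncertainty
reading; a strict-mismatch switch is provided). Pairs with no mutually
scored characters are flagged undefined rather than imputed. Principal
coordinates are classical metric scaling of the double-centred
$-D^2/2$ with all eigenvalues (including negative ones) reported and an
optional Cailliez correction; no correction is applied by default since
the motivating analysis states none. Nearest-taxon summaries find, for
each retained ancestor draw, the minimum-MORD taxon under that draw's
homology alignment, with deterministic first-taxon tie-breaking (ties
flagged) and optional group binning. For ordination, ancestors are
subsampled by keeping every 20th retained sample (5%) after excluding
draws at non-modal homology states; because the thinning-vs-exclusion
order is ambiguous in the source description and changes the count by one,
both arithmetics are reported rather than silently chosen.

# Synthetic data and what the tests do (and do not) show

`simulate_matrix()` evolves characters forward under the Mk model on a
known dated tree (uniform root states, closed-form transition
probabilities per branch, i.i.d. missing-data masking, fully deterministic
per seed) and writes a truth record for assertions.
`make_fig2_fixture()` is a constructed didactic example: three taxon
groups A, B, C with six fixed binary characters and one two-state block of
two characters whose coding X aligns group C's structures with A and
coding Y with B. Variant 2 carries three B+C synapomorphies (strong
signal for Y); variant 1 carries one A+C synapomorphy (moderate signal for
X). Its cell values are constructed to satisfy that support pattern, and
its strength was fixed once by a power analysis (20 seeded end-to-end runs
of variant 2 at the test chain length all gave the true state posterior
probability above 0.9) before the acceptance suite was written. The
fixture's analysis settings treat all tips as extant with full extant
sampling and a clock prior centred near 0.02 substitutions per character
per unit time, appropriate to its arbitrary (non-Ma) timescale.
`synthetic_study_matrix()` emulates the *structure* of a published-scale
dataset — 107 taxa, 489 fixed plus 18 variable-homology characters across
two codings, heavy missing data — with simulated cell values, for
exercising the reader and partition machinery at realistic size; it is
synthetic and never presented as the study's data.

These generators emulate dimension, missingness and signal structure, but
not several features of real morphological data: hierarchically dependent
(inapplicable-prone) characters, correlated characters, non-random
missingness concentrated in poorly preserved taxa, or tip-date measurement
error. Passing tests therefore demonstrate the correctness of the
machinery and the recoverability of strong signals, not the field
performance of the model on any particular empirical matrix.

# Numerical choices and problem sizes

Likelihood partials are rescaled per node with accumulated log scalers;
per-state tie-breaking in summaries is first-found in the seeded order;
SPR accepts the first strict improvement (tolerance 1e−12). The test and
validation runs use desk-scale problem sizes chosen to make the
statistical checks sharp while keeping the suite quick: 3–11 taxa for
oracle comparisons (where exhaustive enumeration is feasible), 8–10 taxa
for sampler audits, chains of 10^4–10^5 generations for the statistical
reproductions, and the 107-taxon synthetic stand-in for parsing. The
engine itself supports the production configuration shipped in
`inst/extdata/fullscale_run.yaml` (800 million generations × 4 runs);
running it is a cluster-scale job.

# Known limitations

* Homology blocks must have equal character counts across codings; blocks
  with genuinely different column counts per hypothesis are not supported
  (the likelihoods of different-width alignments would not be directly
  comparable without further modelling choices).
* The implied-weights search implements random-addition + SPR only; no
  ratchet, tree fusing or TBR. For large matrices the reference tree is a
  heuristic optimum.
* Consensus node ages use mean MRCA heights and can be non-monotone on
  nested clades.
* The FBD prior is constant-rate; no skyline variants, no diversified
  sampling.
* Inapplicable cells are treated as missing in the likelihood and
  parsimony scores; no hierarchical character dependencies.
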