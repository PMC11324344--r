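---
title: "Evolutionary binder optimization: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary binder optimization: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evobinder)
```

## The procedure

`evobinder` performs in silico affinity maturation of a protein binder
against a fixed target. One **epoch** of the protocol, applied to every
active lineage, is:

1. *Choose* — pick mutation site(s) on the binder and replacement residues.
2. *Mutate* — apply the substitutions to the structural model.
3. *Sample* — generate an ensemble of conformations around the bound pose.
4. *Score* — evaluate every frame with each configured scoring function and
   average per scorer.
5. *Prune* — compare the mutant's averages against its parent's and decide
   whether the lineage continues.

Branches surviving an epoch become the parents of the next, forming a
layered directed acyclic graph: edges only run from one epoch to the next,
so acyclicity holds by construction. When *no* mutant survives an epoch, the
parent binders are carried into the next layer unchanged (with their cached
scores) and re-branched — the search restarts from the originals rather than
dying. Width is managed in two modes: **variable** (every survivor
continues; suited to abundant compute) and **constant** (survivors are
ranked and capped at `max_width`).

All scores obey a single convention: **lower is better**, enforced by a
per-scorer sign multiplier. This is what makes "improvement" a single global
predicate that consensus pruning and width ranking can share across scorers
with heterogeneous native conventions.

## The coarse-grained structural model

Full-atom molecular dynamics is out of scope at desk scale, so the package
represents each residue by two pseudo-atoms: the backbone **anchor** (the
alpha-carbon) and a **side pseudo-atom** (the beta-carbon when present;
glycine's coincides with its anchor). The interface is defined by side-side
distance: two residues across the binder/target partition are in contact
when their side pseudo-atoms lie within a cutoff, default **8 Å**, a
standard coarse-grained contact convention. The cutoff is configurable per
scorer; interface membership is monotone in it.

Mutation changes residue identity without moving coordinates, because
side-chain repacking belongs to the full-atom mutators the adapter contract
accommodates, and the built-in scorers read only identity plus pseudo-atom
position. Two glycine special cases keep the representation consistent:
mutating *to* glycine collapses the side pseudo-atom onto the anchor;
mutating *from* glycine grows a pseudo-beta-carbon at **1.53 Å** (the
C–C bond length) along the local outward direction — from the centroid of
the two flanking anchors through the residue anchor, with a deterministic
perpendicular for chain-terminal residues. The construction is
rotation-covariant and purely geometric, so lineage replay is exact.

## The sampler as an MD stand-in

The sampler exists to reproduce the *ensemble-averaging semantics* of
MD-based protocols, not their thermodynamics. Each frame beyond the first
applies to the binder a uniform random rotation (angle ≤ `rigid_rot_max`,
default 5°) about its centroid and a random translation (≤
`rigid_trans_max`, default 1 Å), then adds isotropic Gaussian jitter
(`residue_noise_sd`, default 0.3 Å) to every pseudo-atom of both partners.
Defaults are deliberately small so the interface stays intact while score
averages become ensemble quantities. Frame 1 is always the unperturbed
input pose, which stabilizes averages at small ensemble sizes and gives
every ensemble a reference frame whose scores equal the un-sampled
complex's.

Restrained sampling — the early phase of two-phase protocols, where
positional restraints keep the binding pose from drifting before the
interface has matured — is modelled by multiplying all three amplitudes by
`restraint_factor` (default 0.2, in (0, 1]). The epoch schedule's
`restrained_epochs` field says how many leading epochs sample restrained; a
5-restrained + 13-unrestrained schedule reproduces the classic two-phase
shape, and the trajectory report labels each epoch's phase. The ensemble
size default (`n_frames` = 10) is a free choice: large enough for averaging
to matter, small enough to keep desk-scale runs in seconds.

## Scorers

Three built-in scorers operate on the pseudo-atom interface:

* **contact count** — minus the number of cross-interface contacts; the
  crudest possible packing proxy.
* **contact potential** — a symmetric 20×20 residue-pair table summed over
  contacts. The shipped default (`inst/extdata/contact_matrix.txt`) has
  plausible, documented structure — hydrophobic–hydrophobic −0.5,
  opposite-charge −0.6, like-charge +0.6, polar–polar −0.2 — and can be
  overridden per scorer; it makes no claim to be a fitted potential.
* **screened electrostatics** — Debye-screened Coulomb
  q·q·e^(−d/λ)/d over contact pairs, with integer-ish residue charges
  (D, E: −1; K, R: +1; H: +0.5 for partial protonation) and screening
  length λ default 10 Å. Coincident pseudo-atoms are skipped with a
  warning rather than producing an infinity.

External scorers attach through the same adapter contract as mutators and
samplers: a frame PDB in, one real number out, sign-normalized like every
other scorer.

**Per-residue decomposition.** Guided site selection needs to know which
residues contribute least to binding. Every built-in scorer decomposes by
splitting each pair's term half to each partner residue; the hidden-oracle
scorer (below) additionally charges its mismatch penalty to the deviating
residue. The half-split is a design choice — pair potentials admit no
canonical attribution — with the conservation property that per-residue
contributions sum exactly to the total score, which the tests verify to
1e-9. The residue with the *largest* (worst) contribution is the guided
chooser's next target, with (chain, position) order breaking ties
deterministically.

## Choosing mutations

Site selection is `random` (uniform over the user-declared mutable
positions) or `guided` (worst-first by the decomposition of a configurable
guide scorer, defaulting to the first decomposable scorer of the run).
Replacement schemes: `uniform` over the 19 alternatives, `custom` weights
(renormalized after zeroing the current residue), or `grouped` within one
physico-chemical category. The default partition — negative {D,E}, positive
{K,R,H}, polar {S,T,N,Q,C,Y}, aliphatic {A,V,L,I,M,G,P}, aromatic {F,W} —
is a conventional five-class grouping; users can supply their own.

An epoch's branches must be *pairwise-distinct* mutation sets with distinct
sites within each set. Distinctness is enforced by resampling with a
bounded retry budget (default 100 consecutive duplicates) so generation
always terminates; when the policy admits fewer distinct sets than
requested, the error reports the exact achievable maximum (computed by
enumeration in the single-site case). A node whose chooser is exhausted is
marked *failed* and the run continues while any lineage remains; only when
every lineage has failed does the run stop early, recording the reason.

## Pruning

* **Consensus threshold** — retain a mutant iff at least `consensus_k`
  scorers improved by more than `tolerance` (default 0: strict inequality,
  no margin). Retention is monotone in both parameters.
* **Metropolis** — single-scorer Monte Carlo acceptance with probability
  min(1, e^(−Δ/T)); improvements always pass, slight worsenings sometimes,
  giving the search a temperature-controlled tolerance for downhill moves.
* **Top-N** — keep the `keep_n` lowest averages on a reference scorer,
  ties broken by branch id.

One design decision deserves emphasis: under top-N pruning the engine lets
the **parent compete in the ranking pool**. A mutant is retained only if it
outranks the parent into the top `keep_n`; when the parent itself wins a
slot, the no-retention restart rule carries it forward. Without this, pure
top-N would always advance the best mutant even when all mutants are worse
than the parent, and greedy (`keep_n` = 1) optimization would random-walk
instead of hill-climb. With it, the best retained score is provably
non-increasing in the greedy regime — a property the acceptance tests
check over 15 epochs. `top_prune()` itself implements the plain
mutants-only contract; the pooling happens one level up, in the epoch loop.

Width capping in constant mode ranks survivors by (number of scorers
improved over the parent, descending; mean across-scorer rank of the
averages, ascending; node id) — improvement breadth first, then aggregate
quality, then a deterministic tiebreak.

## Determinism and dispatch

Reproducibility is a hard contract: a run is a pure function of (config,
seed). Every stochastic stage — choosing, sampling, Metropolis pruning —
draws from a private substream whose seed is a polynomial rolling hash
(modulo the Mersenne prime 2³¹−1) of the master seed and the stage's
(epoch, node, branch, stage) labels. Task randomness therefore never
depends on worker identity or timing, and the sampling/scoring tasks of an
epoch can be executed over any worker count (first-come-first-served FIFO
over a forked pool) with bit-identical results — the acceptance suite
compares `lineage.json` and every score CSV across 1, 2 and 8 workers. A
failing task is recorded as a failed branch without aborting the batch.

## Synthetic fixtures and what passing tests mean

`make_toy_complex()` builds two idealized chains (strands, helices or
seeded random blobs) facing across a configurable `interface_gap`, with
3.8 Å consecutive anchors and seeded random sequences. It emulates the
*geometry* of a binding interface — enough cross-partner contacts for every
scorer and chooser to operate — but none of the statistics of real
proteins: no secondary-structure propensities, no packing constraints, no
realistic sequence composition.

`hidden_oracle_scorer()` plants a known optimal binder sequence and scores
contact count plus a per-mismatch penalty (`weight`, default 1.0 —
comparable to one contact, so structural noise does not drown the planted
signal at default sampler amplitudes). It gives the optimizer a testable
analogue of "improving affinity" with a known global minimum while
remaining frame-dependent like a genuine scorer. `plant_suboptimal()`
corrupts exactly *k* sites; glycine is excluded as source and replacement
so the corruption is purely sequence-level and the oracle cost is exactly
*k*·weight above the optimum.

The recovery experiment — corrupt 3 of 12 binder positions, guided
chooser, greedy top-1 pruning, 10 branches per node, 15 epochs, zero-noise
sampler — uses the *guided* chooser deliberately. The oracle decomposition
makes mismatched residues the worst contributors, so each epoch
concentrates its 10 distinct replacement draws on one mismatched site and
fixes it with probability 10/19; three fixes in 15 epochs then succeed in
essentially every seeded run, and the acceptance criterion (≥ 16 of 20
runs) passes with margin. With a random-site chooser the per-epoch fix
probability drops to roughly 0.12 and 15 epochs are nowhere near enough —
a useful illustration of why score-guided site selection matters. Passing
these tests demonstrates that the engine's bookkeeping, pruning logic and
search dynamics are correct; it says nothing about affinity prediction on
real complexes, which depends entirely on the scorers plugged in.

## Numerical choices and degenerate inputs

* Improvement comparisons use strict `<` with an additive tolerance
  (default 0); score-table averages are validated against per-frame means
  to 1e-9.
* Zero-amplitude sampling reproduces the input pose bit-exactly (the rigid
  move is skipped when its drawn angle and translation are exactly zero,
  avoiding spurious floating-point round-trips).
* Glycine side pseudo-atoms are re-pinned to their anchors after jitter so
  the representation invariant survives sampling.
* PDB coordinates round-trip at the format's 1e-3 Å precision; a second
  round trip is exact. Duplicate atom records and non-canonical residues
  are rejected; missing CB falls back to CA with a warning; residues
  without CA are skipped with a warning.
* Ties everywhere (guided site, top-N, width ranking) break by fixed
  lexicographic keys so no decision depends on hash order or locale.

Problem sizes in the shipped tests and acceptance script — 12+12 to 30+30
residue complexes, ensembles of 2–10 frames, up to 18 epochs, 20-run
experiments — are the package's chosen desk-scale operating point: large
enough to exercise every code path and statistical check, small enough
that the full suite runs in well under a minute.

## Known limitations

* The coarse-grained scorers are placeholders with plausible structure,
  not validated energy functions; real campaigns should plug in external
  scorers through the adapter contract.
* Mutation does not repack side chains; conformational response to
  mutation is delegated entirely to the sampler (or an external one).
* The sampler explores a small neighbourhood of the input pose; it cannot
  discover alternative binding modes, and restrained/unrestrained phases
  differ only in amplitude.
* Hand-off between the restrained and unrestrained phases is direct: no
  trajectory clustering or representative-structure selection happens
  between phases.
* Lineages never recombine, and a resumed run must reuse the identical
  configuration; resuming across config changes is unsupported.
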