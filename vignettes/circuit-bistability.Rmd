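---
title: "Screening two-position histone codes for heritable bistability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening two-position histone codes for heritable bistability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histcirc)
```

## The model

Epigenetic memory requires a cluster of nucleosomes to hold one of two
alternative modification states through noise and DNA replication. histcirc
models the smallest histone code in which this choice is combinatorially
rich: two histone positions, each unmodified (0) or modified (1), giving
four half-nucleosome types indexed `0 = 00`, `1 = 10`, `2 = 01`, `3 = 11`
(index = pos1 + 2·pos2). The eight one-modification interconversions are
fixed; a *circuit code* such as `00033033` assigns to each reaction the
single nucleosome type whose bound reader–writer enzyme catalyses it, or
`x` for a noise-only transition. Two types, E1 and E2, are read out as the
alternative epigenetic states; a third role, R, is the type deposited on
newly replicated DNA.

The slot order of the code string is

```{r}
reaction_table()
```

Reactions 1, 2, 3, 6 move toward type 0 and reactions 4, 5, 7, 8 toward
type 3. This ordering is pinned by the printed reference circuits it must
reproduce: the consensus circuit `00033033` assigns every toward-0 reaction
to type 0 and every toward-3 reaction to type 3; the classical circuit
`x003xx3x` runs both of its two-step pathways over a single intermediate;
and the exceptional working circuit `x10320x3` contains neither a standard
two-step nor a pull-push motif (see below) — a property that distinguishes
this slot assignment from its position-swapped alternative. With this
convention the classical pathway runs over type `01` (index 2), so the
standard E-opposite/R-out arrangement uses `R = 2`; choosing `R = 1`
instead gives an equivalent screen by the position-exchange symmetry.

Two relabellings act on circuit codes: `complement_twin()` exchanges the
roles of the two E types (`t -> 3 - t`) and `position_swap_twin()`
exchanges the two histone positions (`1 <-> 2`). Both are involutions and
they commute, so symmetry orbits have size 1, 2 or 4.

## The stochastic dynamics

A system of `N = 30` half-nucleosomes evolves by three elementary moves:

* **Recruitment.** A substrate and a distinct recruiter nucleosome are
  drawn uniformly; if the recruiter's type catalyses an applicable
  reaction (at most two can apply; ties are a fair coin), the substrate
  converts. Recruitment has no distance structure: any nucleosome can
  convert any other.
* **Noise.** With probability `alpha` per iteration, one nucleosome steps
  to one of its two Hamming neighbours.
* **Replication.** After `50 * N` recruitment+noise iterations (one
  generation), every nucleosome is independently replaced by the R type
  with probability 0.5.

The protocol behind every screen is 250 generations from an all-E1 start,
250 more from an all-E2 start, repeated 4 times: 2000 recorded generations
per circuit, with `(n_E1, n_E2)` sampled just before each replication.

Three scores summarise a trajectory. A generation is in state E1 when
`n_E1 - n_E2 >= N/2` (and symmetrically for E2), else undecided. With
`P1` and `P2` the classified fractions, the balance is `B = 4 P1 P2`,
which is 1 for a perfectly balanced trajectory and reaches the working
threshold 0.75 both at a 25/75 split of a fully classified trajectory and
when each state holds 43.3% of a trajectory with undecided time. `f`
counts spontaneous switches per recorded generation (undecided gaps are
collapsed; forced re-initialisation flips are excluded), and `tau` is the
mean length of the undecided gaps crossed while switching. A circuit
*works* when `B >= 0.75`, `f <= 0.1` and `tau <= tau_max`.

```{r}
arr <- standard_arrangement("e-opposite-r-out")
traj <- run_circuit("x003xx3x", arr, sim_params(seed = 1))
score_trajectory(traj)
```

The compiled kernel consumes the RNG stream in exactly the same order as
the exported pure-R steppers (`step_recruitment()`, `step_noise()`,
`replicate_state()`), so `run_circuit()` and `run_circuit_r()` are
bit-identical for a given seed — the slow reference implementation is a
genuine cross-check of the fast one, not a re-export.

## Parameter choices

* `alpha = 0.004` per iteration is the default screening noise: 0.2
  random conversions per nucleosome per generation against 50 recruitment
  attempts, i.e. recruitment dominates noise by two orders of magnitude as
  heritable bistability requires. Where a reference working count is
  available, `calibrate_alpha()` sweeps a grid of noise levels and selects
  the one whose working count comes closest before downstream counts are
  compared.
* `tau_max = 5` generations. The dwell threshold expresses decisiveness;
  `working_sensitivity()` re-thresholds a finished screen's stored scores
  over `tau_max` in {2, 5, 10} without re-simulating, and at low noise the
  verdicts barely move because working circuits switch rarely and cross
  quickly.
* High-noise demonstrations (replication off) use `alpha = 0.016`, the
  screening default increased four-fold — the same multiplier used for
  robustness checks of the screened circuits.
* Destabilisation scope: the back-reaction converting a pathway's
  intermediate to the attacked E type counts as destabilising when it is
  recruited by any type *other than the driver*; driver-recruited loss
  cancels out of the feedback and demonstrably fails to rescue
  bistability. The stricter reading (only the attacked E type counts) is
  available as `destab_scope = "attacked-E"` for sensitivity reporting.

## Cooperativity motifs

Positive feedback needs cooperativity, and with four types it can be
assembled in two ways, both detected statically:

* **Standard two-step** (`count_standard_two_step()`): E recruits the
  attack `O -> I` on its opponent and its own creation `I -> E`. Two E
  nucleosomes act in sequence, so the feedback is quadratic in the E
  count.
* **Pull-push** (`count_pull_push()`): E recruits the attack `O -> I`,
  and the intermediate itself recruits `I -> E`. E creates both the
  recruiter and the target of its own creation.

Either motif yields ultrasensitivity only when the intermediate is
*destabilised* — a recruited loss `I -> O`. In mean field the steady
intermediate occupancy is its creation flux divided by its total loss
rate; a sizeable recruited loss makes that occupancy, and hence the
second feedback step, sensitive to the attacking E population. When the
driver itself recruits the loss, the sensitivity cancels.

```{r}
count_standard_two_step("x003xx3x", arr)
motif_report("x10320x3", arr)
```

`minimal_enzymes()` counts distinct (recruiter, position, direction)
triples: an enzyme that modifies one position regardless of the other
position's state serves two slots at once, which is why the consensus
circuit needs only 4 enzymes for its 8 recruited reactions.

## Screening and the evolutionary network

`enumerate_codes()` generates the full `5^8 = 390625`-code space or any
slot-restricted subspace; `screen_codes()` runs the standard protocol per
code with a per-code seed hashed from the master seed and code index, so
results are independent of screening order and trivially parallelisable.
The full space takes hours of CPU; the vignette-scale surrogate used
throughout the tests is the 625-code subspace `"x***xx*x"` that contains
both the classical and the all-noise circuit (problem sizes here and in
the test suite — restricted subspaces, 1–2 repeats, 20-seed panels — are
chosen to keep each analysis in the seconds-to-minutes range while leaving
every protocol parameter at its standard value).

`summarize_screen()` tabulates the working set: reaction usage per slot,
toward/away recruitment histograms, pathway classes split by direction and
by over-R versus non-R intermediate, destabilised-motif combinations,
exotic circuits (working without any standard two-step pathway), and a
twin-discordance diagnostic. The symmetry that fixes a whole R-out screen
is the E-role swap `e_swap_twin()` (complement and position exchange
composed, leaving both intermediates and hence R in place): twin pairs
under it face identical dynamics and should receive equal verdicts up to
Monte-Carlo noise at the working boundary, so the discordant fraction
measures screening noise and shrinks with more repeats. The bare
complement twin instead maps an `R = 2` screen onto the equivalent
`R = 1` screen.

`build_circuit_graph()` links working circuits that differ at exactly one
slot; `graph_components()` and `neutral_path()` then answer the
evolutionary question of whether one working circuit can be rewired into
another through single enzymatic replacements without ever losing
bistability.

## Mean-field analysis

`build_meanfield()` writes the deterministic rate equations on the
occupancy simplex: each recruited reaction `s -> t` by `q` contributes a
mass-action flux `P_q P_s`, and noise exchanges occupancy with both
Hamming neighbours at rate `alpha_mf` (replication is deliberately absent,
matching the replication-free simulations the motif arguments rest on).
`find_fixed_points()` uses damped Newton iterations from 100 Halton
multi-starts on the simplex plus vertex and centre starts, deduplicates
solutions, and classifies stability by the eigenvalues of the reduced
(3-coordinate) Jacobian; non-converged starts are counted, never silently
dropped. `meanfield_bistable()` asks for two stable fixed points dominated
by different E types.

```{r}
find_fixed_points(build_meanfield("00033033", alpha_mf = 0.05))
```

The mean-field and stochastic routes agree on the qualitative suite the
package tests: consensus, classical and the destabilised double pull-push
circuit are bistable; the all-noise circuit and the symmetric double
two-step *without* destabilisation are not.

## Numerical and design notes

* Dedup tolerance for fixed points is 1e-8 (solutions are refined to
  ~1e-12 residuals first); stability uses a -1e-8 margin on the largest
  real part, so marginal directions are conservatively called unstable.
* `early_abort` in `screen_codes()` skips remaining repeats only when the
  balance score provably cannot reach `B_min` even under an optimal
  allocation of all remaining records — it can re-score non-working
  circuits from fewer records but can never flip a verdict. It is off by
  default.
* Ties between two applicable reactions are a fair coin; the substrate
  cannot recruit onto itself (the recruiter is drawn from the other
  `N - 1` nucleosomes).
* Degenerate inputs fail fast: codes of the wrong length or alphabet name
  the offending position; trajectories shorter than 2 records, negative
  counts and off-simplex probabilities are errors, not warnings.

## What the simulations do and do not show

The generator *is* the model under study — there is no external data.
What passing tests establish is internal: the dynamics honour their
contracts (conservation, seeding, kernel-reference identity), the motif
detectors match their definitions, and the known reference circuits
reproduce their qualitative behaviour. The model idealises aggressively:
recruitment is distance-free and all reaction strengths are equal; each
nucleosome is two independent half-nucleosomes (the 10-type full
nucleosome combinatorics is out of scope); enzymes are maximally
discriminating (one recruiter per reaction). Conclusions about real
chromatin — where rates are graded, recruitment decays with distance and
readers bind combinatorially — inherit those caveats.

## Known limitations

* The full 4-arrangement screen of all 390,625 circuits is a multi-hour
  single-CPU computation; the packaged tests exercise the screen on
  restricted subspaces only.
* Mean-field fixed-point search is heuristic multi-start Newton; for
  pathological circuits with near-degenerate fixed-point clusters the
  deduplication tolerance may merge genuinely distinct points.
* The k-step path finder (`feedback_paths()`) generalises the two-step
  motifs but no reference count exists for paths longer than two steps.
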