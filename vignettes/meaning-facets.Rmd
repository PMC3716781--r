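---
title: "Meaning facets of kinetic bio-models: data model, dynamics classification and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meaning facets of kinetic bio-models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The data model

A kinetic bio-model has a dual interpretation.  As a formal object it can
be parsed, analysed and integrated with no reference to biology; as a
scientific artefact its parts stand for molecules, conditions and
phenomena.  `semfacets` represents both sides from three perspectives —
the model's *structure* (what its components are), its *function* (how it
is meant to be used in simulation experiments) and its *behaviour* (what
its dynamics mean) — giving nine facet cells S1–S3, F1–F3, B1–B3, each
with an intrinsic and an extrinsic side and two fixed aspect names per
(cell, side).  The resulting 36 addresses are a closed vocabulary
(`facet_addresses()`); nuances that do not fit an aspect go into the
slot's free text rather than into ad-hoc extensions.

Slot content is deliberately dual-channel: free text for prose answers,
resource annotations (MIRIAM URN / identifiers.org URL cross-references
into UniProt, GO, NCBI Taxonomy, SBO, TEDDY, KiSAO, Reactome, the Cell
Ontology, ...) for machine-comparable claims, and an optional structured
payload where the content is executable — a simulation setup belongs under
F3-intrinsic *setup*, an instantiation under F2-intrinsic, a DYML document
under B1-intrinsic, a trajectory handle under B2-intrinsic.  The validator
enforces payload placement, annotation well-formedness and the single hard
rule of the framework: **at least one extrinsic slot must be filled**,
because a model that represents no biological system at all is
biologically meaningless.  Every other missing aspect is a *gap* — an
incompleteness, reported together with the guiding question that would
fill it (`completeness_questions()`), not an error.  This is the
non-interactive counterpart of an annotation assistant: the questions are
generated from the record's actual holes.

Records serialize to a versioned YAML document with sorted slot keys, so
two records diff cleanly as text and write–read–write is byte-identical.
Global meta-information (origin, access, relations to other models) uses a
closed relation vocabulary — abstraction, refinement, version_of,
integrated_from, competing, modified_version_of; the direction of an
asymmetric relation such as abstraction is carried in the note field.

## From reaction network to programme

The SBML subset is pinned to Level 2 Version 4 core constructs: species
(with boundary/constant marking), global parameters, assignment rules for
algebraic definitions, reactions with MathML kinetic laws restricted to
`+ - * /` and integer powers, and RDF resource annotations.  Events,
rate and algebraic rules, function definitions and constraints raise
explicit unsupported-feature errors — a silent misparse would corrupt the
programme — while purely declarative extras (compartments, unit
definitions) are reported via a warning and skipped.  There is no unit
conversion engine; the model records its units as text.

The programme derives mechanically: for every non-constant species the
right-hand side is the sum over reactions of net stoichiometry times the
kinetic law.  Constant species (the nucleotide pool `AP`, amino acids
`aa` in the packaged model) appear in laws but get no rate equation.
Conservation can be checked two ways: `conserved_total_residual()`
evaluates the drift of a weighted total at a state point, and
`conserved_total_symbolic()` cancels syntactically identical terms of
opposite sign across the summed right-hand sides — for total cdc2
([CT] = [C2]+[CP]+[pM]+[M]) the cancellation is exact, term by term,
returning the number 0.  Symbolic equality between a derived programme
and independently written equations is checked numerically at randomized
states (tolerance 1e-9 at 100 states); full polynomial canonicalization
is not attempted because the rational term ([M]/[CT])² makes it brittle
while the numerical check is sharp at these tolerances.

## The simulation engine

`run_timecourse()` integrates with `deSolve::lsoda` at absolute/relative
tolerances 1e-9.  The KiSAO algorithm identifier in a setup (the packaged
time-course records KISAO_0000280, a fourth-order Adams–Moulton routine)
is preserved as metadata, not used for dispatch: one robust stiff-capable
integrator at these tolerances gives results that are
algorithm-independent to far below every threshold used in the package,
and faithfully recording the *described* setup is itself part of the F3
facet.  The output grid is decoupled from internal steps (so a 0.001 min
reporting step does not force 100 001 integrator steps), perturbations are
instantaneous state increments applied through solver events (zero-delta
perturbations are dropped before integration — they are no-ops, and
keeping them would perturb the adaptive step sequence), and states more
negative than −1e-9 abort the run rather than being clipped: a mass-action
system started non-negative should stay non-negative, so deeper
negativity signals solver trouble that clipping would hide.

Post-processing expressions are evaluated pointwise over the raw columns
with the model's algebraic definitions in scope; only definitions the
expressions transitively use are computed.  The packaged Model 1
experiment normalises [M] and total cyclin [YT] by [CT].  The membership
of "total cyclin" is fixed as [YT] = [Y]+[YP]+[pM]+[M] — every species
containing a cyclin moiety; the source text never enumerates the summands,
so this is a recorded package decision.

## Classifying qualitative dynamics

`classify()` is deterministic given (instance, protocol).  The default
protocol runs 2400 min sampled every 0.3 min and discards the first half
as transient.  The decision sequence:

1. **Fixed point** — relative post-transient variation of every state
   below `tol_fp = 1e-6`.
2. **Excitability test** — a converged system is perturbed upward in the
   designated slow variable by 5 % of a reference steady-state value; an
   excursion at least 10× the perturbation, followed by return to the
   fixed point, classifies as *excitable switch*, otherwise *stable fixed
   point* (TEDDY_0000113).  For the two-variable model the perturbed and
   reference variable is `v`; for the six-variable model the perturbed
   pool is free cyclin `Y` with the magnitude referenced to the
   inactive-MPF pool `pM`.  Newly synthesised cyclin binds phosphorylated
   cdc2 quickly, so accumulated cyclin lives in `pM` — the counterpart of
   `v` — while the free pool is nearly empty at steady state and 5 % of it
   would be no perturbation at all.  Perturbing `pM` directly would be
   wrong for a subtler reason: it adds cdc2 along with the cyclin,
   inflating [CT] and partially cancelling its own effect.
3. **Limit cycle** — at least 5 successive peaks with period
   coefficient-of-variation below 1 %, plus a sustainment guard: the mean
   peak height of the first and second half of the window must agree
   within 2 % of the oscillation amplitude.  Period CV alone would accept
   a slowly decaying stable focus (its ringing is perfectly periodic),
   which would then contradict the Jacobian oracle.  Because very sharp
   spikes are undersampled on the output grid (making one state's
   interpolated peak heights noisy), sustainment may be certified by any
   appreciably oscillating state — a decaying focus drifts in every state
   alike, so the guard still excludes it.  A trajectory with a clean
   period whose heights still drift is *settling* (usually slow approach
   to the cycle); one extension leg restarted from the final state decides
   it, after which the verdict is `unclassified`.
4. Anything else is `unclassified` with a diagnostic — deliberately
   including chaotic or quasi-periodic behaviour (no Lyapunov-exponent
   machinery) and cells whose slow modes outlast the horizon.

The independent oracle is `jacobian_class_at_fixed_point()`: the Jacobian
is built symbolically (base `D()` on the closed-form right-hand sides,
algebraic definitions substituted) and its eigenvalue real parts give the
local verdict.  The test suite checks the two routes against each other
across a full regime scan.

`scan()` classifies a two-parameter grid; per-cell solver failures
downgrade to `unclassified` cells with diagnostics rather than aborting
the scan.  `locate_bifurcation()` refines every boundary edge between a
stable-fixed-point cell and a limit-cycle cell: the equilibrium is
continued by damped Newton iteration (warm-started from the stable side)
along the geometric interpolation of the two parameter points, and
bisection drives the leading eigenvalue real part to |Re λ| < 1e-6.  Such
a crossing is labelled Hopf (TEDDY_0000074).  Supercriticality is asserted
from the systems' phenomenology, not verified by normal-form
coefficients — first-Lyapunov-coefficient computation is out of scope.
Edges between other label pairs are left `unknown`: an excitable/stable
edge has no eigenvalue crossing, and typing an excitable/oscillation edge
would need the same normal-form analysis.

## DYML

The dynamics-assertion language relates parameter constraints (closed
intervals or fixed values) to an asserted dynamics class.  Its concrete
syntax here — a versioned YAML dialect with a model reference, per-statement
constraints and a class label — is a fresh design by this package: the
idea of such a language exists in the literature but no usable concrete
syntax does, so the format should be read as package-defined.
`check_dyml()` samples each statement's constraint box by a seeded Latin
hypercube (default 16 samples; log-uniform on strictly positive bounds,
since the constrained quantities are rate constants), classifies every
sample, and passes a statement only if all samples match, reporting
counterexample points otherwise.  The packaged Model 2 document asserts
the found stable and oscillatory regimes on ±5 % boxes around the packaged
regime points, with only k4 and k6 varying.

## Model comparison and the abstraction check

Structural comparison intersects resource annotations per (cell, side) by
exact (namespace, identifier) match.  No subsumption reasoning over GO or
SBO is performed — the comparator stays dependency-free and honest about
its evidence; the one deliberate exception is the taxonomy fragment's
lowest-common-ancestor helper, which generalizes organisms (sea urchin
7625 × frog → Deuterostomia 33511).  Exact-string text matches are
reported but flagged as weak evidence.  Behavioural comparison is set
algebra over class labels produced under the same protocol family.

`check_abstraction()` compares trajectories, not vector fields: the
variable mapping u = [M]/[CT], v = ([Y]+[pM]+[M])/[CT], α = k₄′/k₄ is
applied to the source run and the per-variable maximum and RMS deviations
from the target run are reported.  Trajectory comparison is well-defined
without symbolically deriving the reduction, which matches how the
models' equivalence is argued in the first place.  The packaged
abstraction pair is the Model 1 oscillatory regime point *projected* to
Model 2 (k4, k4′, k6 shared; r = k1·[aa]/[CT] with aa = 1 and conserved
CT = 1).  The direction matters: an arbitrary Model 2 point need not lift
to an equivalent Model 1 point, because Model 1's activation flux is
capped by the finite pM pool while Model 2's (v − u) factor is unbounded —
lifting a point whose cycle relies on v − u exceeding that cap produces a
six-variable system that stalls at a low-activity equilibrium while free
cyclin accumulates.  Projection of a Model 1 point never faces this
problem.  The consistency tolerance for the packaged pair is a fixture
constant (0.01), calibrated once by running the comparison in the packaged
regime (observed maximum deviation ≈ 5e-4, i.e. a 20× margin); it is not a
universal threshold, because the reduction holds only under its
assumptions.

## The fixtures as a synthetic-data generator

`tyson_model1()` rebuilds the six-ODE model reaction-wise so that
programme construction is exercised: cyclin synthesis (k1·aa), cyclin
degradation (k2), association of phosphorylated cdc2 with cyclin (k3),
autocatalytic activation pM → M at rate pM·F with
F = k4′ + k4·([M]/[CT])², inactivation (k5·AP), dissociation M → C2 + YP
(k6), YP degradation (k7), cdc2 phosphorylation (k8·AP) and
dephosphorylation (k9).  Only the dissociation reaction is printed
explicitly in the source; this set is the sparse decomposition whose
programme reproduces the six printed equations exactly, but the archived
database encoding may group steps differently.  The facet record carries
the printed cross-references (UniProt P04551 on C2, GO:0000278,
Taxonomy 7625/33511/6072, SBO:0000293/252/180/012/472, REACT_6308,
CL:0000007, KISAO_0000280, TEDDY_0000113/0000074, PubMed 1831270) and
leaves unfilled exactly the aspects the source publication never
provides.  The frog taxonomy node is label-only — no numeric identifier is
given in the source material, and inventing one would be worse than
honesty.

The source parameter table is cited but not available, so **no rate
constants are hard-coded**.  `find_regime_parameters()` samples a
documented search box by a seeded Latin hypercube — k4 ∈ [30, 600]/min,
k6 ∈ [0.05, 10]/min, k4′ ∈ [0.003, 0.3]/min, lumped cyclin synthesis
∈ [0.01, 0.04]/min, log-uniform, 96 samples — and returns the first point
classifying to the requested label.  The box spans the physiologically
plausible decades around the oscillatory operating point of the MPF
system; the synthesis-rate band keeps cycle periods within what the
classification window can certify (five peaks in 1200 min).  The
six-variable model fixes the auxiliary constants once at values satisfying
the reduction's stated assumptions (k2 = 0 and k5 = 0, fast binding
k3 = 200, fast phosphorylation k8 = 1000 ≫ k9 = 10, k7 = 0.6; all per
min).  The excitable regime is a thin sliver adjoining the Hopf boundary
on the stable side, which blind sampling can miss; when it does, the
finder walks deterministically from a found oscillatory point toward
increasing k6 (stepping the basal rate k4′ down to sharpen the activation
knee) and probes just beyond the oscillation's end.  Everything is
reproducible from the seed; the packaged bundles pin seed 101.

What the generator does *not* emulate: measurement noise, cell-to-cell
variability, stochastic kinetics, or the archived SBML files themselves
(byte-level equivalence with the database encodings is a non-goal).
Passing tests therefore demonstrate internal correctness of the machinery
and fidelity to the printed equations and annotations — not agreement
with the historical archive or with wet-lab data.

## Problem sizes and runtime choices

The test suite runs the full pipeline at sizes chosen to keep a complete
run comfortable on one CPU: regime searches with 96-sample budgets, a
20×20 (k4, k6) scan for the classifier/oracle agreement check, 6×6 scans
elsewhere, 1000 random states for the conservation property, and
randomized round-trip batches of 4–8 documents per format.  The packaged
time-course description keeps its faithful 0.001 min reporting step; tests
that execute it use a coarser copy, which changes only the output grid,
not the solution.

## Known limitations

* Chaotic and quasi-periodic dynamics fall into `unclassified`; there is
  no Lyapunov-exponent machinery.
* Hopf supercriticality is asserted, not verified (no normal-form
  coefficients); limit-point and period-doubling detection are absent.
* Identifier resolution is offline: annotations are syntax-checked and
  compared, never dereferenced against the live registries.
* No OWL/description-logic reasoning over the referenced ontologies;
  structural overlap is exact-identifier only.
* The SBML subset excludes events, delays, algebraic rules and the units
  machinery; SED-ML-lite is a marked subset, not compliant SED-ML.
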