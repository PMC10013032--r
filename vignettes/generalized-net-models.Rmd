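---
title: "Modelling impact and reaction with reduced Generalized Nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling impact and reaction with reduced Generalized Nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fopnet)
```

## The model

`fopnet` is a discrete-event engine for *reduced Generalized Nets* (GNs), a
Petri-net extension with three distinguishing features:

1. **Predicate-valued transition conditions.** Each transition is a triple
   ⟨L′, L″, r⟩ of input places, output places, and a condition r in the form
   of an *index matrix*: rows are labelled by input places, columns by output
   places, and each cell holds a Boolean predicate. A token in input place i
   may transfer to output place j only when r(i, j) evaluates to true under
   the current net state.
2. **Token characteristics.** Tokens are information carriers with an
   append-only history of timestamped characteristic records. Whenever a
   token transfers, unites, or receives new information, the characteristic
   function Φ appends a record at the current tick.
3. **A global tick clock.** All events refer to one integer time scale, so
   latencies are counted in ticks and traces are totally ordered.

Formally the net is the four-tuple ⟨A, K, X, Φ⟩ — transitions, tokens,
initial characteristics, and the characteristic hooks — exposed by
`gn_components()`. Places are not a top-level component of the reduced form:
they live inside the transitions' input/output sets (the engine keeps an
operational place registry, clock and trace buffer alongside, but those are
plumbing, not part of the formal tuple). The reduced form deliberately omits
transition priorities, place capacities and multi-tick transition durations;
everything here is unit-tick and unbounded.

Token lifecycle events are **transfer** (a token moves along an enabled
arc), **split** (a token stays put and spawns children with their own
characteristics and parent provenance), **unite** (co-located tokens merge
into a surviving host whose history is the stable tick-ordered merge of the
constituents'), and **stop** (a token ceases functioning). Every state
change is mirrored by exactly one trace event, which is what makes the
conservation audit possible:

    live(t+1) = live(t) + births_by_split − deaths_by_unite − deaths_by_stop

A token that unites *and* stops (a sub-threshold impact absorbed by a
threshold token) dies exactly once in this ledger: the unite event carries
the death, and the accompanying stop event is marked with cause `"united"`
so the audit does not double-count it.

## Scheduling

Execution is synchronous. One call to `step()` fires every transition once,
in the net's declared order, then advances the clock. A token moved or
created during tick t is frozen until tick t+1, so a token never crosses two
transitions within one tick. For the foreign-object net the declared order
is En0, En1, I₁…I_m, S, S₁…S_n, O₁…O_p, En2.

This convention was chosen over event-queue scheduling because it is
deterministic, hand-traceable (every latency below can be derived on paper),
and faithful to the reduced formalism, which has no transition durations or
priorities to order concurrent firings. The cost is that per-tick latency
depends on the declared transition order; that order is therefore part of
the model definition, not an implementation detail.

When a token's condition row has no enabled column, the token simply stays
where it is and nothing is recorded — the formalism defines no drop rule.
The one exception is the routing transition En1: a stimulus no receptor
registers stays at the boundary place and raises a one-time warning
(`fop_unrouted_stimulus`), because a silently stuck stimulus is almost
always a configuration mistake.

## The foreign-object net

The net models a system that functions by accepting foreign objects from
its environment and emitting objects back into it. `build_fop_net()`
constructs, for m receptors, n processing components and p effectors:

* environment transitions **En0** (stimuli enter; total reactions are
  absorbed), **En1** (routing to receptors), **En2** (effector outputs
  unite into one total-reaction token);
* one receptor transition **I_k** per receptor, holding a threshold token
  whose newest `threshold` record gates passage;
* the system core **S**, holding the permanent status token around which
  all registration and dispatch happens;
* one component transition **S_k** with a processing delay;
* one effector transition **O_k** with an emission delay.

Enumerating the built object gives m+n+p+4 transitions and
4m + 3(n+p+1) + 1 places, and exactly six declared token roles regardless of
size: the environment token, impact tokens, the system status token,
effector tokens, threshold tokens, and threshold-control tokens. (Five more
tags — the processing, reaction, response, output and total-reaction tokens —
arise as split products at run time; they are stages of the six roles'
information, not independently seeded types.)

Several wiring details are not forced by the net's verbal description and
are fixed here as package conventions, flagged with comments at the
construction site:

* **Initial placement.** The environment token starts in e₀, the status
  token in s, each threshold token in its receptor's loop place, each
  effector token in its effector's loop place — these are the tokens the
  model describes as permanently resident there.
* **Stimulus entry.** The environment token never leaves e₀; it *splits*
  one impact token per pending stimulus into e₁. It must persist because the
  total reaction later unites with it.
* **Loop arcs.** The self-loops on e₀ and the receptor/component/effector
  loop places have stay semantics: resident tokens remain without events;
  the readiness predicates gate only the split-out arcs.
* **Two-phase system core.** Within one firing of S, arriving impact and
  response tokens first unite into the status token, and only then is the
  status token's own row evaluated, so dispatch decisions see the updated
  registrations. This is realized purely by input order: the place s is the
  last input of S.
* **Aggregation without a barrier.** En2 unites whatever effector-output
  tokens are present at the tick it fires; it does not wait for all p
  effectors. Responses processed with unequal delays therefore emit as
  separate total reactions.
* **Threshold control.** A threshold change is never applied directly: the
  core splits a control token into the receptor's control place, and at the
  receptor's next firing that token unites with the threshold token,
  whose newest record then holds the validated new value
  (`threshold_update()` rejects negative or non-finite proposals). Within
  one receptor firing the impact row is evaluated *before* the control row,
  so an update takes effect from the following evaluation on.

## Parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `initial_thresholds` | strength | 3.0 per receptor | a stimulus passes only if strictly greater |
| `processing_delays` | ticks | 1 per component | time from intake to ready response |
| `effector_delays` | ticks | 1 per effector | time from receipt to emission |
| `routing` | — | everything → receptor 1 | modality → receptor map (`"*"` catch-all) |
| `component_policy` | — | everything → component 1 | registered impact → component |
| `effector_policy` | — | everything → effector 1 | response → effector |
| `adaptation` | — | `rule = "none"` | threshold feedback (below) |

Threshold comparison is **strict**: equality routes to the sub-threshold
branch. The same strictness is used by the threshold gate of the abstract
impact–reaction model, so the two formalizations agree at the boundary.

The default one-receptor/one-component/one-effector routing makes each
stimulus produce at most one total reaction, which keeps response counting
conservative (responses ≤ supra-threshold stimuli) and hand-checkable.
Broadcast policies are expressible through the maps but are not the default.

**Adaptation.** The formalism only says *that* a threshold-change predicate
exists, not what triggers it; the trigger is therefore a configuration
choice, not an interpretation claim. Under the multiplicative rule, each
trigger scales the receptor's threshold by γ: after j triggers the threshold
is θ₀·γʲ. The trigger may be every registered impact (the default used by
the chronic-pain scenario: both sub- and supra-threshold registrations
count), only sub-threshold ones, or only supra-threshold ones. Outstanding
triggers are batched into a single control token carrying θ·γ^(outstanding),
so the trajectory is identical whether updates are applied one at a time or
in bursts.

## Scenarios and what the hand traces pin down

With unit delays the acute-reflex path — boundary, routing, receptor,
core, component intake, component readiness, core again, effector intake,
effector readiness, aggregation — takes nine ticks from stimulus to total
reaction, derivable on paper from the scheduling convention; the shipped
fixture `pain_reflex_hand_trace.json` records that derivation and the test
suite holds the engine to it exactly. Latency is independent of
supra-threshold strength and stretches by one tick per extra tick of
processing delay.

The chronic-pain scenario fixes θ₀ = 3.0, γ = 0.8 and a constant stimulus
strength 2.5 every 15 ticks. Since 3.0·0.8 = 2.4 < 2.5, the first stimulus
is unanswered and hypersensitivity begins exactly at the second — the
trajectory 3.0, 2.4, 1.92, 1.536, 1.2288 is the closed form θ₀·γʲ. The
period of 15 ticks is deliberately longer than the 9-tick reflex plus the
2-tick control-token round trip, so consecutive stimuli never interleave;
shortening the period below that makes threshold updates land mid-flight,
which is legitimate dynamics but no longer hand-checkable.

The exchange scenario routes three intake modalities (food, drink, oxygen)
through three distinct receptors into two internal components and out
through three distinct effectors, with stimuli drawn by the bundled
generator. All scenario magnitudes are package defaults chosen for legible
hand traces, and every one can be overridden through the scenario config.

## The stimulus generator

`generate_stimuli()` draws per-tick stimulus counts from a Poisson
distribution, strengths uniformly within bounds, and modalities from stated
weights, all from one seeded generator — hooks may not create their own
entropy, which is what makes `run` traces byte-identical under equal seed.
It emulates an environment with memoryless arrivals and stationary
intensity. It does **not** emulate temporally correlated stimulation,
strength drift, refractory periods, or modality bursts; passing tests
therefore demonstrate the net's bookkeeping and threshold logic under
stationary load, not robustness to realistic physiological input
statistics.

## Numerical and degenerate-input choices

* Ticks are integers; there is no continuous time. The abstract
  impact–reaction model (`simulate_simplified()` / `simulate_complex()`)
  runs on the same integer scale; its two event streams are merged
  chronologically, and at equal time-moments the system-side entry is
  processed first — the formal model leaves this interleaving open, so the
  merge order is recorded as a package convention.
* A time-advance hook that fails to advance raises an error instead of
  looping forever.
* Tie-breaks everywhere follow declared order: a token with several enabled
  carrying arcs takes the first in column order; input places are scanned
  in declared order; trace events are sequence-numbered densely.
* Running a net for zero ticks is valid and yields an empty trace.
* An empty stimulus train, an empty input place, a unite with no resident
  host (the arriving token becomes the resident) are all defined, tested
  behaviours rather than errors.

The test suite's problem sizes — nets up to (4, 4, 4), 200 seeded trains of
roughly three stimuli each for the exclusivity property, 100 random small
nets against a brute-force firing reference, 50 random impact specifications
for the gate-free limit — were chosen so the full suite completes in well
under a minute while still exercising every branch of the token lifecycle;
the properties they check are size-independent invariants, so larger sizes
add cost, not coverage.

## Known limitations

* Predicate truth is strictly Boolean; graded or fuzzy signal evaluations
  are out of scope.
* Single system vs environment only: composing several foreign-object
  systems into a supersystem is not supported.
* Responses have occurrence and latency but no magnitude semantics, so
  summaries report counts and ticks, not amplitudes.
* Place capacities are unbounded and transitions have no priorities or
  multi-tick durations (the reduced formalism omits them by design).
* The engine is pure R and tuned for traceability, not throughput; it is
  comfortable at thousands of events per run, not millions.
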