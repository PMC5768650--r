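---
title: "Benchmarking asynchronous BCIs with a simulated obstacle race"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking asynchronous BCIs with a simulated obstacle race}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcirace)
```

## The benchmark and why simulation

An asynchronous brain-computer interface (BCI) is one the user may engage
at any moment, which means its hardest requirement is a reliable *idle*
state: most of the time the right output is no output at all. The
obstacle-race benchmark encodes this directly. A track consists of
no-input fields, where any command is penalized, and three kinds of action
field, each with a single correct command (`rotate`, `jump`, `slide`) that
is rewarded with speed. The only outcome measure is time to the finish
line: it folds accuracy, responsiveness and false-positive restraint into
one number that laypeople and reviewers alike can read.

A live competition runs each layout once, with humans in the loop, and a
~3-minute race is vulnerable to luck. This package replaces the live race
with a deterministic simulator plus parametric pilot models, so that the
relationship between classifier quality and race time becomes an object
one can compute: distributions over hundreds of races, break-even
accuracies, and the effect of strategy parameters.

## Game dynamics

The avatar's speed is a function of its *speed state* — `default`,
`reward`, or `penalty` — and the kind of field it is on, yielding four
realized speeds that every valid parameter set must order as

\[ s_{\mathrm{reward,Action}} > s_{\mathrm{default,NoInput}} >
   s_{\mathrm{default,Action}} > s_{\mathrm{punish,NoInput}} =
   s_{\mathrm{punish,Action}}. \]

The regulation values are 3, 1, 0.5 and 0.3 with a 4 s cap on the
no-input penalty (`validate_params()` enforces the chain; the punish-speed
equality can be relaxed via `strict = FALSE` for design exploration
only). State changes on command receipt:

* action field, correct command → `reward` (re-sending it is idempotent);
* action field, wrong command → `penalty`; reward and penalty override
  each other freely within the field;
* no-input field, any command → `penalty` with the timer (re)set to its
  4 s maximum — penalties restart rather than stack, reading the
  "maximum penalty time" as a per-offense cap;
* both action-field states last until the field ends; the no-input
  penalty ends when its timer expires.

Crossing into a new field always resets the state to `default` and
cancels any pending timer, including a no-input penalty that would have
outlasted the field. Whether the original game let such a penalty spill
across the boundary is not documented; truncation is the simpler rule and
is the one implemented, so worst-case no-input behaviour here is mildly
optimistic.

### Units and calibration

The no-input default speed defines the unit system (1 track-unit per
second), matching the percentage phrasing of the other speeds. Field
lengths are nowhere stated; they are calibrated from the stated silent
crossing times, treated as exact: 6 s × 1 unit/s = 6 units for a no-input
field and 11 s × 0.5 units/s = 5.5 units for an action field. Those
crossing times are given as approximate ("about 6 s"), so the calibration
is an assumption — but it is the unique one that reproduces every stated
timing, and all derived numbers (156 s silent regulation race, 46 s
perfect race) follow from it.

## The event-driven engine and its oracle

`simulate_race()` integrates the piecewise-constant motion exactly: the
only events are command arrivals, penalty expiries and field-boundary
crossings, and between events position is linear in time. All arithmetic
is double precision with no rounding of event times; the finish is the
exact boundary crossing of the last field. Ties are resolved boundary
first, then penalty expiry, then command, so a command arriving exactly
at a boundary applies to the field being entered. Event times within
1 ns are treated as simultaneous: boundary times are *derived* quantities
(recomputed from the anchor of the last state change), and two runs of
the same race that pause at different places — the closed-loop
co-simulation pauses at every agent decision — could otherwise resolve an
exact tie in opposite directions. For the same reason the engine advances
positions from per-event anchors rather than from pause points, which
makes a closed-loop run and an open-loop replay of its emitted log
bit-identical, a property the test suite asserts.

`simulate_race_stepped()` is a deliberately different implementation of
the same rules used as a cross-check: a compiled forward time-marching
integrator with steps of at most `dt`, steps additionally capped at
command times and penalty expiries, and boundary crossings located by
linear interpolation within a step. The suite fuzzes 1,000+ random
(track, log) pairs and requires agreement within 2 ms at `dt` = 1 ms.

### A non-obvious property of the dynamics

Penalties are locally monotone: appending an incorrect command after all
other logged commands can only slow the race, and delaying the sole
correct command on an action field never helps (both fuzz-tested).
But inserting an incorrect command *between* fixed-time commands is not
monotone in general: the slowdown it causes can shift a later command
onto the field where that command is correct, and the reward can outweigh
the penalty. The test suite carries a two-field counterexample (a lone
`rotate` that lands wrong at 29 s total; adding an earlier wrong `slide`
re-aligns it and finishes in 23.2 s). This is a real feature of
override-based scoring, worth knowing when reasoning about replayed logs;
closed-loop pilots, which react to the field they are actually on, are
unaffected.

## Observation and preview

Agents observe the current field, speed state, distance to the field end,
and the upcoming field kinds within the preview window. The lookahead
distance is `preview_horizon × s_reward_action` (30 units under the
regulation set): scaling by the *maximum* speed is the only choice that
keeps the "seen at least 10 s before arrival" guarantee for every pilot,
since a window scaled by the current speed can be outrun after a
speed-up. Fields already visible at the start of the race are seen as
early as the race allows; for every later field the suite verifies the
10 s guarantee on both the slowest and the fastest trajectories. Agents
never receive information beyond the window (also asserted).

## Pilot models

* `silent_agent()` — never sends; the guaranteed-finish baseline (156 s).
* `spam_agent(period)` — a uniformly random command every `period`
  seconds; the strategy the reward/penalty structure is meant to punish.
* `oracle_agent(latency)` — the correct command exactly `latency` seconds
  after entering each action field, silence elsewhere; the performance
  ceiling for a given reaction time (46 s at zero latency).
* `classifier_agent(profile)` — the BCI model. At each decision tick the
  pilot forms an intent (rest on no-input fields, rest after the reward
  has been secured, otherwise the field's correct command if it is in the
  pilot's command subset) and emits a sample from that intent's row of a
  4×4 confusion matrix over (rotate, jump, slide, none); emissions reach
  the game after `latency` seconds. The rest row is the sole source of
  no-input false positives, matching the asynchronous framing in which
  idling is itself a classifier state. `command_subset` models two-class
  entrants that use a single command.

Decision ticks restart at each field entry (first tick `entry_delay`
seconds after entry, then every `decision_period`). Tick-on-entry is what
makes the degenerate checks exact: an identity-confusion pilot emits at
field entry precisely like the zero-latency oracle, and the suite
requires those finish times to be bit-identical (as it does for the
all-`none` pilot versus silence). The default `decision_period` of 0.5 s
reflects typical sub-second asynchronous update rates; no canonical value
exists, so it is an explicit profile parameter. The intent policy itself
is one plausible strategy, not an observed one — real pilots' strategies
were not recorded — and `entry_delay` / `command_subset` expose the
obvious strategy axes.

Sampling uses inversion on a single uniform draw per tick, so runs with
the same seed stay coupled across different confusion matrices — the
common-random-numbers device that makes accuracy sweeps and the
break-even search low-noise.

## Benchmarking layer

`monte_carlo()` runs `n_races` closed-loop races and summarizes the
finish-time distribution (mean, sd, 5/50/95% quantiles, mean incorrect
commands). A master seed deterministically spawns one race seed and one
track-shuffle seed per race, so identical inputs give identical
summaries; the track policy is either a fixed track or a fresh regulation
shuffle per race. `race_metrics()` extracts the per-race command metrics:
the incorrect-command count, the per-action-field time to the first
correct command, and the correction time, defined here as first correct
minus the *last* preceding incorrect command on that field (the phrase
"time to correct an incorrect command" does not pin down which incorrect
command when several pile up; the most recent one measures the recovery
the pilot actually performed).

`breakeven_accuracy()` bisects the one-parameter accuracy family
(`accuracy_profile()`: diagonal accuracy with the residual split over the
two wrong commands, rest row with a `rest_none` mass) for the smallest
accuracy whose mean finish ties the silent baseline, using the same
spawned seeds at every evaluation. With the illustrative default rest row
(5% false-positive mass) the crossing lies *below* the 1/3 accuracy
floor — even a chance-level classifier beats silence, because 12 of 16
fields reward any correct hit and geometric retry at 2 ticks/s is fast —
and the search reports `below_range` rather than inventing a number.
Heavier false-positive rows move the crossing inside (or above) the
interval; the status field distinguishes the three outcomes.

`ordering_report()` benchmarks named agents on common seeds and reports
the empirical ordering by mean finish. The claim that silence beats
random spamming is treated as an empirical question, not an assertion:
with 12 of 16 fields being action fields, a spam command is correct with
probability 1/3 most of the time, so the claim is rate- and
composition-dependent. The suite exercises spam periods of 0.5, 1, 2 and
5 s on the regulation composition and reports the resulting means; on a
pure no-input track silence wins by construction (6 versus 20 s per
field), which the suite does assert.

## Problem sizes and determinism

The shipped tests use desk-scale sizes chosen to make their statistical
checks decisive: 1,000 fuzz cases for each engine property, 200 races per
accuracy for the monotone-in-accuracy check, 40–100 races per agent for
ordering and error-scaling checks. Every stochastic path is seeded —
track shuffles, agent randomness, seed spawning — and nothing reads a
global RNG without restoring it, so the whole suite and the acceptance
script are reproducible run to run.

## Known limitations

* The confusion-matrix pilot is stationary: no fatigue, learning, or
  error-related adaptation, and its false positives are i.i.d. per tick,
  which understates the burstiness of real artifacts.
* Field lengths rest on the 6 s / 11 s calibration assumption above.
* Cross-boundary penalty truncation is a modeling choice where the source
  material is silent.
* Multi-pilot races are independent single-avatar runs (the real game has
  no avatar interaction), so audience-facing phenomena like mid-race
  rank dynamics are out of scope, as are EEG signal simulation and
  classifier training.
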