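# bcirace

Deterministic simulation and Monte-Carlo benchmarking of the obstacle-race
game used to benchmark asynchronous brain-computer interfaces (BCIs).

## The problem

Asynchronous BCIs must do two things well: emit the right command at the
right moment, and emit *nothing* the rest of the time. The racing-game
benchmark captures both. An avatar runs along a track of 16 fields — four
*no-input* fields, where any command is penalized, and four instances each
of three *action* fields (spinning winds / stumbling blocks / sticky
lasers), where exactly one command (`rotate` / `jump` / `slide`) speeds the
avatar up and anything else slows it down. The single performance measure
is the time to the finish line: a pilot who never sends a command still
finishes, a good pilot finishes much faster, and an erratic one can finish
slower than silence.

`bcirace` re-implements the race as an exact event-driven simulator plus a
benchmarking layer, so that the mapping from BCI quality parameters
(accuracy, decision rate, latency, false-positive rate) to race-time
distributions can be studied in the thousands of repetitions a live
competition cannot run.

## The model

The avatar moves at a piecewise-constant speed determined by its speed
state (default / reward / penalty) and the field it is on. With the
regulation parameter set the speeds obey

```
s_reward,Action (3)  >  s_default,NoInput (1)  >  s_default,Action (0.5)
                     >  s_punish,NoInput = s_punish,Action (0.3)
```

in track-units per second, with the no-input default defining the unit. A
correct command on an action field enters the reward state; a wrong one
enters the penalty state; each overrides the other; both last to the end
of the field. Any command on a no-input field triggers the penalty for (at
most) `t_maxPunish,NoInput` = 4 s. Field lengths are calibrated from the
published silent crossing times — 6 s for a no-input field, 11 s for an
action field — giving 6.0 and 5.5 units. Upcoming fields are visible to
the pilot at least 10 s before arrival.

The engine integrates this motion exactly, event by event (commands,
penalty expiries, boundary crossings), and a compiled time-stepped
integrator serves as an independent cross-check. Pilot models range from
baselines (silent, random spam, zero/fixed-latency oracle) to a
confusion-matrix classifier pilot: a 4×4 row-stochastic matrix from intent
(rotate/jump/slide/rest) to emission (rotate/jump/slide/none) sampled at
discrete decision ticks, with latency, entry-delay and command-subset
strategy parameters.

## Worked example

```r
library(bcirace)
p   <- default_params_2016()
trk <- regulation_track(p, seed = 7)

simulate_race(trk, p)$finish_time                            # silent pilot
# [1] 156
run_closed_loop(oracle_agent(0), trk, p, seed = 1)$result$finish_time
# [1] 46

pr  <- accuracy_profile(0.8, rest_none = 0.95)   # 80% accurate, 5% false positives
mc  <- monte_carlo(classifier_agent(pr), "regulation", p,
                   n_races = 200, master_seed = 1)
mc
# Benchmark over 200 races: mean finish 55.148 s (sd 4.934)
#   quantiles 5/50/95%: 48.250 / 54.367 / 64.543 s
#   mean incorrect commands per race: 7.69
```

The silent pilot needs 4×6 + 12×11 = 156 s; a perfect zero-latency pilot
needs 4×6 + 12×(5.5/3) = 46 s; the 80%-accurate classifier pilot lands in
between, its spread and its ~7.7 incorrect commands per race quantifying the
price of misclassification. `race_metrics()` breaks a single race down
further (incorrect-command count, time to the first correct command per
action field, wrong-to-correct correction time), `breakeven_accuracy()`
bisects for the accuracy at which a classifier ties the silent baseline,
and `ordering_report()` compares agents on common seeds. A command-line
interface (`exec/bcirace`, subcommands `track-gen`, `simulate`, `replay`,
`metrics`, `benchmark`, `breakeven`, `ordering`) wraps the same functions
for shell use.

See the vignette in `vignettes/race-benchmarking.Rmd` for the model
details, numerical conventions and design choices.

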