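# Shared fixtures: the regulation parameter set and small random-case
# generators used by the property-style tests.

p2016 <- default_params_2016()

# random track of 2-8 fields (any kinds)
rand_track <- function(params = p2016, nf = sample(2:8, 1)) {
  race_track(sample(field_kinds(), nf, replace = TRUE), params)
}

# random command log with times spread over the slowest plausible crossing
rand_log <- function(track, params = p2016, n = sample(0:10, 1)) {
  tmax <- 0.8 * track$total_length / params$s_punish_noinput
  command_log(sort(stats::runif(n, 0, tmax)),
              sample(commands(), n, replace = TRUE))
}
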