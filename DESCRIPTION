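Package: bcirace
Title: Event-Driven Simulation and Benchmarking of Asynchronous BCI Racing Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A deterministic, event-driven simulator of the obstacle-race game
    used to benchmark asynchronous brain-computer interfaces (BCIs), in which an
    avatar crosses a track of no-input and action fields and timestamped
    rotate/jump/slide commands trigger reward, penalty and override speed
    dynamics.  Includes pluggable pilot-agent models (silent, random spam,
    oracle, and a confusion-matrix classifier pilot), closed-loop co-simulation,
    Monte-Carlo benchmarking of race-time distributions, break-even accuracy
    search, and per-race command metrics (incorrect commands, time to correct
    command, correction time).  File formats (command-log CSV, track and race
    JSON, flat parameter files) and a command-line interface are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
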