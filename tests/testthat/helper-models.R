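# Shared fixtures: converged default pre/post simulations are expensive
# enough to be worth computing once per test run.

.cache <- new.env(parent = emptyenv())

cached_pre_sim <- function() {
  if (is.null(.cache$pre)) {
    .cache$pre <- run_to_periodicity(default_network())
  }
  .cache$pre
}

cached_post_sim <- function() {
  if (is.null(.cache$post)) {
    m <- default_network()
    m$junction <- apply_endograft(m$junction)
    .cache$post <- run_to_periodicity(m)
  }
  .cache$post
}

cached_scenario <- function() {
  if (is.null(.cache$scenario)) {
    .cache$scenario <- default_scenario(seed = 42, sim = cached_pre_sim())
  }
  .cache$scenario
}

# trapezoidal cycle mean, duplicated here so tests do not depend on
# package internals
tmean <- function(t, x) {
  n <- length(t)
  sum((x[-1] + x[-n]) * diff(t)) / 2 / (t[n] - t[1])
}
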