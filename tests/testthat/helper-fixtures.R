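# shared, lazily computed fixtures: steady runs are cached per test session
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

steady_preset <- function(name, configuration = "BVFS", ...) {
  key <- paste("steady", name, configuration, sep = "_")
  cached(key, {
    p <- mcl_preset(name, configuration = configuration)
    p <- configure_ecmo(p, enabled = FALSE)
    find_steady_state(p, ...)
  })
}

# a small, fast parameter set used by unit tests (default circuit, short runs)
unit_params <- function(configuration = "BV") {
  set_configuration(mcl_preset("normal"), configuration)
}

random_state <- function(params, seed) {
  set.seed(seed)
  s <- params$initial_state
  s[1:4] <- s[1:4] * runif(4, 0.8, 1.2)
  s[5:8] <- s[5:8] + runif(4, -15, 15)   # keep air columns positive
  s[["q_ecmo"]] <- runif(1, -20, 80)
  s
}
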