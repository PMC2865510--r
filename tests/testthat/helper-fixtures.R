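# shared fixtures, built once per test run

fixture_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- hsc_reporter_library()
    cache
  }
})

# full triad fitted from the packaged reporter table with auto-chosen K
fixture_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_triad(fixture_table())
    cache
  }
})

# a hand-specified Scl+19 model with simple weights for arithmetic checks
toy_scl19 <- function(K = 100) {
  enhancer_model("scl19", c(G = 2, FF = 3, G.FF = 5), K = K)
}

# brute-force two-level partition oracle: enumerate {closed} and
# {open x (empty + bound configurations)} x {promoter empty, polymerase}
# explicitly, with polymerase weight p -> 0 (weak promoter binding), and
# return the reporter fold enhancement over the enhancerless construct
brute_force_fold <- function(model, state, p = 1e-9) {
  cf <- model$configurations
  openZ <- 1 + sum(cf$weight * state[1]^cf$scl * state[2]^cf$gata2 *
                     state[3]^cf$fli1)
  rate <- function(oz) (p * oz) / ((model$K - 1) + (1 + p) * oz)
  rate(openZ) / rate(1)
}

# attractors by long forward integration from scattered starts (an
# integration-only oracle, independent of the Newton-based search)
basin_attractors <- function(params, signal = signal_input(), n_starts = 25,
                             seed = 1) {
  set.seed(seed)
  starts <- matrix(10^runif(3 * n_starts, -4, 1), ncol = 3)
  ends <- apply(starts, 1, function(x0) {
    tr <- integrate_triad(params, x0, signal, horizon = 600, n_out = 5)
    as.numeric(utils::tail(tr, 1)[, c("x_s", "x_g", "x_f")])
  })
  ends <- t(ends)
  keep <- list()
  for (i in seq_len(nrow(ends))) {
    x <- ends[i, ]
    if (!length(keep) ||
        !any(vapply(keep, function(k)
          max(abs(log(k + 1e-8) - log(x + 1e-8))) < 0.05, logical(1)))) {
      keep <- c(keep, list(x))
    }
  }
  keep
}
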