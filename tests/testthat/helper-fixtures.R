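# Shared fixtures, built once per test run and memoized.

.kc_fix <- new.env(parent = emptyenv())

fix_memo <- function(key, expr) {
  if (is.null(.kc_fix[[key]])) .kc_fix[[key]] <- force(expr)
  .kc_fix[[key]]
}

fix_params <- function() fix_memo("params", default_gen_params())

fix_stimuli <- function() fix_memo("stimuli", {
  make_stimulus_set(fix_params(), seed = 101)
})

fix_design <- function() fix_memo("design", {
  make_design(design_spec(seed = 102), fix_stimuli())
})

fix_control_session <- function() fix_memo("ctl_session", {
  simulate_observer(observer_preset("control", fix_params()),
                    fix_design(), fix_stimuli(), seed = 103,
                    observer_id = "ctl01")
})

fix_patient_session <- function() fix_memo("pat_session", {
  simulate_observer(observer_preset("patient", fix_params()),
                    fix_design(), fix_stimuli(), seed = 104,
                    observer_id = "pat01")
})

# Brute-force oracle for the unregularized logistic likelihood on tiny
# instances: iterative grid refinement over (intercept, beta).
brute_logistic <- function(X, y, span = 8, iters = 8, pts = 11) {
  X <- as.matrix(X); y <- as.numeric(y)
  p <- ncol(X) + 1L
  centre <- numeric(p)
  width <- rep(span, p)
  nll <- function(b) {
    eta <- b[1] + as.vector(X %*% b[-1])
    -sum(y * eta - log1p(exp(eta)))
  }
  for (it in seq_len(iters)) {
    grids <- lapply(seq_len(p), function(j)
      seq(centre[j] - width[j], centre[j] + width[j], length.out = pts))
    best <- Inf; best_b <- centre
    idx <- rep(1L, p)
    repeat {
      b <- vapply(seq_len(p), function(j) grids[[j]][idx[j]], numeric(1))
      v <- nll(b)
      if (v < best) { best <- v; best_b <- b }
      j <- 1L
      while (j <= p) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= pts) break
        idx[j] <- 1L; j <- j + 1L
      }
      if (j > p) break
    }
    centre <- best_b
    width <- width * 2.2 / (pts - 1)  # shrink around the best grid point
  }
  list(intercept = centre[1], beta = centre[-1], nll = nll(centre))
}
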