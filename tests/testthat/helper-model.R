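# One shared model instance for the whole suite (polynomial fit is the
# expensive part); tests that need a modified model copy and edit it.
the_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- hop_model()
    m
  }
})

# finite-difference second derivative with shrinking steps; returns the
# sequence of estimates so tests can check convergence
fd_second <- function(f, x, steps = c(1e-2, 1e-3, 1e-4)) {
  vapply(steps, function(h) (f(x + h) - 2 * f(x) + f(x - h)) / h^2, numeric(1))
}

expect_c2 <- function(f, x, tol_rel = 0.05, steps = c(1e-2, 1e-3, 1e-4)) {
  d2 <- fd_second(f, x, steps)
  expect_true(all(is.finite(d2)))
  # estimates stabilise as the step shrinks (no jump/kink at x)
  if (abs(d2[3]) > 1e-3) {
    expect_lt(abs(d2[2] - d2[3]) / max(abs(d2[3]), 1e-8), tol_rel)
  } else {
    expect_lt(abs(d2[2] - d2[3]), 1e-2)
  }
}

# smooth periodic test trajectory over all coordinates
smooth_traj <- function(model, times, amp = 0.2) {
  nq <- length(model$coordinates)
  freq <- seq(0.7, 1.3, length.out = nq)
  phase <- seq(0, pi, length.out = nq)
  base <- c(0, 1.0, 0, 0, 0.4, -0.8, 0.2)
  q <- sapply(seq_len(nq), function(j) base[j] + amp * sin(2 * pi * freq[j] * times + phase[j]))
  qd <- sapply(seq_len(nq), function(j) amp * 2 * pi * freq[j] * cos(2 * pi * freq[j] * times + phase[j]))
  qdd <- sapply(seq_len(nq), function(j) -amp * (2 * pi * freq[j])^2 * sin(2 * pi * freq[j] * times + phase[j]))
  list(q = q, qd = qd, qdd = qdd)
}
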