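# Independent oracles, coded from scratch against the model equations and
# kept deliberately separate from the package implementation.

# Hand-coded explicit-Euler recurrence for the two-compartment ion/turgor
# model. `trigger_at(t)` supplies the excitation flag per step.
oracle_euler <- function(n_steps, trigger_at,
                         alpha = 15, v_excited = -60, v_rest = -170,
                         k = 1, beta = 0.01, rtf = 25, dt = 0.05,
                         k_cell = 100, k_apo = 1, a_cell = 100, a_apo = 1) {
  v0 <- rtf * log(k_apo / k_cell) - v_rest
  rt_bar <- (rtf / 1000) * 96485 / 1e5
  dp <- rt_bar * ((k_cell + a_cell) - (k_apo + a_apo))
  out <- matrix(NA_real_, n_steps + 1, 6)
  colnames(out) <- c("t", "k_cell", "k_apo", "a_cell", "a_apo", "dp")
  out[1, ] <- c(0, k_cell, k_apo, a_cell, a_apo, dp)
  for (i in seq_len(n_steps)) {
    trig <- trigger_at((i - 1) * dt)
    e_k <- rtf * log(k_apo / k_cell)
    j <- k * (v_excited - e_k) * trig +
      min(0, k * beta * (v_rest - e_k + v0)) * (1 - trig)
    k_cell <- k_cell - j * dt
    k_apo <- k_apo + j * dt / alpha
    a_cell <- a_cell - j * dt
    a_apo <- a_apo + j * dt / alpha
    dp <- dp - 2 * rt_bar * (alpha + 1) / alpha * j * dt
    out[i + 1, ] <- c(i * dt, k_cell, k_apo, a_cell, a_apo, dp)
  }
  out
}

# Entropy/Q oracle: direct formula evaluation for a single expression vector.
oracle_entropy <- function(e, pseudocount = 0) {
  p <- (e + pseudocount) / sum(e + pseudocount)
  h <- -sum(ifelse(p > 0, p * log2(p), 0))
  list(H = h, Q = h - log2(p))
}

# Default parameter set shared across tests.
default_params <- function(...) ap_params(...)
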