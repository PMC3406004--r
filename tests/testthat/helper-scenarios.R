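# Shared scenario shortcuts and an independent fixed-step integrator.

ref_params <- function() reference_pk_parameters()

# the generating truth as a named vector in coef() order
ref_truth <- function() {
  p <- reference_pk_parameters()
  c(V_p = p$V_p, V_b = p$V_b, K_pb = p$K_pb, K_bp = p$K_bp)
}
wt <- function(E = 0.035) reference_enzyme("wtBChE", E)
coch3 <- function(E = 0.035) reference_enzyme("CocH3", E)

# Hand-rolled classical 4th-order Runge-Kutta at a fixed step: the
# brute-force oracle against which the adaptive solver is checked. Kept
# deliberately independent of the package's deSolve path.
rk4_simulate <- function(C1_0, params, enzyme, t_end, dt = 0.001) {
  f <- function(y) {
    elim <- enzyme$v_max * y[1] / (enzyme$K_M + y[1])
    c(-elim - params$K_pb * y[1] + params$K_bp * y[2],
      (params$V_p / params$V_b) * (params$K_pb * y[1] - params$K_bp * y[2]))
  }
  n <- ceiling(t_end / dt)
  out <- matrix(NA_real_, n + 1L, 3L)
  y <- c(C1_0, 0)
  out[1L, ] <- c(0, y)
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1L, ] <- c(i * dt, y)
  }
  colnames(out) <- c("t", "C1", "C2")
  out
}
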