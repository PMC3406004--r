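#' Model right-hand side
#'
#' Instantaneous rates of change of the plasma (`C1`) and brain (`C2`)
#' cocaine concentrations. Plasma loses drug to enzymatic
#' Michaelis-Menten elimination and exchanges with brain by first-order
#' diffusion across the blood-brain barrier; brain only exchanges:
#' \deqn{dC_1/dt = -V_{max} C_1/(K_M + C_1) - K_{pb} C_1 + K_{bp} C_2}
#' \deqn{dC_2/dt = (V_p/V_b)(K_{pb} C_1 - K_{bp} C_2)}
#' The \eqn{V_p/V_b} factor makes the exchange conserve amount:
#' \eqn{V_p \cdot dC_1^{exch} + V_b \cdot dC_2 = 0}.
#'
#' @param C1,C2 plasma and brain concentrations, uM (scalars or equal
#'   length vectors); must be nonnegative.
#' @param params a [pk_parameters()] object.
#' @param enzyme an [enzyme_kinetics()] object.
#' @return A list with components `dC1` and `dC2`, uM/min.
#' @examples
#' pk_rhs(1, 0, reference_pk_parameters(), reference_enzyme("wtBChE"))
#' @export
pk_rhs <- function(C1, C2, params, enzyme) {
  stopifnot(inherits(params, "pk_parameters"), inherits(enzyme, "enzyme_kinetics"))
  if (any(!is.finite(C1)) || any(!is.finite(C2)) || any(C1 < 0) || any(C2 < 0))
    stop("concentrations must be finite and nonnegative")
  elim <- enzyme$v_max * C1 / (enzyme$K_M + C1)
  dC1 <- -elim - params$K_pb * C1 + params$K_bp * C2
  dC2 <- (params$V_p / params$V_b) * (params$K_pb * C1 - params$K_bp * C2)
  list(dC1 = dC1, dC2 = dC2)
}

# deSolve-facing derivative function; p is the flat numeric parameter vector.
.ode_rhs <- function(t, y, p) {
  C1 <- y[1L]; C2 <- y[2L]
  elim <- p[["vmax"]] * C1 / (p[["KM"]] + C1)
  list(c(-elim - p[["Kpb"]] * C1 + p[["Kbp"]] * C2,
         (p[["Vp"]] / p[["Vb"]]) * (p[["Kpb"]] * C1 - p[["Kbp"]] * C2)))
}

.flat_params <- function(params, enzyme) {
  c(Vp = params$V_p, Vb = params$V_b, Kpb = params$K_pb, Kbp = params$K_bp,
    vmax = enzyme$v_max, KM = enzyme$K_M)
}

#' Paired plasma/brain time course
#'
#' Container for a simulated or observed concentration time course:
#' a strictly increasing time grid starting at 0 (min), the plasma series
#' `C1` and the brain series `C2` (uM).
#'
#' @param t time grid, min.
#' @param C1,C2 plasma and brain concentrations, uM.
#' @return A data frame of class `"pk_timecourse"` with columns
#'   `t`, `C1`, `C2`.
#' @export
pk_timecourse <- function(t, C1, C2) {
  if (length(t) != length(C1) || length(t) != length(C2))
    stop("t, C1, C2 must have equal lengths")
  if (length(t) < 1L || t[1L] != 0 || any(diff(t) <= 0))
    stop("'t' must be strictly increasing and start at 0")
  if (any(C1 < 0) || any(C2 < 0))
    stop("concentrations must be nonnegative")
  structure(data.frame(t = t, C1 = C1, C2 = C2),
            class = c("pk_timecourse", "data.frame"))
}

#' @export
print.pk_timecourse <- function(x, ...) {
  cat(sprintf("<pk_timecourse> %d points on [0, %g] min; C1 peak %.4g uM, C2 peak %.4g uM\n",
              nrow(x), max(x$t), max(x$C1), max(x$C2)))
  invisible(x)
}

#' @export
plot.pk_timecourse <- function(x, log = "", ...) {
  graphics::matplot(x$t, cbind(x$C1, x$C2), type = "l", lty = 1,
                    col = c("red3", "black"), xlab = "time (min)",
                    ylab = "concentration (uM)", log = log, ...)
  graphics::legend("topright", c("plasma C1", "brain C2"),
                   col = c("red3", "black"), lty = 1, bty = "n")
  invisible(x)
}

#' Simulate the two-compartment model
#'
#' Integrates the coupled plasma/brain equations for an intravenous bolus
#' (`C2(0) = 0`) with a stiff-capable adaptive solver (lsoda) at tight
#' default tolerances; high-activity enzymes at high dose collapse plasma
#' within a minute, so stiffness handling matters. Tiny negative solver
#' undershoot is clipped to zero (with a warning if it exceeds
#' `1e3 * atol` in magnitude).
#'
#' @param spec a [sim_spec()].
#' @param params a [pk_parameters()] object.
#' @param enzyme an [enzyme_kinetics()] object.
#' @param times optional explicit output grid overriding `spec$dt`.
#' @return A [pk_timecourse()] with the scenario attached as attributes
#'   `spec`, `params`, `enzyme`.
#' @examples
#' tc <- pk_simulate(sim_spec(C1_0 = 1, t_end = 60),
#'                   reference_pk_parameters(), reference_enzyme("wtBChE"))
#' max(tc$C2)  # brain peak, ~0.908 uM
#' @export
pk_simulate <- function(spec, params, enzyme, times = NULL) {
  stopifnot(inherits(spec, "sim_spec"), inherits(params, "pk_parameters"),
            inherits(enzyme, "enzyme_kinetics"))
  C1_0 <- initial_concentration(spec, params)
  if (is.null(times)) {
    dt <- spec$dt
    if (is.null(dt)) dt <- min(0.01, spec$t_end / 2000)
    times <- seq(0, spec$t_end, by = dt)
    if (times[length(times)] < spec$t_end) times <- c(times, spec$t_end)
  }
  if (C1_0 == 0) {
    tc <- pk_timecourse(times, rep(0, length(times)), rep(0, length(times)))
  } else {
    out <- deSolve::ode(y = c(C1 = C1_0, C2 = 0), times = times,
                        func = .ode_rhs, parms = .flat_params(params, enzyme),
                        method = "lsoda", rtol = spec$rtol, atol = spec$atol,
                        maxsteps = 50000)
    if (attr(out, "istate")[1L] < 0)
      stop(sprintf("ODE integration failed; last valid time %g min",
                   max(out[stats::complete.cases(out), 1L])))
    C1 <- out[, 2L]; C2 <- out[, 3L]
    worst <- min(0, C1, C2)
    if (worst < -spec$atol * 1e3)
      warning(sprintf("solver undershoot %g clipped to 0", worst))
    tc <- pk_timecourse(out[, 1L], pmax(C1, 0), pmax(C2, 0))
  }
  attr(tc, "spec") <- spec
  attr(tc, "params") <- params
  attr(tc, "enzyme") <- enzyme
  tc
}

#' Mass-balance residual of a simulated time course
#'
#' Verifies the conservation structure of the model: the amount in plasma
#' plus the amount in brain plus the cumulative amount eliminated must
#' equal the injected amount at every time,
#' \deqn{V_p C_1(t) + V_b C_2(t) + V_p \int_0^t V_{max} C_1/(K_M+C_1)\,ds
#'   - V_p C_1(0) \approx 0.}
#' The elimination integral is evaluated by trapezoidal quadrature on the
#' stored grid.
#'
#' @param tc a [pk_timecourse()] produced by [pk_simulate()].
#' @param params,enzyme scenario objects; default to the ones stored on
#'   `tc`.
#' @return A list with the `residual` series (uM-equivalents of plasma
#'   amount, i.e. litre-scaled micromoles), `max_abs`, and
#'   `max_rel` = `max_abs / (V_p * C1(0))`.
#' @export
mass_balance_residual <- function(tc, params = attr(tc, "params"),
                                  enzyme = attr(tc, "enzyme")) {
  stopifnot(inherits(tc, "pk_timecourse"))
  if (is.null(params) || is.null(enzyme))
    stop("params and enzyme must be supplied or stored on the time course")
  elim <- enzyme$v_max * tc$C1 / (enzyme$K_M + tc$C1)
  cum <- c(0, cumsum(diff(tc$t) * (elim[-length(elim)] + elim[-1L]) / 2))
  res <- params$V_p * tc$C1 + params$V_b * tc$C2 + params$V_p * cum -
    params$V_p * tc$C1[1L]
  denom <- params$V_p * tc$C1[1L]
  list(residual = res, max_abs = max(abs(res)),
       max_rel = if (denom > 0) max(abs(res)) / denom else max(abs(res)))
}

#' Write / read a time course as delimited text
#'
#' Three-column comma-separated text with header `t_min,C1_uM,C2_uM`;
#' round-trippable at full double precision.
#'
#' @param tc a [pk_timecourse()].
#' @param path file path.
#' @return `write_timecourse` returns `path` invisibly; `read_timecourse`
#'   returns a [pk_timecourse()].
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "pk_timecourse"))
  lines <- c("t_min,C1_uM,C2_uM",
             sprintf("%.17g,%.17g,%.17g", tc$t, tc$C1, tc$C2))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  d <- utils::read.csv(path)
  if (!identical(names(d), c("t_min", "C1_uM", "C2_uM")))
    stop("expected header 't_min,C1_uM,C2_uM'")
  pk_timecourse(d$t_min, d$C1_uM, d$C2_uM)
}
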