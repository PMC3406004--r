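#' Two-compartment transfer and volume parameters
#'
#' The four structural parameters of the plasma/brain model: effective
#' plasma volume `V_p` (L), effective brain volume `V_b` (L), the
#' plasma-to-brain diffusion constant `K_pb` (min^-1) and the
#' brain-to-plasma diffusion constant `K_bp` (min^-1). All four must be
#' strictly positive to be physically meaningful (and for the model to be
#' identifiable). `V_b` is additionally checked against the anatomical
#' plausibility window between the volume of the striatum alone
#' (0.00633 L) and that of the whole brain (1.2538 L); values outside set
#' the `plausible_V_b` attribute to `FALSE` with a warning but are not
#' rejected.
#'
#' @param V_p effective plasma-compartment volume, L.
#' @param V_b effective brain-compartment volume, L.
#' @param K_pb plasma-to-brain diffusion constant, min^-1.
#' @param K_bp brain-to-plasma diffusion constant, min^-1.
#' @param warn warn when `V_b` falls outside the plausibility window.
#' @return An object of class `"pk_parameters"`.
#' @examples
#' reference_pk_parameters()
#' @export
pk_parameters <- function(V_p, V_b, K_pb, K_bp, warn = TRUE) {
  vals <- c(V_p = V_p, V_b = V_b, K_pb = K_pb, K_bp = K_bp)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all of V_p, V_b, K_pb, K_bp must be finite and strictly positive")
  plausible <- V_b >= .Vb_range[1] && V_b <= .Vb_range[2]
  if (warn && !plausible)
    warning(sprintf("V_b = %g L lies outside the anatomical range [%g, %g] L",
                    V_b, .Vb_range[1], .Vb_range[2]))
  structure(
    list(V_p = as.numeric(V_p), V_b = as.numeric(V_b),
         K_pb = as.numeric(K_pb), K_bp = as.numeric(K_bp)),
    plausible_V_b = plausible,
    class = "pk_parameters"
  )
}

# striatum alone .. whole brain, litres
.Vb_range <- c(0.00633, 1.2538)

#' Calibrated reference parameter set
#'
#' The parameter values obtained by fitting the model to human PET
#' tracer-dose time courses: V_b = 0.3292 L, V_p = 11.89 L,
#' K_pb = 0.01898 min^-1, K_bp = 0.01780 min^-1. These are the values
#' used by all lookup-table and threshold computations.
#'
#' @return A [pk_parameters()] object.
#' @export
reference_pk_parameters <- function() {
  pk_parameters(V_p = 11.89, V_b = 0.3292, K_pb = 0.01898, K_bp = 0.01780)
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf("<pk_parameters> V_p = %g L, V_b = %g L, K_pb = %g min^-1, K_bp = %g min^-1\n",
              x$V_p, x$V_b, x$K_pb, x$K_bp))
  if (!isTRUE(attr(x, "plausible_V_b")))
    cat("  (V_b outside the striatum..whole-brain plausibility window)\n")
  invisible(x)
}

#' @export
as.numeric.pk_parameters <- function(x, ...) {
  c(V_p = x$V_p, V_b = x$V_b, K_pb = x$K_pb, K_bp = x$K_bp)
}

#' Simulation specification
#'
#' Defines one bolus simulation scenario: the initial plasma
#' concentration (either directly in uM, or as an intravenous dose in
#' micrograms converted via `C1_0 = dose / (MW * V_p)` with the cocaine
#' free-base molecular weight 303.35 g/mol), the integration horizon and
#' solver controls.
#'
#' @param C1_0 initial plasma cocaine concentration, uM. Exactly one of
#'   `C1_0` and `dose_ug` must be given.
#' @param dose_ug intravenous bolus dose, micrograms; converted to `C1_0`
#'   using `V_p` at simulation time.
#' @param t_end integration horizon, min.
#' @param dt output grid spacing, min; `NULL` picks a dense default
#'   (`min(0.01, t_end/2000)` but at least 2001 points).
#' @param rtol,atol relative and absolute solver tolerances.
#' @param mw molecular weight used for dose conversion, g/mol.
#' @return An object of class `"sim_spec"`.
#' @examples
#' sim_spec(C1_0 = 1, t_end = 60)
#' sim_spec(dose_ug = 11, t_end = 35)   # tracer dose
#' @export
sim_spec <- function(C1_0 = NULL, dose_ug = NULL, t_end = 60, dt = NULL,
                     rtol = 1e-9, atol = 1e-12, mw = 303.35) {
  if (is.null(C1_0) == is.null(dose_ug))
    stop("give exactly one of 'C1_0' (uM) or 'dose_ug' (micrograms)")
  if (!is.null(C1_0) && (!is.finite(C1_0) || C1_0 < 0))
    stop("'C1_0' must be nonnegative")
  if (!is.null(dose_ug) && (!is.finite(dose_ug) || dose_ug < 0))
    stop("'dose_ug' must be nonnegative")
  if (!is.finite(t_end) || t_end <= 0) stop("'t_end' must be positive")
  if (!is.null(dt) && (!is.finite(dt) || dt <= 0)) stop("'dt' must be positive")
  if (rtol <= 0 || atol <= 0) stop("solver tolerances must be positive")
  structure(
    list(C1_0 = C1_0, dose_ug = dose_ug, t_end = t_end, dt = dt,
         rtol = rtol, atol = atol, mw = mw),
    class = "sim_spec"
  )
}

# Resolve the initial plasma concentration of a spec, uM.
initial_concentration <- function(spec, params) {
  if (!is.null(spec$C1_0)) return(spec$C1_0)
  spec$dose_ug / (spec$mw * params$V_p)
}
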