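#' Lookup table of brain-exposure metrics across enzymes and doses
#'
#' For every (enzyme, initial plasma concentration) pair, simulates the
#' calibrated model to full decay and tabulates the brain peak
#' concentration, peak time, brain half-life and brain AUC to infinity.
#' This is the table used to compare candidate therapeutic enzymes
#' against the endogenous wtBChE baseline.
#'
#' @param panel an [enzyme_panel()] (or any named list of
#'   [enzyme_kinetics()] objects).
#' @param doses initial plasma concentrations `C1_0`, uM. An empty vector
#'   yields a header-only (zero-row) table.
#' @param params calibrated [pk_parameters()]; defaults to the reference
#'   fit.
#' @param convention half-life convention, see [half_life()].
#' @param t_end initial horizon per scenario (auto-extended), min.
#' @return A data frame with columns `enzyme`, `C1_0`, `peak_C2`,
#'   `peak_time`, `t_b_half`, `AUC2_inf` (one row per enzyme x dose).
#' @examples
#' \donttest{
#' lookup_table(enzyme_panel(c("wtBChE", "CocH3")), doses = c(1, 5))
#' }
#' @export
lookup_table <- function(panel, doses = c(1, 5, 50, 100, 200),
                         params = reference_pk_parameters(),
                         convention = c("from_peak", "absolute"),
                         t_end = 60) {
  convention <- match.arg(convention)
  empty <- data.frame(enzyme = character(), C1_0 = numeric(),
                      peak_C2 = numeric(), peak_time = numeric(),
                      t_b_half = numeric(), AUC2_inf = numeric())
  if (length(panel) == 0L || length(doses) == 0L) return(empty)
  rows <- lapply(names(panel), function(nm) {
    enz <- panel[[nm]]
    do.call(rbind, lapply(doses, function(d) {
      m <- summary_metrics(sim_spec(C1_0 = d, t_end = t_end), params, enz,
                           convention = convention)
      data.frame(enzyme = nm, C1_0 = d, peak_C2 = m$peak_C2,
                 peak_time = m$peak_time, t_b_half = m$t_b_half,
                 AUC2_inf = m$AUC2_inf)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "convention") <- convention
  out
}

#' Threshold of physiological effect from the two calibration doses
#'
#' Human DAT-occupancy measurements anchor the threshold: an intravenous
#' 0.1 mg/kg dose (peak plasma concentration ~0.32 uM) blocked 47% of
#' dopamine transporters and was perceptible, while 0.05 mg/kg (~0.16 uM)
#' blocked 41% and had no measurable effect. Simulating both doses with
#' only endogenous wtBChE gives the bracketing brain peak concentrations
#' and brain AUC values; the threshold estimates are their midpoints.
#'
#' @param params calibrated [pk_parameters()].
#' @param baseline the endogenous enzyme (default wtBChE at 0.035 uM).
#' @param cal_doses the two calibration plasma concentrations, uM,
#'   ordered `c(low, high)`.
#' @param t_end initial horizon (auto-extended), min.
#' @return A list of class `"threshold_estimate"` with fields `peak_low`,
#'   `peak_high`, `peak_mid` (uM), `auc_low`, `auc_high`, `auc_mid`
#'   (uM*min) and `cal_doses`.
#' @examples
#' \donttest{
#' estimate_thresholds()
#' }
#' @export
estimate_thresholds <- function(params = reference_pk_parameters(),
                                baseline = reference_enzyme("wtBChE", 0.035),
                                cal_doses = c(0.16, 0.32),
                                t_end = 60) {
  stopifnot(length(cal_doses) == 2L, cal_doses[1L] < cal_doses[2L])
  m <- lapply(cal_doses, function(d)
    summary_metrics(sim_spec(C1_0 = d, t_end = t_end), params, baseline))
  structure(list(
    peak_low = m[[1L]]$peak_C2, peak_high = m[[2L]]$peak_C2,
    peak_mid = (m[[1L]]$peak_C2 + m[[2L]]$peak_C2) / 2,
    auc_low = m[[1L]]$AUC2_inf, auc_high = m[[2L]]$AUC2_inf,
    auc_mid = (m[[1L]]$AUC2_inf + m[[2L]]$AUC2_inf) / 2,
    cal_doses = cal_doses
  ), class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(paste0(
    "<threshold_estimate> calibration doses %g / %g uM in plasma\n",
    "  brain peak:  %.3g .. %.3g uM  (midpoint %.3g +/- %.2g)\n",
    "  brain AUCinf: %.3g .. %.3g uM*min (midpoint %.3g +/- %.2g)\n"),
    x$cal_doses[1L], x$cal_doses[2L],
    x$peak_low, x$peak_high, x$peak_mid, (x$peak_high - x$peak_low) / 2,
    x$auc_low, x$auc_high, x$auc_mid, (x$auc_high - x$auc_low) / 2))
  invisible(x)
}

#' Maximum plasma concentration an enzyme dose can keep sub-threshold
#'
#' Finds the largest initial plasma cocaine concentration for which the
#' brain exposure metric (peak concentration or AUC to infinity) stays at
#' or below a threshold, for a given enzyme at a given plasma
#' concentration. The boundary is bracketed on a coarse grid (1 uM steps
#' up to 20 uM, 5 uM above), refined by bisection to `tol` uM, and
#' reported both as the refined continuous value and as the largest
#' not-exceeding integer (`max_C1_0`).
#'
#' @param enzyme an [enzyme_kinetics()] object.
#' @param criterion `"peak"` (brain peak, uM) or `"auc"` (brain AUC to
#'   infinity, uM*min).
#' @param threshold positive threshold value in the criterion's units.
#' @param params calibrated [pk_parameters()].
#' @param tol bisection tolerance on the refined boundary, uM.
#' @param c0_max search cap, uM.
#' @param t_end initial horizon per simulation (auto-extended), min.
#' @return A list of class `"prevention_result"`: `enzyme`, `E_conc`,
#'   `criterion`, `threshold`, `refined` (uM), `max_C1_0` (integer uM).
#'   If the metric already exceeds the threshold at `C1_0 = 1` uM,
#'   `max_C1_0` is 0 with a warning.
#' @examples
#' \donttest{
#' thr <- estimate_thresholds()
#' max_preventable_c0(reference_enzyme("CocH3", 0.035), "peak", thr$peak_mid)
#' }
#' @export
max_preventable_c0 <- function(enzyme, criterion = c("peak", "auc"),
                               threshold,
                               params = reference_pk_parameters(),
                               tol = 0.1, c0_max = 5000, t_end = 60) {
  criterion <- match.arg(criterion)
  if (!is.finite(threshold) || threshold <= 0) stop("'threshold' must be positive")
  metric <- function(c0) {
    if (c0 <= 0) return(0)
    if (criterion == "peak")
      tc_peak(pk_simulate(sim_spec(C1_0 = c0, t_end = t_end), params, enzyme),
              "brain")$peak
    else
      auc_infinity(sim_spec(C1_0 = c0, t_end = t_end), params, enzyme, "brain")
  }
  result <- function(refined, warn0 = FALSE) {
    if (warn0) warning("threshold already exceeded at C1_0 = 1 uM; returning max_C1_0 = 0")
    structure(list(enzyme = enzyme$name, E_conc = enzyme$E_conc,
                   criterion = criterion, threshold = threshold,
                   refined = refined,
                   max_C1_0 = max(0, floor(refined + 1e-9))),
              class = "prevention_result")
  }
  grid <- c(1:20, seq(25, c0_max, by = 5))
  lo <- 0; hi <- NA_real_
  for (g in grid) {
    if (metric(g) > threshold) { hi <- g; break }
    lo <- g
  }
  if (is.na(hi)) stop(sprintf("metric stays below threshold up to C1_0 = %g uM", c0_max))
  warn0 <- lo == 0  # already above threshold at the first grid point
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (metric(mid) > threshold) hi <- mid else lo <- mid
  }
  result(lo, warn0 = warn0)
}

#' @export
print.prevention_result <- function(x, ...) {
  cat(sprintf("<prevention_result> %s at [E] = %g uM, %s <= %.4g: max C1_0 = %d uM (refined %.2f uM)\n",
              x$enzyme, x$E_conc, x$criterion, x$threshold, x$max_C1_0, x$refined))
  invisible(x)
}

#' Prevention table across enzymes, concentrations and criteria
#'
#' Applies [max_preventable_c0()] over a panel of enzymes at one or more
#' plasma concentrations, for the peak and/or AUC criteria, with
#' thresholds recomputed from [estimate_thresholds()] unless supplied.
#'
#' @param enzymes enzyme names from the registry.
#' @param E_concs plasma enzyme concentrations, uM.
#' @param criteria subset of `c("peak", "auc")`.
#' @param thresholds optional named list `list(peak = , auc = )`;
#'   defaults to the runtime midpoints.
#' @param params calibrated [pk_parameters()].
#' @return A data frame with one row per enzyme x concentration x
#'   criterion (`max_C1_0` in integer uM, `refined` in uM).
#' @export
prevention_table <- function(enzymes = c("CocE", "CocH1", "CocH2", "CocH3"),
                             E_concs = c(0.035, 0.5),
                             criteria = c("peak", "auc"),
                             thresholds = NULL,
                             params = reference_pk_parameters()) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  if (is.null(thresholds)) {
    est <- estimate_thresholds(params)
    thresholds <- list(peak = est$peak_mid, auc = est$auc_mid)
  }
  rows <- list()
  for (ec in E_concs) for (crit in criteria) for (nm in enzymes) {
    r <- max_preventable_c0(reference_enzyme(nm, ec), crit,
                            thresholds[[crit]], params = params)
    rows[[length(rows) + 1L]] <- data.frame(
      enzyme = nm, E_conc = ec, criterion = crit,
      threshold = thresholds[[crit]], max_C1_0 = r$max_C1_0,
      refined = r$refined)
  }
  do.call(rbind, rows)
}

#' Tracer-dose comparison of wtBChE and CocH3
#'
#' Simulates the ~11 ug intravenous tracer dose (converted to the initial
#' plasma concentration via the effective plasma volume and the cocaine
#' free-base molecular weight 303.35 g/mol) with endogenous wtBChE and
#' with CocH3 at the same plasma concentration, on a 0-35 min grid. With
#' CocH3 the brain curve peaks earlier and much lower.
#'
#' @param params calibrated [pk_parameters()].
#' @param dose_ug tracer dose, micrograms.
#' @param E_conc plasma enzyme concentration for both enzymes, uM.
#' @param t_end horizon, min.
#' @return A named list of two [pk_timecourse()] objects
#'   (`wtBChE`, `CocH3`), class `"tracer_comparison"`.
#' @examples
#' \donttest{
#' ts <- tracer_scenario()
#' max(ts$CocH3$C2) < max(ts$wtBChE$C2)  # TRUE
#' }
#' @export
tracer_scenario <- function(params = reference_pk_parameters(),
                            dose_ug = 11, E_conc = 0.035, t_end = 35) {
  spec <- sim_spec(dose_ug = dose_ug, t_end = t_end)
  structure(list(
    wtBChE = pk_simulate(spec, params, reference_enzyme("wtBChE", E_conc)),
    CocH3 = pk_simulate(spec, params, reference_enzyme("CocH3", E_conc))
  ), class = "tracer_comparison")
}

#' @export
plot.tracer_comparison <- function(x, ...) {
  ylim <- range(0, x$wtBChE$C2, x$CocH3$C2)
  graphics::plot(x$wtBChE$t, x$wtBChE$C2, type = "l", col = "black",
                 xlab = "time (min)", ylab = "brain concentration (uM)",
                 ylim = ylim, ...)
  graphics::lines(x$CocH3$t, x$CocH3$C2, col = "blue3")
  graphics::legend("topright", c("wtBChE", "CocH3"),
                   col = c("black", "blue3"), lty = 1, bty = "n")
  invisible(x)
}
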