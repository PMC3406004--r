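#' Read and validate a run configuration
#'
#' A YAML file with blocks `enzyme` (name, optionally k_cat/K_M
#' overrides, E_conc), `pk_parameters` (V_p, V_b, K_pb, K_bp; omit for
#' the calibrated reference values), `simulation` (C1_0 or dose_ug,
#' t_end, dt, rtol, atol), `evaluation` (doses, enzymes, E_concs,
#' criterion), `thresholds` (cal_doses), `fit` (data, units, starts,
#' seed, C1_0/dose_ug), `synth` (C1_0, sigma, kind, units, seed),
#' `output` (directory) and `seed`. Unknown keys anywhere are rejected.
#' Units follow the package conventions: uM, min, L.
#'
#' @param path YAML file path, or a list already parsed.
#' @return A validated list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  allowed <- list(
    enzyme = c("name", "k_cat", "K_M", "E_conc"),
    pk_parameters = c("V_p", "V_b", "K_pb", "K_bp"),
    simulation = c("C1_0", "dose_ug", "t_end", "dt", "rtol", "atol"),
    evaluation = c("doses", "enzymes", "E_concs", "criterion"),
    thresholds = c("cal_doses"),
    fit = c("data", "units", "starts", "seed", "C1_0", "dose_ug"),
    synth = c("C1_0", "sigma", "kind", "units", "seed", "schedule_to",
              "schedule_n"),
    output = c("dir"),
    seed = NULL, verbose = NULL)
  bad <- setdiff(names(cfg), names(allowed))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (blk in intersect(names(cfg), names(allowed))) {
    if (is.null(allowed[[blk]])) next
    bad <- setdiff(names(cfg[[blk]]), allowed[[blk]])
    if (length(bad))
      stop(sprintf("unknown keys in '%s': %s", blk, paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

.cfg_enzyme <- function(cfg) {
  e <- cfg$enzyme
  if (is.null(e)) return(reference_enzyme("wtBChE"))
  if (!is.null(e$k_cat) || !is.null(e$K_M)) {
    base <- if (!is.null(e$name) && e$name %in% names(.enzyme_registry))
      .enzyme_registry[[e$name]] else list(k_cat = NULL, K_M = NULL)
    enzyme_kinetics(if (is.null(e$name)) "custom" else e$name,
                    if (is.null(e$k_cat)) base$k_cat else e$k_cat,
                    if (is.null(e$K_M)) base$K_M else e$K_M,
                    if (is.null(e$E_conc)) 0.035 else e$E_conc)
  } else {
    reference_enzyme(if (is.null(e$name)) "wtBChE" else e$name,
                     if (is.null(e$E_conc)) 0.035 else e$E_conc)
  }
}

.cfg_params <- function(cfg) {
  p <- cfg$pk_parameters
  if (is.null(p)) return(reference_pk_parameters())
  pk_parameters(p$V_p, p$V_b, p$K_pb, p$K_bp)
}

.cfg_spec <- function(cfg) {
  s <- cfg$simulation
  if (is.null(s)) stop("config needs a 'simulation' block")
  do.call(sim_spec, s)
}

.provenance <- function() {
  sprintf("# cocainePK %s",
          as.character(utils::packageVersion("cocainePK")))
}

.write_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(.provenance(), header), con)
  utils::write.csv(format(df, digits = 15), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Pipeline commands
#'
#' Config-driven entry points tying the pipeline together; each is a pure
#' function of its configuration (reruns reproduce outputs exactly).
#' `cmd_simulate` runs one scenario and writes the time course plus a
#' one-row metrics table; `cmd_table` writes the enzyme-by-dose lookup
#' table; `cmd_thresholds` writes the threshold estimates and the
#' maximum-preventable-concentration table; `cmd_fit` calibrates the
#' model to a data file; `cmd_synth` writes a synthetic dataset. All
#' reports carry the package version and scenario parameters as `#`
#' comment lines; numbers in the returned tables retain full precision.
#'
#' @param config a `"run_config"` (or path to one).
#' @param out_dir output directory; created if missing; defaults to the
#'   config's `output$dir` or `"."`.
#' @return The main result of the step, invisibly (paths as attributes).
#' @name commands
NULL

#' @rdname commands
#' @export
cmd_simulate <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$output$dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- .cfg_params(cfg); enzyme <- .cfg_enzyme(cfg); spec <- .cfg_spec(cfg)
  tc <- pk_simulate(spec, params, enzyme)
  m <- summary_metrics(spec, params, enzyme)
  write_timecourse(tc, file.path(out_dir, "timecourse.csv"))
  row <- data.frame(enzyme = enzyme$name, E_conc = enzyme$E_conc,
                    C1_0 = initial_concentration(spec, params),
                    peak_C2 = m$peak_C2, peak_time = m$peak_time,
                    t_b_half = m$t_b_half, AUC1_inf = m$AUC1_inf,
                    AUC2_inf = m$AUC2_inf)
  .write_report(row, file.path(out_dir, "metrics.csv"),
                sprintf("# scenario: %s, [E]=%g uM", enzyme$name, enzyme$E_conc))
  invisible(list(timecourse = tc, metrics = row))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname commands
#' @export
cmd_table <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$output$dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ev <- cfg$evaluation
  panel <- enzyme_panel(ev$enzymes %||% c("wtBChE", "CocE", "CocH1", "CocH2", "CocH3"),
                        E_conc = (ev$E_concs %||% 0.035)[1L])
  tab <- lookup_table(panel, doses = ev$doses %||% c(1, 5, 50, 100, 200),
                      params = .cfg_params(cfg))
  .write_report(tab, file.path(out_dir, "lookup_table.csv"),
                sprintf("# half-life convention: %s", attr(tab, "convention") %||% "from_peak"))
  invisible(tab)
}

#' @rdname commands
#' @export
cmd_thresholds <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$output$dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- .cfg_params(cfg)
  est <- estimate_thresholds(params,
                             cal_doses = cfg$thresholds$cal_doses %||% c(0.16, 0.32))
  ev <- cfg$evaluation
  tab <- prevention_table(enzymes = ev$enzymes %||% c("CocE", "CocH1", "CocH2", "CocH3"),
                          E_concs = ev$E_concs %||% c(0.035, 0.5),
                          criteria = ev$criterion %||% c("peak", "auc"),
                          thresholds = list(peak = est$peak_mid, auc = est$auc_mid),
                          params = params)
  .write_report(tab, file.path(out_dir, "prevention_table.csv"),
                sprintf("# thresholds: peak %.6g uM, auc %.6g uM*min",
                        est$peak_mid, est$auc_mid))
  invisible(list(thresholds = est, table = tab))
}

#' @rdname commands
#' @export
cmd_fit <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$output$dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- cfg$fit
  if (is.null(f$data)) stop("'fit' block needs a 'data' file path")
  data <- read_dataset(f$data)
  fit <- pk_fit(data, C1_0 = f$C1_0, dose_ug = f$dose_ug,
                n_starts = f$starts %||% 25, seed = f$seed %||% cfg$seed %||% 1L)
  out <- data.frame(t(coef(fit)), RMSE1 = fit$RMSE1, RMSE2 = fit$RMSE2,
                    r1 = fit$r1, r2 = fit$r2, auc_ratio = fit$auc_ratio,
                    converged = fit$converged)
  .write_report(out, file.path(out_dir, "fit_result.csv"),
                sprintf("# n_starts = %d, seed = %d", fit$n_starts, fit$seed))
  invisible(fit)
}

#' @rdname commands
#' @export
cmd_synth <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$output$dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- cfg$synth %||% list()
  params <- .cfg_params(cfg)
  C1_0 <- s$C1_0 %||% (11 / (303.35 * params$V_p))
  ds <- generate_pk_dataset(
    params, .cfg_enzyme(cfg), C1_0,
    schedule = seq(0, s$schedule_to %||% 35, length.out = s$schedule_n %||% 36),
    noise = noise_model(s$kind %||% "multiplicative-lognormal",
                        s$sigma %||% 0.05),
    units = s$units %||% "abs", seed = s$seed %||% cfg$seed %||% 1L)
  write_dataset(ds, file.path(out_dir, "synthetic_dataset.csv"))
  invisible(ds)
}
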