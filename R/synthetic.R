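#' Observation noise model
#'
#' @param kind `"none"`, `"additive-gaussian"` (sigma in uM) or
#'   `"multiplicative-lognormal"` (sigma is the coefficient of variation;
#'   the lognormal factor is mean-unbiased, so the expected observation
#'   equals the model value and the CV equals `sigma` exactly).
#' @param sigma noise magnitude, >= 0.
#' @return A list of class `"noise_model"`.
#' @examples
#' noise_model("multiplicative-lognormal", 0.05)
#' @export
noise_model <- function(kind = c("none", "additive-gaussian",
                                 "multiplicative-lognormal"),
                        sigma = 0) {
  kind <- match.arg(kind)
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be nonnegative")
  if (kind == "none") sigma <- 0
  structure(list(kind = kind, sigma = sigma), class = "noise_model")
}

.apply_noise <- function(y, noise) {
  switch(noise$kind,
    "none" = y,
    "additive-gaussian" = y + stats::rnorm(length(y), 0, noise$sigma),
    "multiplicative-lognormal" = {
      sdlog <- sqrt(log(1 + noise$sigma^2))
      y * stats::rlnorm(length(y), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
}

# run code with a private, seeded RNG stream; restores the global state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Paired plasma/brain observations
#'
#' Container for calibration data: plasma and brain observations on
#' (possibly different) sampling schedules, a units flag, and the enzyme
#' kinetics that generated the elimination (known and held fixed during
#' fitting).
#'
#' @param plasma,brain data frames with columns `t` (min) and `value`
#'   (uM, or fraction of initial plasma concentration when
#'   `units = "rel"`). At least 4 points per observed compartment (the
#'   model has 4 free parameters); a compartment may be entirely absent
#'   (zero rows), e.g. for identifiability probing, but not both.
#' @param units `"abs"` (uM) or `"rel"` (plasma value 1 at t = 0).
#' @param enzyme the known [enzyme_kinetics()].
#' @return A list of class `"observed_dataset"`.
#' @export
observed_dataset <- function(plasma, brain, units = c("abs", "rel"), enzyme) {
  units <- match.arg(units)
  stopifnot(inherits(enzyme, "enzyme_kinetics"))
  chk <- function(d, nm) {
    if (!all(c("t", "value") %in% names(d))) stop(sprintf("'%s' needs columns t, value", nm))
    if (nrow(d) > 0L && nrow(d) < 4L) stop(sprintf("'%s' needs at least 4 observations", nm))
    if (any(d$t < 0) || any(d$value < 0)) stop(sprintf("'%s' times and values must be nonnegative", nm))
    d[order(d$t), c("t", "value"), drop = FALSE]
  }
  if (nrow(plasma) == 0L && nrow(brain) == 0L) stop("no observations in either compartment")
  structure(list(plasma = chk(plasma, "plasma"), brain = chk(brain, "brain"),
                 units = units, enzyme = enzyme),
            class = "observed_dataset")
}

#' @export
print.observed_dataset <- function(x, ...) {
  cat(sprintf("<observed_dataset> %d plasma + %d brain points on [0, %g] min; units = %s; enzyme = %s\n",
              nrow(x$plasma), nrow(x$brain),
              max(x$plasma$t, x$brain$t), x$units, x$enzyme$name))
  invisible(x)
}

#' Generate a synthetic PET-like dataset with known truth
#'
#' Simulates the model from a known parameter set, samples the
#' trajectories at the given schedules, applies observation noise and
#' optionally rescales to relative units (both series divided by the
#' initial plasma concentration, mimicking tracer studies that report
#' plasma activity as 1 at t = 0). Negative noisy observations are
#' clipped at 0 (`clipped` attribute records how many). Identical seeds
#' reproduce identical datasets.
#'
#' @param params true [pk_parameters()].
#' @param enzyme true [enzyme_kinetics()].
#' @param C1_0 true initial plasma concentration, uM.
#' @param schedule sampling times, min: either a numeric vector used for
#'   both compartments or a list with components `plasma` and `brain`.
#'   Default: 36 equally spaced points over 0-35 min.
#' @param noise a [noise_model()].
#' @param units `"abs"` or `"rel"`.
#' @param seed integer seed for the noise stream.
#' @return A list of class `"synthetic_dataset"` with fields `data`
#'   (an [observed_dataset()]), `truth` (params, enzyme, C1_0), `seed`.
#' @examples
#' d <- generate_pk_dataset(reference_pk_parameters(),
#'                          reference_enzyme("wtBChE"), C1_0 = 0.00305,
#'                          noise = noise_model("multiplicative-lognormal", 0.05),
#'                          seed = 42)
#' @export
generate_pk_dataset <- function(params, enzyme, C1_0,
                                schedule = seq(0, 35, length.out = 36),
                                noise = noise_model("none"),
                                units = c("abs", "rel"), seed = 1L) {
  units <- match.arg(units)
  if (!is.list(schedule)) schedule <- list(plasma = schedule, brain = schedule)
  if (length(schedule$plasma) == 0L && length(schedule$brain) == 0L)
    stop("empty sampling schedule")
  t_max <- max(schedule$plasma, schedule$brain)
  tc <- pk_simulate(sim_spec(C1_0 = C1_0, t_end = t_max), params, enzyme)
  samp <- function(times, col) {
    if (length(times) == 0L) return(numeric(0))
    stats::approx(tc$t, tc[[col]], xout = times, ties = "ordered")$y
  }
  y1 <- samp(schedule$plasma, "C1")
  y2 <- samp(schedule$brain, "C2")
  if (units == "rel") { y1 <- y1 / C1_0; y2 <- y2 / C1_0 }
  obs <- with_seed(seed, list(p = .apply_noise(y1, noise),
                              b = .apply_noise(y2, noise)))
  clipped <- sum(obs$p < 0) + sum(obs$b < 0)
  data <- observed_dataset(
    plasma = data.frame(t = schedule$plasma, value = pmax(obs$p, 0)),
    brain = data.frame(t = schedule$brain, value = pmax(obs$b, 0)),
    units = units, enzyme = enzyme)
  structure(list(data = data,
                 truth = list(params = params, enzyme = enzyme, C1_0 = C1_0),
                 noise = noise, seed = seed, clipped = clipped),
            class = "synthetic_dataset")
}

#' Deterministic reference fixture
#'
#' Noise-free synthetic dataset from the calibrated reference truth:
#' the ~11 ug tracer bolus (C1_0 = 11/(303.35 * 11.89) uM) with
#' endogenous wtBChE, both compartments sampled at 1-min spacing over
#' 0-35 min. Used to test that calibration closes the loop (refitting
#' recovers the truth).
#'
#' @param units `"abs"` or `"rel"`.
#' @return A `"synthetic_dataset"`.
#' @examples
#' fx <- reference_fixture()
#' fx$truth$C1_0
#' @export
reference_fixture <- function(units = "abs") {
  params <- reference_pk_parameters()
  C1_0 <- 11 / (303.35 * params$V_p)
  generate_pk_dataset(params, reference_enzyme("wtBChE", 0.035), C1_0,
                      schedule = seq(0, 35, by = 1),
                      noise = noise_model("none"), units = units, seed = 0L)
}

#' Write / read an observed dataset as columnar text
#'
#' Wide comma-separated format `t_min,C1_uM,C2_uM` (header records the
#' units flag and enzyme as comment lines starting with `#`); a
#' compartment with no observation at a time carries `NA`.
#'
#' @param data an [observed_dataset()] (or `"synthetic_dataset"`, whose
#'   `data` field is written).
#' @param path file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset`
#'   returns an [observed_dataset()].
#' @export
write_dataset <- function(data, path) {
  if (inherits(data, "synthetic_dataset")) data <- data$data
  stopifnot(inherits(data, "observed_dataset"))
  times <- sort(unique(c(data$plasma$t, data$brain$t)))
  v <- function(d, tt) d$value[match(tt, d$t)]
  hdr <- c(sprintf("# units: %s", data$units),
           sprintf("# enzyme: %s k_cat=%.10g K_M=%.10g E_conc=%.10g",
                   data$enzyme$name, data$enzyme$k_cat, data$enzyme$K_M,
                   data$enzyme$E_conc),
           "t_min,C1_uM,C2_uM")
  rows <- sprintf("%.17g,%s,%s", times,
                  ifelse(is.na(v(data$plasma, times)), "NA",
                         sprintf("%.17g", v(data$plasma, times))),
                  ifelse(is.na(v(data$brain, times)), "NA",
                         sprintf("%.17g", v(data$brain, times))))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  units <- sub("^# units: *", "", grep("^# units:", meta, value = TRUE))
  em <- regmatches(meta, regexec(
    "^# enzyme: (\\S+) k_cat=(\\S+) K_M=(\\S+) E_conc=(\\S+)",
    meta))
  em <- em[lengths(em) == 5L][[1L]]
  enzyme <- enzyme_kinetics(em[2L], as.numeric(em[3L]), as.numeric(em[4L]),
                            as.numeric(em[5L]))
  d <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  observed_dataset(
    plasma = data.frame(t = d$t_min, value = d$C1_uM)[!is.na(d$C1_uM), ],
    brain = data.frame(t = d$t_min, value = d$C2_uM)[!is.na(d$C2_uM), ],
    units = units, enzyme = enzyme)
}
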