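#' Enzyme kinetic constants
#'
#' Construct the kinetic description of one cocaine-metabolising enzyme:
#' the catalytic rate constant \eqn{k_{cat}} (min\eqn{^{-1}}), the
#' Michaelis constant \eqn{K_M} (\eqn{\mu}M) and the molar active-site
#' concentration of the enzyme in plasma \eqn{[E]} (\eqn{\mu}M). The
#' maximal elimination velocity is derived as
#' \eqn{V_{max} = k_{cat} \cdot [E]} (\eqn{\mu}M/min).
#'
#' @param name label for the enzyme.
#' @param k_cat catalytic rate constant, per minute; must be positive.
#' @param K_M Michaelis constant, \eqn{\mu}M; must be positive.
#' @param E_conc active-site concentration in plasma, \eqn{\mu}M;
#'   must be nonnegative (zero gives a no-elimination enzyme).
#'
#' @return An object of class `"enzyme_kinetics"`: a list with fields
#'   `name`, `k_cat`, `K_M`, `E_conc` and the derived `v_max`.
#' @examples
#' wt <- enzyme_kinetics("wtBChE", k_cat = 4.1, K_M = 4.5, E_conc = 0.035)
#' wt$v_max  # 0.1435 uM/min
#' @export
enzyme_kinetics <- function(name, k_cat, K_M, E_conc) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(k_cat) || length(k_cat) != 1L || !is.finite(k_cat) || k_cat <= 0)
    stop("'k_cat' must be a single positive number (min^-1)")
  if (!is.numeric(K_M) || length(K_M) != 1L || !is.finite(K_M) || K_M <= 0)
    stop("'K_M' must be a single positive number (uM)")
  if (!is.numeric(E_conc) || length(E_conc) != 1L || !is.finite(E_conc) || E_conc < 0)
    stop("'E_conc' must be a single nonnegative number (uM)")
  structure(
    list(name = name, k_cat = as.numeric(k_cat), K_M = as.numeric(K_M),
         E_conc = as.numeric(E_conc), v_max = as.numeric(k_cat) * as.numeric(E_conc)),
    class = "enzyme_kinetics"
  )
}

#' @export
print.enzyme_kinetics <- function(x, ...) {
  cat(sprintf("<enzyme_kinetics> %s: k_cat = %g min^-1, K_M = %g uM, [E] = %g uM, Vmax = %g uM/min\n",
              x$name, x$k_cat, x$K_M, x$E_conc, x$v_max))
  invisible(x)
}

# In vitro constants for the cocaine-metabolising enzymes considered:
# endogenous wild-type butyrylcholinesterase, bacterial cocaine esterase,
# and the engineered BChE-derived cocaine hydrolases CocH1-CocH3.
.enzyme_registry <- list(
  wtBChE = list(k_cat = 4.1,  K_M = 4.5),
  CocE   = list(k_cat = 468,  K_M = 0.64),
  CocH1  = list(k_cat = 3060, K_M = 3.1),
  CocH2  = list(k_cat = 1730, K_M = 1.1),
  CocH3  = list(k_cat = 5700, K_M = 3.1)
)

#' Reference enzyme registry
#'
#' Look up one of the reference cocaine-metabolising enzymes by name and
#' attach a plasma concentration. The registry carries the published in
#' vitro constants: wtBChE (k_cat 4.1 min^-1, K_M 4.5 uM), CocE (468,
#' 0.64), CocH1 (3060, 3.1), CocH2 (1730, 1.1), CocH3 (5700, 3.1).
#' The physiological concentration of endogenous wtBChE active sites is
#' 0.035 uM; 0.5 uM is the plasma level achieved by enzyme gene transfer.
#'
#' @param name one of `"wtBChE"`, `"CocE"`, `"CocH1"`, `"CocH2"`, `"CocH3"`.
#' @param E_conc plasma active-site concentration, uM (default 0.035).
#' @return An [enzyme_kinetics()] object.
#' @examples
#' reference_enzyme("CocH3")
#' reference_enzyme("CocH3", E_conc = 0.5)
#' @export
reference_enzyme <- function(name, E_conc = 0.035) {
  name <- match.arg(name, names(.enzyme_registry))
  e <- .enzyme_registry[[name]]
  enzyme_kinetics(name, e$k_cat, e$K_M, E_conc)
}

#' Panel of reference enzymes
#'
#' Build the evaluation panel of cocaine-metabolising enzymes at a common
#' plasma concentration, for use with [lookup_table()].
#'
#' @param names enzymes to include; defaults to the full registry with
#'   endogenous wtBChE first as baseline.
#' @param E_conc plasma active-site concentration applied to all, uM.
#' @return A named list of [enzyme_kinetics()] objects, class
#'   `"enzyme_panel"`.
#' @examples
#' enzyme_panel(E_conc = 0.5)
#' @export
enzyme_panel <- function(names = c("wtBChE", "CocE", "CocH1", "CocH2", "CocH3"),
                         E_conc = 0.035) {
  if (anyDuplicated(names)) stop("enzyme names must be unique")
  panel <- lapply(names, reference_enzyme, E_conc = E_conc)
  names(panel) <- names
  structure(panel, class = "enzyme_panel")
}

#' @export
print.enzyme_panel <- function(x, ...) {
  cat(sprintf("<enzyme_panel> %d enzymes at [E] = %g uM: %s\n",
              length(x), if (length(x)) x[[1]]$E_conc else NA_real_,
              paste(names(x), collapse = ", ")))
  invisible(x)
}
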