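#' Physiological constants of the SPINA-GT model
#'
#' Bundles the seven constants entering the thyroid secretory-capacity
#' formula: the thyroxine dilution factor, its clearance exponent, the TSH
#' damping constant (EC50 of the thyroid's response to TSH), the dissociation
#' constants of T4 at its two main plasma carriers, and the standard carrier
#' concentrations. All defaults are the values established for the adult
#' SPINA reference model; TBG and transthyretin concentrations take the same
#' values in children.
#'
#' @param alpha_t Dilution factor for thyroxine, 1/L.
#' @param beta_t Clearance exponent for T4, 1/s.
#' @param d_t Damping constant (EC50) of TSH, mIU/L.
#' @param k41 Dissociation constant of T4 at thyroxine-binding globulin, L/mol.
#' @param k42 Dissociation constant of T4 at transthyretin, L/mol.
#' @param tbg Standard thyroxine-binding globulin concentration, mol/L.
#' @param tbpa Standard transthyretin concentration, mol/L.
#'
#' @return An object of class `spina_constants`: a named list of the seven
#'   constants.
#' @seealso [binding_factor()], [compute_gt()]
#' @examples
#' spina_constants()
#' # lowered TBG, e.g. congenital TBG deficiency
#' spina_constants(tbg = 150e-9)
#' @export
spina_constants <- function(alpha_t = 0.1,
                            beta_t = 1.1e-6,
                            d_t = 2.75,
                            k41 = 2e10,
                            k42 = 2e8,
                            tbg = 300e-9,
                            tbpa = 4.5e-6) {
  const <- list(
    alpha_t = alpha_t, beta_t = beta_t, d_t = d_t,
    k41 = k41, k42 = k42, tbg = tbg, tbpa = tbpa
  )
  for (nm in names(const)) {
    x <- const[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("`", nm, "` must be a single strictly positive number.", call. = FALSE)
    }
  }
  structure(const, class = "spina_constants")
}

#' Plasma protein binding factor for thyroxine
#'
#' The dimensionless factor `1 + K41*[TBG] + K42*[TBPA]` relating total to
#' free T4 through equilibrium binding at thyroxine-binding globulin and
#' transthyretin. With the default constants it equals 6901.
#'
#' @param constants A [spina_constants()] object.
#' @return A single number.
#' @export
binding_factor <- function(constants = spina_constants()) {
  stopifnot(inherits(constants, "spina_constants"))
  1 + constants$k41 * constants$tbg + constants$k42 * constants$tbpa
}

#' @export
print.spina_constants <- function(x, ...) {
  cat("SPINA model constants\n")
  cat(sprintf("  alpha_T (dilution factor, 1/L):       %g\n", x$alpha_t))
  cat(sprintf("  beta_T  (clearance exponent, 1/s):    %g\n", x$beta_t))
  cat(sprintf("  D_T     (TSH damping const., mIU/L):  %g\n", x$d_t))
  cat(sprintf("  K41     (T4 at TBG, L/mol):           %g\n", x$k41))
  cat(sprintf("  K42     (T4 at TTR, L/mol):           %g\n", x$k42))
  cat(sprintf("  [TBG]   (mol/L):                      %g\n", x$tbg))
  cat(sprintf("  [TBPA]  (mol/L):                      %g\n", x$tbpa))
  cat(sprintf("  binding factor 1+K41*TBG+K42*TBPA:    %g\n", binding_factor(x)))
  invisible(x)
}
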