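#' Reference range of SPINA-GT
#'
#' The secretory capacity of a healthy thyroid lies between 1.4 and
#' 8.7 pmol/s.
#' @format Numeric vector of length 2, pmol/s.
#' @export
gt_reference_range <- c(1.4, 8.7)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("`", name, "` must be numeric.", call. = FALSE)
  }
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    stop("`", name, "` must be strictly positive and finite; offending value(s): ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Thyroid secretory capacity (SPINA-GT)
#'
#' Estimates the thyroid's maximum stimulated secretion rate of T4 from a
#' paired serum TSH/FT4 measurement at equilibrium:
#'
#' \deqn{\hat{G}_T = \frac{\beta_T (D_T + TSH)(1 + K_{41}[TBG] + K_{42}[TBPA])\,FT4}
#'                        {\alpha_T\, TSH}}
#'
#' FT4 is converted from pmol/L to mol/L internally and the result from mol/s
#' back to pmol/s; `D_T` and TSH share the unit mIU/L so their ratio structure
#' is dimensionless. GT is linear in FT4 at fixed TSH and strictly decreasing
#' in TSH at fixed FT4, approaching the asymptote
#' `beta_T * binding_factor * FT4 / alpha_T` from above as TSH grows.
#'
#' @param tsh Serum TSH, mIU/L (equivalently uIU/mL). Vectorised.
#' @param ft4 Serum free T4, pmol/L. Vectorised (recycled against `tsh`).
#' @param constants A [spina_constants()] object.
#' @return Numeric vector of secretory capacities, pmol/s.
#' @seealso [invert_gt()], [in_gt_reference_range()], [predict_gt()]
#' @examples
#' compute_gt(tsh = 3.01, ft4 = 16.3) # ~2.37 pmol/s
#' compute_gt(tsh = 6.7, ft4 = 15.7)  # ~1.68 pmol/s, below euthyroid levels
#' @export
compute_gt <- function(tsh, ft4, constants = spina_constants()) {
  stopifnot(inherits(constants, "spina_constants"))
  check_positive(tsh, "tsh")
  check_positive(ft4, "ft4")
  ft4_mol <- ft4 * 1e-12
  gt_mol <- constants$beta_t * (constants$d_t + tsh) * binding_factor(constants) *
    ft4_mol / (constants$alpha_t * tsh)
  gt_mol * 1e12
}

#' Is a secretory capacity within the reference range?
#'
#' @param gt Secretory capacity, pmol/s.
#' @return Logical vector: `TRUE` where `gt` lies in \[1.4, 8.7\] pmol/s.
#' @export
in_gt_reference_range <- function(gt) {
  gt >= gt_reference_range[1] & gt <= gt_reference_range[2]
}

#' Smallest secretory capacity attainable at a given FT4
#'
#' The TSH -> Inf asymptote of the GT formula: no equilibrium TSH, however
#' high, can push the estimated capacity below
#' `beta_T * binding_factor * FT4 / alpha_T`. Used as the feasibility bound
#' by [invert_gt()] and by the synthetic-cohort generator's rejection step.
#'
#' @inheritParams compute_gt
#' @return Numeric vector, pmol/s.
#' @export
min_feasible_gt <- function(ft4, constants = spina_constants()) {
  stopifnot(inherits(constants, "spina_constants"))
  check_positive(ft4, "ft4")
  constants$beta_t * binding_factor(constants) * ft4 / constants$alpha_t
}

#' Equilibrium TSH implied by a secretory capacity and an FT4 level
#'
#' Algebraic inversion of [compute_gt()]: the TSH at which a gland of
#' capacity `gt` holds serum FT4 at `ft4`,
#' \deqn{TSH = \frac{\beta_T D_T C\, FT4}{\alpha_T G_T - \beta_T C\, FT4}, \quad
#'       C = 1 + K_{41}[TBG] + K_{42}[TBPA].}
#' Round-trips with [compute_gt()] to machine precision. The pair is only
#' feasible when `gt` exceeds [min_feasible_gt()] at that FT4.
#'
#' @param gt Secretory capacity, pmol/s. Vectorised.
#' @param ft4 Serum free T4, pmol/L. Vectorised (recycled).
#' @param constants A [spina_constants()] object.
#' @return Numeric vector of TSH values, mIU/L.
#' @examples
#' tsh <- invert_gt(gt = 2.368, ft4 = 16.3) # ~3.01 mIU/L
#' compute_gt(tsh, 16.3)
#' @export
invert_gt <- function(gt, ft4, constants = spina_constants()) {
  stopifnot(inherits(constants, "spina_constants"))
  check_positive(gt, "gt")
  check_positive(ft4, "ft4")
  n <- max(length(gt), length(ft4))
  gt <- rep_len(gt, n)
  ft4 <- rep_len(ft4, n)
  cb <- binding_factor(constants)
  denom <- constants$alpha_t * gt * 1e-12 - constants$beta_t * cb * ft4 * 1e-12
  if (any(denom <= 0)) {
    i <- which(denom <= 0)[1L]
    stop(sprintf(paste0(
      "Infeasible (gt, ft4) pair: gt = %.4g pmol/s at ft4 = %.4g pmol/L; ",
      "the minimum feasible capacity at this FT4 is %.4g pmol/s ",
      "(the TSH -> Inf asymptote)."),
      gt[i], ft4[i], min_feasible_gt(ft4[i], constants)), call. = FALSE)
  }
  constants$beta_t * constants$d_t * cb * ft4 * 1e-12 / denom
}
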