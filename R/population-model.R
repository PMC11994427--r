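#' Parameters of the population TSH-FT4 curve
#'
#' The population relationship between ln(TSH) and FT4 in children over one
#' year of age (not on thyroxine) is described by two overlapping negative
#' log-sigmoid branches, each a 4-parameter logistic
#' `ln TSH = offset + span / (1 + exp(-(center - FT4)/width))`, switching at
#' an FT4 of 12 pmol/L. FT4 exactly at the boundary is evaluated on the high
#' branch; the published branches do not meet exactly there and the small
#' discontinuity is retained deliberately rather than smoothed away.
#'
#' @param low Named numeric vector `c(offset, span, center, width)` for the
#'   FT4 < boundary branch. Defaults: 1.4, 3.5, 7.0 pmol/L, 1.0 pmol/L.
#' @param high Same for the FT4 >= boundary branch. Defaults: -3.7, 5.3,
#'   20.6 pmol/L, 3.0 pmol/L.
#' @param boundary Branch switch point, pmol/L (default 12).
#' @return An object of class `tsh_curve_params`.
#' @export
tsh_curve_params <- function(low = c(offset = 1.4, span = 3.5, center = 7.0, width = 1.0),
                             high = c(offset = -3.7, span = 5.3, center = 20.6, width = 3.0),
                             boundary = 12) {
  req <- c("offset", "span", "center", "width")
  for (br in list(low = low, high = high)) {
    if (!all(req %in% names(br))) {
      stop("Branch parameters need named entries: ", paste(req, collapse = ", "),
           call. = FALSE)
    }
  }
  stopifnot(is.numeric(boundary), length(boundary) == 1L, boundary > 0)
  structure(list(low = low[req], high = high[req], boundary = boundary),
            class = "tsh_curve_params")
}

logistic_branch <- function(ft4, p) {
  unname(p["offset"] + p["span"] / (1 + exp(-(p["center"] - ft4) / p["width"])))
}

#' Population-predicted ln(TSH) at a given FT4
#'
#' Evaluates the branch-appropriate log-sigmoid of the population TSH-FT4
#' curve and back-transforms to the TSH scale. Within each branch the curve
#' is strictly decreasing in FT4: small FT4 shifts produce large relative
#' TSH changes, the hallmark of pituitary-thyroid feedback.
#'
#' @param ft4 Serum free T4, pmol/L. Vectorised.
#' @param params A [tsh_curve_params()] object.
#' @return A tibble with columns `ft4`, `ln_tsh`, `tsh` (mIU/L) and `branch`
#'   (`"low_ft4"` or `"high_ft4"`), one row per input.
#' @examples
#' predict_ln_tsh(c(7, 16.3, 20.6))
#' @export
predict_ln_tsh <- function(ft4, params = tsh_curve_params()) {
  stopifnot(inherits(params, "tsh_curve_params"))
  check_positive(ft4, "ft4")
  low <- ft4 < params$boundary
  ln_tsh <- ifelse(low,
                   logistic_branch(ft4, params$low),
                   logistic_branch(ft4, params$high))
  tibble::tibble(
    ft4 = ft4,
    ln_tsh = ln_tsh,
    tsh = exp(ln_tsh),
    branch = ifelse(low, "low_ft4", "high_ft4")
  )
}

#' Population-predicted TSH at a given FT4
#'
#' Convenience wrapper around [predict_ln_tsh()] returning the
#' back-transformed TSH only.
#'
#' @inheritParams predict_ln_tsh
#' @return Numeric vector of TSH values, mIU/L.
#' @export
predict_tsh <- function(ft4, params = tsh_curve_params()) {
  predict_ln_tsh(ft4, params)$tsh
}

#' Predicted secretory capacity of a population-average individual
#'
#' The GT a subject would exhibit if their TSH sat exactly on the population
#' curve at their measured FT4: `compute_gt(predict_tsh(ft4), ft4)`. It is a
#' function of FT4 alone — two subjects with equal FT4 share the same
#' predicted GT regardless of their measured TSH. Comparing actual against
#' predicted GT localises a subject relative to the population set-point: a
#' measured TSH above the curve implies actual GT below predicted GT.
#'
#' @inheritParams predict_ln_tsh
#' @param constants A [spina_constants()] object.
#' @return Numeric vector of predicted secretory capacities, pmol/s.
#' @examples
#' predict_gt(16.3) # ~3.14 pmol/s
#' @export
predict_gt <- function(ft4, params = tsh_curve_params(),
                       constants = spina_constants()) {
  compute_gt(predict_tsh(ft4, params), ft4, constants)
}
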