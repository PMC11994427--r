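#' Stratum labels in reporting order
#' @format Character vector of length 6.
#' @export
stratum_levels <- c("Q1", "Q2", "Q3", "Q4", "mild_SH", "severe_SH")

#' Classify thyroid status from TSH
#'
#' Subclinical hypothyroidism (SH) is defined by TSH strictly above
#' 4.5 mIU/L with FT4 in the normal range; beyond the neonatal period it is
#' subcategorised into a mild (4.5 < TSH <= 10) and a severe (TSH > 10) form.
#' TSH exactly at a threshold goes to the lower category.
#'
#' @param tsh Serum TSH, mIU/L. Vectorised.
#' @param sh_threshold Euthyroid/SH boundary, mIU/L (default 4.5).
#' @param severe_threshold Mild/severe SH boundary, mIU/L (default 10).
#' @return Factor with levels `euthyroid`, `mild_SH`, `severe_SH`.
#' @examples
#' classify_thyroid_status(c(4.5, 4.51, 10, 10.23))
#' @export
classify_thyroid_status <- function(tsh, sh_threshold = 4.5, severe_threshold = 10) {
  check_positive(tsh, "tsh")
  stopifnot(sh_threshold > 0, severe_threshold > sh_threshold)
  out <- ifelse(tsh <= sh_threshold, "euthyroid",
                ifelse(tsh <= severe_threshold, "mild_SH", "severe_SH"))
  factor(out, levels = c("euthyroid", "mild_SH", "severe_SH"))
}

#' Thyroid autoantibody positivity
#'
#' A subject is antibody positive when anti-thyroglobulin and/or
#' anti-thyroid-peroxidase antibodies exceed the assay cut-off (strictly
#' above 34 IU/mL). With one assay missing, positivity is judged on the
#' available one; with both missing the subject is indeterminate (`NA`) and
#' is excluded from positivity denominators downstream.
#'
#' @param tg_ab Anti-thyroglobulin antibodies, IU/mL (`NA` = not measured).
#' @param tpo_ab Anti-thyroid-peroxidase antibodies, IU/mL (`NA` = not measured).
#' @param threshold Positivity cut-off, IU/mL (default 34).
#' @return Logical vector, `NA` where both assays are missing.
#' @examples
#' antibody_positive(tg_ab = c(35, 34, NA), tpo_ab = c(1, 34, 100))
#' @export
antibody_positive <- function(tg_ab, tpo_ab, threshold = 34) {
  n <- max(length(tg_ab), length(tpo_ab))
  tg_ab <- rep_len(as.numeric(tg_ab), n)
  tpo_ab <- rep_len(as.numeric(tpo_ab), n)
  pos <- (!is.na(tg_ab) & tg_ab > threshold) | (!is.na(tpo_ab) & tpo_ab > threshold)
  pos[is.na(tg_ab) & is.na(tpo_ab)] <- NA
  pos
}

#' Quartile bins of euthyroid TSH
#'
#' Splits the euthyroid TSH distribution at its 25th/50th/75th percentiles
#' (linear interpolation between order statistics, `quantile()` type 7).
#' Values tied with a boundary fall into the lower bin, so bin sizes may
#' differ by the number of boundary ties.
#'
#' @param tsh Euthyroid TSH values, mIU/L; at least 4 distinct values.
#' @return A list with `bins` (factor `Q1`..`Q4`, one per input), `breaks`
#'   (the three interior quantiles) and `table` (tibble: label, n, tsh_min,
#'   tsh_max of bin members).
#' @examples
#' tsh_quartile_bins(seq(0.6, 4.4, length.out = 8))$table
#' @export
tsh_quartile_bins <- function(tsh) {
  check_positive(tsh, "tsh")
  if (length(tsh) < 4L || length(unique(tsh)) < 4L) {
    stop("Quartile binning needs at least 4 distinct TSH values.", call. = FALSE)
  }
  breaks <- stats::quantile(tsh, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  idx <- 1L + (tsh > breaks[1]) + (tsh > breaks[2]) + (tsh > breaks[3])
  bins <- factor(stratum_levels[idx], levels = stratum_levels[1:4])
  tab <- tibble::tibble(label = levels(bins)) |>
    dplyr::mutate(
      n = as.integer(table(bins)[.data$label]),
      tsh_min = vapply(.data$label, function(l) suppressWarnings(min(tsh[bins == l])), 1.0),
      tsh_max = vapply(.data$label, function(l) suppressWarnings(max(tsh[bins == l])), 1.0)
    )
  list(bins = bins, breaks = breaks, table = tab)
}

#' BMI standard-deviation score
#'
#' `(BMI - reference mean BMI for age, race and sex) / reference SD for age
#' and sex`. Reference means and SDs come from national growth tables
#' supplied by the user.
#'
#' @param bmi Observed body-mass index, kg/m^2.
#' @param ref_mean Reference mean BMI, kg/m^2.
#' @param ref_sd Reference BMI standard deviation, kg/m^2; must be positive.
#' @return Dimensionless SDS, vectorised.
#' @examples
#' bmi_sds(20, ref_mean = 17, ref_sd = 1.5)
#' @export
bmi_sds <- function(bmi, ref_mean, ref_sd) {
  if (any(!is.finite(ref_sd) | ref_sd <= 0)) {
    stop("`ref_sd` must be strictly positive.", call. = FALSE)
  }
  (bmi - ref_mean) / ref_sd
}

#' Assign every subject to a stratum
#'
#' Euthyroid subjects (TSH <= 4.5 mIU/L) are binned into quartiles `Q1`-`Q4`
#' of the euthyroid TSH distribution; the rest are `mild_SH` or `severe_SH`.
#' The six labels partition the cohort.
#'
#' @param subjects A tibble with at least a `tsh` column (mIU/L).
#' @param sh_threshold,severe_threshold Classification thresholds, mIU/L.
#' @return `subjects` with added `status` and `stratum` factor columns;
#'   the quartile breaks are attached as attribute `"quartile_breaks"`.
#' @export
assign_strata <- function(subjects, sh_threshold = 4.5, severe_threshold = 10) {
  stopifnot(is.data.frame(subjects), "tsh" %in% names(subjects))
  status <- classify_thyroid_status(subjects$tsh, sh_threshold, severe_threshold)
  eu <- status == "euthyroid"
  qb <- tsh_quartile_bins(subjects$tsh[eu])
  stratum <- factor(rep(NA_character_, nrow(subjects)), levels = stratum_levels)
  stratum[eu] <- as.character(qb$bins)
  stratum[status == "mild_SH"] <- "mild_SH"
  stratum[status == "severe_SH"] <- "severe_SH"
  out <- dplyr::mutate(tibble::as_tibble(subjects), status = status, stratum = stratum)
  attr(out, "quartile_breaks") <- qb$breaks
  out
}

#' Augment subjects with actual and predicted SPINA values
#'
#' Adds, per subject: actual GT from the measured (TSH, FT4) pair, the
#' population-predicted TSH at the measured FT4, and the predicted GT
#' computed from that predicted TSH. Predicted quantities are functions of
#' FT4 only.
#'
#' @param subjects Tibble with `tsh` and `ft4` columns.
#' @param constants A [spina_constants()] object.
#' @param params A [tsh_curve_params()] object.
#' @return `subjects` with added `gt_actual_pmol_s`, `tsh_predicted`,
#'   `gt_predicted_pmol_s` columns.
#' @export
augment_spina <- function(subjects, constants = spina_constants(),
                          params = tsh_curve_params()) {
  stopifnot(is.data.frame(subjects), all(c("tsh", "ft4") %in% names(subjects)))
  dplyr::mutate(
    tibble::as_tibble(subjects),
    gt_actual_pmol_s = compute_gt(.data$tsh, .data$ft4, constants),
    tsh_predicted = predict_tsh(.data$ft4, params),
    gt_predicted_pmol_s = compute_gt(.data$tsh_predicted, .data$ft4, constants)
  )
}

#' Per-stratum summary of secretory capacity and antibody positivity
#'
#' One row per stratum in the order Q1..Q4, mild SH, severe SH: subject
#' count, TSH extrema, median and mean of actual and predicted GT, and
#' antibody positivity (count and percentage among subjects with at least
#' one antibody assay). Empty strata yield a row with `n = 0` and `NA`
#' aggregates.
#'
#' @param subjects Output of [assign_strata()] piped through
#'   [augment_spina()] (columns `stratum`, `tsh`, `gt_actual_pmol_s`,
#'   `gt_predicted_pmol_s`; optional `tg_ab`, `tpo_ab`).
#' @param ab_threshold Antibody positivity cut-off, IU/mL.
#' @param pct_digits Decimal places for the positivity percentage; stratum
#'   tables conventionally round to integers (default 0), group-level
#'   reports use one decimal.
#' @return A tibble, one row per stratum.
#' @export
summarize_strata <- function(subjects, ab_threshold = 34, pct_digits = 0) {
  need <- c("stratum", "tsh", "gt_actual_pmol_s", "gt_predicted_pmol_s")
  stopifnot(is.data.frame(subjects), all(need %in% names(subjects)))
  subjects <- tibble::as_tibble(subjects)
  if (!all(c("tg_ab", "tpo_ab") %in% names(subjects))) {
    subjects$tg_ab <- subjects$tpo_ab <- NA_real_
  }
  subjects$ab_pos <- antibody_positive(subjects$tg_ab, subjects$tpo_ab, ab_threshold)
  subjects |>
    dplyr::group_by(stratum = factor(.data$stratum, levels = stratum_levels),
                    .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      tsh_min = if (dplyr::n() > 0) min(.data$tsh) else NA_real_,
      tsh_max = if (dplyr::n() > 0) max(.data$tsh) else NA_real_,
      gt_actual_median = stats::median(.data$gt_actual_pmol_s),
      gt_actual_mean = mean(.data$gt_actual_pmol_s),
      gt_predicted_median = stats::median(.data$gt_predicted_pmol_s),
      gt_predicted_mean = mean(.data$gt_predicted_pmol_s),
      ab_assessed = sum(!is.na(.data$ab_pos)),
      ab_positive = sum(.data$ab_pos, na.rm = TRUE),
      ab_positive_pct = round(100 * .data$ab_positive /
                                ifelse(.data$ab_assessed > 0, .data$ab_assessed, NA_real_),
                              pct_digits),
      .groups = "drop"
    )
}

#' Group comparisons by standard statistical tests
#'
#' Thin, tidy wrapper over base R's tests, matching the analysis plan for
#' this kind of cohort: Welch two-sided t-test for two groups of continuous
#' values, one-way ANOVA with Tukey's HSD (adjusted p-values) for more, and
#' Pearson's chi-squared test for positivity counts. Significance threshold
#' is conventionally 0.05.
#'
#' @param x For `"t_test"` and `"anova_tukey"`: a named list of numeric
#'   vectors, one per group. For `"chi_squared"`: a matrix of counts (groups
#'   in rows, e.g. columns positive/negative).
#' @param test One of `"t_test"`, `"anova_tukey"`, `"chi_squared"`.
#' @param pooled_var Use the pooled-variance Student t-test rather than the
#'   Welch default.
#' @return A tibble with columns `test`, `groups`, `statistic`, `p_value`,
#'   `adjusted`. `anova_tukey` returns the omnibus F row followed by one row
#'   per Tukey pair (statistic = mean difference, adjusted p-value).
#' @examples
#' compare_groups(list(a = rnorm(20), b = rnorm(20, 2)), "t_test")
#' compare_groups(matrix(c(22, 161, 20, 293), 2, byrow = TRUE), "chi_squared")
#' @export
compare_groups <- function(x, test = c("t_test", "anova_tukey", "chi_squared"),
                           pooled_var = FALSE) {
  test <- match.arg(test)
  row <- function(groups, statistic, p_value, adjusted, label = test) {
    tibble::tibble(test = label, groups = groups, statistic = statistic,
                   p_value = p_value, adjusted = adjusted)
  }
  if (test == "chi_squared") {
    counts <- as.matrix(x)
    stopifnot(nrow(counts) >= 2, ncol(counts) >= 2, all(counts >= 0))
    ct <- stats::chisq.test(counts)
    return(row(paste(rownames(counts) %||% seq_len(nrow(counts)), collapse = " vs "),
               unname(ct$statistic), ct$p.value, adjusted = FALSE))
  }
  stopifnot(is.list(x), length(x) >= 2, all(vapply(x, is.numeric, TRUE)))
  if (is.null(names(x))) names(x) <- paste0("g", seq_along(x))
  if (stats::var(unlist(x)) == 0) {
    stop("All groups are constant and identical; no variance to test.", call. = FALSE)
  }
  if (test == "t_test") {
    stopifnot(length(x) == 2)
    tt <- stats::t.test(x[[1]], x[[2]], var.equal = pooled_var)
    return(row(paste(names(x), collapse = " vs "),
               unname(tt$statistic), tt$p.value, adjusted = FALSE))
  }
  stopifnot(all(lengths(x) >= 2))
  df <- data.frame(
    value = unlist(x, use.names = FALSE),
    group = factor(rep(names(x), lengths(x)), levels = names(x))
  )
  fit <- stats::aov(value ~ group, data = df)
  omni <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  dplyr::bind_rows(
    row(paste(names(x), collapse = " vs "), omni[["F value"]][1],
        omni[["Pr(>F)"]][1], adjusted = FALSE, label = "anova_F"),
    row(rownames(tk), unname(tk[, "diff"]), unname(tk[, "p adj"]),
        adjusted = TRUE, label = "anova_tukey")
  )
}

#' Run the full cohort analysis
#'
#' Classifies and stratifies the cohort, computes actual and predicted
#' SPINA-GT per subject, summarises each stratum, and runs the standard
#' comparisons: ANOVA + Tukey of actual GT across the six strata, a Welch
#' t-test of actual vs predicted GT within each stratum, and a chi-squared
#' test of antibody positivity between the euthyroid and SH groups.
#'
#' @param subjects Tibble of subject records with at least `tsh` and `ft4`
#'   (see [read_cohort()] for the full schema).
#' @param constants A [spina_constants()] object.
#' @param params A [tsh_curve_params()] object.
#' @param config A [run_config()] list of thresholds and precisions.
#' @return An object of class `thyro_analysis`: a list with `subjects`
#'   (augmented tibble), `strata` (per-stratum summary), `comparisons`
#'   (tidy test results), and `quartile_breaks`.
#' @examples
#' cohort <- generate_cohort(synthetic_spec(seed = 1))
#' fit <- analyze_cohort(cohort$subjects)
#' fit$strata
#' @export
analyze_cohort <- function(subjects, constants = spina_constants(),
                           params = tsh_curve_params(), config = run_config()) {
  aug <- subjects |>
    assign_strata(sh_threshold = config$thresholds$sh_tsh,
                  severe_threshold = config$thresholds$severe_tsh) |>
    augment_spina(constants, params)
  strata <- summarize_strata(aug, ab_threshold = config$thresholds$antibody,
                             pct_digits = config$precision$stratum_pct_digits)
  gt_by_stratum <- split(aug$gt_actual_pmol_s, aug$stratum)
  gt_by_stratum <- gt_by_stratum[lengths(gt_by_stratum) >= 2]
  comparisons <- list()
  if (length(gt_by_stratum) >= 2) {
    comparisons$gt_across_strata <- compare_groups(gt_by_stratum, "anova_tukey")
  }
  comparisons$actual_vs_predicted <- dplyr::bind_rows(lapply(
    names(gt_by_stratum), function(s) {
      sub <- aug[aug$stratum == s, ]
      res <- compare_groups(list(actual = sub$gt_actual_pmol_s,
                                 predicted = sub$gt_predicted_pmol_s), "t_test")
      res$groups <- paste0(s, ": actual vs predicted GT")
      res
    }))
  if (all(c("tg_ab", "tpo_ab") %in% names(aug))) {
    pos <- antibody_positive(aug$tg_ab, aug$tpo_ab, config$thresholds$antibody)
    keep <- !is.na(pos)
    if (any(keep)) {
      sh <- aug$status[keep] != "euthyroid"
      counts <- rbind(SH = c(sum(pos[keep] & sh), sum(!pos[keep] & sh)),
                      euthyroid = c(sum(pos[keep] & !sh), sum(!pos[keep] & !sh)))
      colnames(counts) <- c("positive", "negative")
      if (all(rowSums(counts) > 0)) {
        comparisons$antibody_positivity <- compare_groups(counts, "chi_squared")
      }
    }
  }
  structure(list(
    subjects = aug,
    strata = strata,
    comparisons = dplyr::bind_rows(comparisons),
    quartile_breaks = attr(aug, "quartile_breaks")
  ), class = "thyro_analysis")
}

#' @export
print.thyro_analysis <- function(x, ...) {
  cat("Thyroid homeostasis cohort analysis\n")
  cat(sprintf("  %d subjects; euthyroid TSH quartile breaks at %s mIU/L\n",
              nrow(x$subjects),
              paste(sprintf("%.2f", x$quartile_breaks), collapse = "/")))
  print(x$strata)
  invisible(x)
}
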