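cohort_schema <- c(
  id = "id", age = "age", sex = "sex", bmi = "bmi", bmi_sds = "bmi_sds",
  tsh = "tsh_miu_l", ft4 = "ft4_pmol_l", tg_ab = "tg_ab_iu_ml",
  tpo_ab = "tpo_ab_iu_ml"
)

#' Run configuration
#'
#' Collects every tunable of the analysis in one structure, with the
#' reference values as defaults: the SPINA constants, the population-curve
#' branch parameters, the classification thresholds (SH at 4.5 mIU/L,
#' severe SH at 10 mIU/L, antibody positivity above 34 IU/mL), and report
#' rounding precisions. Serialises to and from YAML.
#'
#' @param constants A [spina_constants()] object.
#' @param curve A [tsh_curve_params()] object.
#' @param sh_tsh,severe_tsh,antibody Classification thresholds.
#' @param group_pct_digits,stratum_pct_digits,gt_signif Report precisions:
#'   decimals for group-level and stratum-level percentages, significant
#'   figures for GT in human-readable tables.
#' @return An object of class `thyro_config` (a nested list).
#' @export
run_config <- function(constants = spina_constants(),
                       curve = tsh_curve_params(),
                       sh_tsh = 4.5, severe_tsh = 10, antibody = 34,
                       group_pct_digits = 1, stratum_pct_digits = 0,
                       gt_signif = 3) {
  stopifnot(sh_tsh > 0, severe_tsh > sh_tsh, antibody > 0)
  structure(list(
    constants = unclass(constants),
    curve = list(low = as.list(curve$low), high = as.list(curve$high),
                 boundary = curve$boundary),
    thresholds = list(sh_tsh = sh_tsh, severe_tsh = severe_tsh,
                      antibody = antibody),
    precision = list(group_pct_digits = group_pct_digits,
                     stratum_pct_digits = stratum_pct_digits,
                     gt_signif = gt_signif)
  ), class = "thyro_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()] object.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `thyro_config` equal to the one written.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "thyro_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(
    constants = do.call(spina_constants, raw$constants),
    curve = tsh_curve_params(low = unlist(raw$curve$low),
                             high = unlist(raw$curve$high),
                             boundary = raw$curve$boundary),
    sh_tsh = raw$thresholds$sh_tsh,
    severe_tsh = raw$thresholds$severe_tsh,
    antibody = raw$thresholds$antibody,
    group_pct_digits = raw$precision$group_pct_digits,
    stratum_pct_digits = raw$precision$stratum_pct_digits,
    gt_signif = raw$precision$gt_signif
  )
}

#' Read a cohort CSV
#'
#' Expects a comma-separated, UTF-8, '.'-decimal file with header
#' `id,age,sex,bmi,bmi_sds,tsh_miu_l,ft4_pmol_l,tg_ab_iu_ml,tpo_ab_iu_ml`;
#' empty fields are missing values. Rows with missing or non-positive TSH
#' or FT4 cannot enter any formula and are excluded; every exclusion is
#' reported with its line number via a message and recorded in the
#' `"exclusions"` attribute of the result.
#'
#' @param path Path to the CSV file.
#' @return A tibble with internal column names (`id, age, sex, bmi,
#'   bmi_sds, tsh, ft4, tg_ab, tpo_ab`), one row per retained subject.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(), age = readr::col_double(),
      sex = readr::col_character(), bmi = readr::col_double(),
      bmi_sds = readr::col_double(), tsh_miu_l = readr::col_double(),
      ft4_pmol_l = readr::col_double(), tg_ab_iu_ml = readr::col_double(),
      tpo_ab_iu_ml = readr::col_double()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(unname(cohort_schema), names(raw))
  if (length(missing_cols) > 0) {
    stop("Cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_problems <- readr::problems(raw)
  if (nrow(parse_problems) > 0) {
    warning(nrow(parse_problems), " field(s) failed to parse and were set to NA.",
            call. = FALSE)
  }
  out <- stats::setNames(raw[, unname(cohort_schema)], names(cohort_schema))
  bad_tsh <- is.na(out$tsh) | out$tsh <= 0
  bad_ft4 <- is.na(out$ft4) | out$ft4 <= 0
  bad <- bad_tsh | bad_ft4
  if (any(bad)) {
    # +1 for the header line
    lines <- which(bad) + 1L
    reasons <- ifelse(bad_tsh[bad] & bad_ft4[bad], "non-positive/missing TSH and FT4",
                      ifelse(bad_tsh[bad], "non-positive/missing TSH",
                             "non-positive/missing FT4"))
    excl <- tibble::tibble(line = lines, id = out$id[bad], reason = reasons)
    message("Excluded ", nrow(excl), " row(s): ",
            paste(sprintf("line %d (%s: %s)", excl$line, excl$id, excl$reason),
                  collapse = "; "))
    out <- out[!bad, ]
    attr(out, "exclusions") <- excl
  } else {
    attr(out, "exclusions") <- tibble::tibble(line = integer(), id = character(),
                                              reason = character())
  }
  out
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: writes the canonical header and maps internal
#' column names back to the file schema. Round-trips valid cohorts exactly.
#'
#' @param subjects Cohort tibble with internal column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(subjects, path) {
  out <- tibble::as_tibble(subjects)
  for (nm in names(cohort_schema)) {
    if (!nm %in% names(out)) out[[nm]] <- NA
  }
  out <- stats::setNames(out[, names(cohort_schema)], unname(cohort_schema))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

fmt_gt <- function(x, sig) ifelse(is.na(x), "", formatC(signif(x, sig), format = "fg"))

#' Render analysis reports to a directory
#'
#' Writes: a group-level comparison table (SH vs euthyroid, in the style of
#' a clinical "Table 1"), the stratum table of TSH ranges, median/mean
#' actual GT and antibody positivity, a companion table of predicted GT per
#' stratum, the per-subject augmented cohort, and the tidy comparison
#' results — each as CSV plus an aligned plain-text rendering of the
#' stratum table. Output is deterministic: re-rendering identical inputs is
#' byte-identical.
#'
#' @param analysis A `thyro_analysis` object from [analyze_cohort()].
#' @param dir Output directory (created if needed).
#' @param config A [run_config()] for formatting precisions.
#' @return Invisible character vector of the files written.
#' @export
render_report <- function(analysis, dir, config = run_config()) {
  stopifnot(inherits(analysis, "thyro_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aug <- analysis$subjects
  sig <- config$precision$gt_signif

  subj_path <- file.path(dir, "subjects_augmented.csv")
  subj_out <- aug
  subj_out$tsh_miu_l <- subj_out$tsh
  subj_out$ft4_pmol_l <- subj_out$ft4
  keep <- intersect(c("id", "group", "age", "sex", "bmi", "bmi_sds",
                      "tsh_miu_l", "ft4_pmol_l", "tg_ab", "tpo_ab", "status",
                      "stratum", "gt_actual_pmol_s", "tsh_predicted",
                      "gt_predicted_pmol_s"), names(subj_out))
  readr::write_csv(subj_out[, keep], subj_path, na = "")

  # Group-level demographics and thyroid indices (clinical "Table 1" style)
  grp <- aug
  grp$grp <- ifelse(grp$status == "euthyroid", "euthyroid", "SH")
  pdg <- config$precision$group_pct_digits
  msd <- function(x) sprintf("%.2f +/- %.2f", mean(x, na.rm = TRUE),
                             stats::sd(x, na.rm = TRUE))
  tab1 <- grp |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      n = dplyr::n(),
      age = if ("age" %in% names(grp)) msd(.data$age) else "",
      sex_m_f = if ("sex" %in% names(grp))
        sprintf("%d/%d", sum(.data$sex == "M", na.rm = TRUE),
                sum(.data$sex == "F", na.rm = TRUE)) else "",
      bmi_sds = if ("bmi_sds" %in% names(grp)) msd(.data$bmi_sds) else "",
      tsh_miu_l = msd(.data$tsh),
      ft4_pmol_l = msd(.data$ft4),
      ab_positive = {
        pos <- antibody_positive(.data$tg_ab, .data$tpo_ab,
                                 config$thresholds$antibody)
        sprintf("%d (%.*f%%)", sum(pos, na.rm = TRUE), pdg,
                100 * mean(pos, na.rm = TRUE))
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$grp == "SH"))
  tab1_path <- file.path(dir, "table1_groups.csv")
  readr::write_csv(tab1, tab1_path, na = "")

  # Stratum table: TSH range, actual GT, antibody positivity
  strata <- analysis$strata
  tab2 <- tibble::tibble(
    stratum = as.character(strata$stratum),
    tsh_min = strata$tsh_min,
    tsh_max = strata$tsh_max,
    gt_median = fmt_gt(strata$gt_actual_median, sig),
    gt_mean = fmt_gt(strata$gt_actual_mean, sig),
    ab_positive = sprintf("%s%% (%d/%d)",
                          ifelse(is.na(strata$ab_positive_pct), "NA",
                                 format(strata$ab_positive_pct, trim = TRUE)),
                          strata$ab_positive, strata$ab_assessed)
  )
  tab2_path <- file.path(dir, "table2_strata.csv")
  readr::write_csv(tab2, tab2_path, na = "")

  # Companion table: predicted GT per stratum (function of FT4 only)
  pred <- tibble::tibble(
    stratum = as.character(strata$stratum),
    gt_predicted_median = fmt_gt(strata$gt_predicted_median, sig),
    gt_predicted_mean = fmt_gt(strata$gt_predicted_mean, sig)
  )
  pred_path <- file.path(dir, "strata_predicted.csv")
  readr::write_csv(pred, pred_path, na = "")

  txt_path <- file.path(dir, "table2_strata.txt")
  txt <- utils::capture.output(print.data.frame(as.data.frame(tab2),
                                                row.names = FALSE))
  writeLines(txt, txt_path)

  cmp_path <- file.path(dir, "comparisons.csv")
  readr::write_csv(analysis$comparisons, cmp_path, na = "")

  invisible(c(subj_path, tab1_path, tab2_path, pred_path, txt_path, cmp_path))
}
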