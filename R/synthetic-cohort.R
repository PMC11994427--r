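#' Default antibody-positivity step function
#'
#' Positivity probability as a step function of measured TSH, with the
#' per-stratum frequencies of the reference pediatric cohort: rising from
#' under 4% in the lower euthyroid quartiles to 10-12% in the upper
#' quartiles and subclinical hypothyroidism, and ~17% in severe SH.
#'
#' @return A tibble with columns `tsh_hi` (upper bin edge, mIU/L, last is
#'   `Inf`) and `prob`.
#' @export
default_ab_prob <- function() {
  tibble::tibble(
    tsh_hi = c(2.25, 3.14, 3.82, 4.5, 10, Inf),
    prob = c(3 / 80, 3 / 77, 8 / 78, 6 / 78, 20 / 171, 2 / 12)
  )
}

group_row <- function(name, n, gt_meanlog, gt_sdlog, ft4_mean, ft4_sd,
                      tsh_lo, tsh_hi, ft4_lo = 0, ft4_hi = Inf,
                      age_lo, age_hi, male_prob, bmi_sds_mean, bmi_sds_sd) {
  tibble::tibble(
    name = name, n = as.integer(n),
    gt_meanlog = gt_meanlog, gt_sdlog = gt_sdlog,
    ft4_mean = ft4_mean, ft4_sd = ft4_sd,
    tsh_lo = tsh_lo, tsh_hi = tsh_hi, ft4_lo = ft4_lo, ft4_hi = ft4_hi,
    age_lo = age_lo, age_hi = age_hi, male_prob = male_prob,
    bmi_sds_mean = bmi_sds_mean, bmi_sds_sd = bmi_sds_sd
  )
}

#' Generative specification for a synthetic pediatric thyroid cohort
#'
#' Encodes the study conditions the generator emulates: a euthyroid group
#' (313 subjects, TSH 0.6-4.5 mIU/L, FT4 16.3 +/- 2.19 pmol/L) and a
#' subclinical-hypothyroidism group (183 subjects, TSH 4.5-15 mIU/L, FT4
#' 15.7 +/- 2.32 pmol/L within 10.43-24.5). Each subject carries an
#' individual set-point: a true secretory capacity drawn from a per-group
#' lognormal, whose interaction with the true FT4 determines the true TSH
#' through the algebraic inversion of the GT formula. Measured TSH and FT4
#' add multiplicative lognormal assay noise (default CV 5% each). The
#' per-group lognormal parameters default to values calibrated once so that
#' simulated measured TSH reproduces the reference group moments
#' (euthyroid 3.01 +/- 0.95, SH 6.7 +/- 2.05 mIU/L).
#'
#' @param n_euthyroid,n_sh Group sizes.
#' @param gt_meanlog_euthyroid,gt_sdlog_euthyroid Log-scale location/spread
#'   of true GT (pmol/s) in the euthyroid group.
#' @param gt_meanlog_sh,gt_sdlog_sh Same for the SH group.
#' @param ft4_mean_euthyroid,ft4_sd_euthyroid True FT4 distribution, pmol/L.
#' @param ft4_mean_sh,ft4_sd_sh Same for the SH group.
#' @param tsh_range_euthyroid,tsh_range_sh Admissible measured TSH interval
#'   `(lo, hi]` per group, mIU/L.
#' @param ft4_range_sh Admissible measured FT4 interval for SH (the normal
#'   range that defines SH), pmol/L.
#' @param noise_cv_tsh,noise_cv_ft4 Relative assay error (coefficient of
#'   variation) applied multiplicatively; 0 disables noise.
#' @param ab_prob Antibody-positivity probability: tibble with `tsh_hi`
#'   (ascending upper bin edges ending in `Inf`) and `prob`; see
#'   [default_ab_prob()].
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec including the seed.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_cohort()], [stratified_synthetic_spec()]
#' @export
synthetic_spec <- function(n_euthyroid = 313,
                           n_sh = 183,
                           gt_meanlog_euthyroid = log(1.35),
                           gt_sdlog_euthyroid = 0.40,
                           gt_meanlog_sh = log(2.0),
                           gt_sdlog_sh = 0.10,
                           ft4_mean_euthyroid = 16.3,
                           ft4_sd_euthyroid = 2.19,
                           ft4_mean_sh = 15.7,
                           ft4_sd_sh = 2.32,
                           tsh_range_euthyroid = c(0.6, 4.5),
                           tsh_range_sh = c(4.5, 15),
                           ft4_range_sh = c(10.43, 24.5),
                           noise_cv_tsh = 0.05,
                           noise_cv_ft4 = 0.05,
                           ab_prob = default_ab_prob(),
                           seed = 1L) {
  groups <- dplyr::bind_rows(
    group_row("euthyroid", n_euthyroid, gt_meanlog_euthyroid, gt_sdlog_euthyroid,
              ft4_mean_euthyroid, ft4_sd_euthyroid,
              tsh_range_euthyroid[1], tsh_range_euthyroid[2],
              age_lo = 1.3, age_hi = 16.7, male_prob = 145 / 313,
              bmi_sds_mean = 1.03, bmi_sds_sd = 1.59),
    group_row("sh", n_sh, gt_meanlog_sh, gt_sdlog_sh,
              ft4_mean_sh, ft4_sd_sh,
              tsh_range_sh[1], tsh_range_sh[2],
              ft4_lo = ft4_range_sh[1], ft4_hi = ft4_range_sh[2],
              age_lo = 1, age_hi = 14.9, male_prob = 84 / 183,
              bmi_sds_mean = 1.11, bmi_sds_sd = 1.46)
  )
  new_synthetic_spec(groups, noise_cv_tsh, noise_cv_ft4, ab_prob, seed)
}

new_synthetic_spec <- function(groups, noise_cv_tsh, noise_cv_ft4, ab_prob, seed) {
  stopifnot(
    all(groups$n > 0), all(groups$gt_sdlog >= 0), all(groups$ft4_sd > 0),
    all(groups$tsh_lo < groups$tsh_hi), all(groups$tsh_lo >= 0),
    noise_cv_tsh >= 0, noise_cv_ft4 >= 0,
    is.data.frame(ab_prob), all(c("tsh_hi", "prob") %in% names(ab_prob)),
    !is.unsorted(ab_prob$tsh_hi), all(ab_prob$prob >= 0 & ab_prob$prob <= 1),
    is.numeric(seed), length(seed) == 1L
  )
  structure(list(groups = groups, noise_cv_tsh = noise_cv_tsh,
                 noise_cv_ft4 = noise_cv_ft4, ab_prob = ab_prob,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Six-stratum generative specification for recovery experiments
#'
#' A variant of [synthetic_spec()] with one generating group per reporting
#' stratum — the four euthyroid TSH quartiles plus mild and severe SH —
#' using the reference cohort's printed TSH ranges, group sizes
#' (80/77/78/78/171/12), and per-stratum median secretory capacities as the
#' lognormal medians. Intended as input to [recovery_experiment()]: the
#' generator truth is per-stratum, so estimator bias can be read off
#' directly.
#'
#' @param gt_medians True GT medians (pmol/s) for Q1..Q4, mild SH, severe SH.
#' @param gt_sdlog Common log-scale spread of true GT within a stratum.
#' @param n Group sizes for the six strata.
#' @param noise_cv_tsh,noise_cv_ft4,seed As in [synthetic_spec()].
#' @return An object of class `synthetic_spec`.
#' @export
stratified_synthetic_spec <- function(gt_medians = c(3.21, 2.53, 2.20, 1.70, 1.77, 1.29),
                                      gt_sdlog = 0.15,
                                      n = c(80, 77, 78, 78, 171, 12),
                                      noise_cv_tsh = 0.05,
                                      noise_cv_ft4 = 0.05,
                                      seed = 1L) {
  stopifnot(length(gt_medians) == 6, length(n) == 6)
  tsh_lo <- c(0.6, 2.26, 3.15, 3.85, 4.5, 10.23)
  tsh_hi <- c(2.25, 3.14, 3.82, 4.47, 9.93, 14)
  eu <- seq_len(4)
  groups <- dplyr::bind_rows(lapply(seq_len(6), function(i) {
    group_row(
      stratum_levels[i], n[i], log(gt_medians[i]), gt_sdlog,
      ft4_mean = if (i %in% eu) 16.3 else 15.7,
      ft4_sd = if (i %in% eu) 2.19 else 2.32,
      tsh_lo = tsh_lo[i], tsh_hi = tsh_hi[i],
      ft4_lo = if (i %in% eu) 0 else 10.43,
      ft4_hi = if (i %in% eu) Inf else 24.5,
      age_lo = if (i %in% eu) 1.3 else 1,
      age_hi = if (i %in% eu) 16.7 else 14.9,
      male_prob = if (i %in% eu) 145 / 313 else 84 / 183,
      bmi_sds_mean = if (i %in% eu) 1.03 else 1.11,
      bmi_sds_sd = if (i %in% eu) 1.59 else 1.46
    )
  }))
  new_synthetic_spec(groups, noise_cv_tsh, noise_cv_ft4, default_ab_prob(), seed)
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s) # mean exactly 1
}

generate_group <- function(g, spec, constants) {
  n <- g$n
  acc <- list()
  got <- 0L
  attempted <- 0L
  batch <- max(2000L, 10L * n)
  repeat {
    ft4_true <- stats::rnorm(batch, g$ft4_mean, g$ft4_sd)
    gt_true <- stats::rlnorm(batch, g$gt_meanlog, g$gt_sdlog)
    ok <- ft4_true > 0
    ok[ok] <- gt_true[ok] > min_feasible_gt(ft4_true[ok], constants)
    tsh_true <- rep(NA_real_, batch)
    tsh_true[ok] <- invert_gt(gt_true[ok], ft4_true[ok], constants)
    tsh <- tsh_true * lognormal_noise(batch, spec$noise_cv_tsh)
    ft4 <- ft4_true * lognormal_noise(batch, spec$noise_cv_ft4)
    keep <- ok & tsh > g$tsh_lo & tsh <= g$tsh_hi &
      ft4 >= g$ft4_lo & ft4 <= g$ft4_hi & ft4 > 0
    keep[is.na(keep)] <- FALSE
    attempted <- attempted + batch
    if (any(keep)) {
      acc[[length(acc) + 1L]] <- tibble::tibble(
        ft4_true = ft4_true[keep], gt_true = gt_true[keep],
        tsh_true = tsh_true[keep], tsh = tsh[keep], ft4 = ft4[keep]
      )
      got <- got + sum(keep)
    }
    if (got >= n) break
    if (attempted >= batch && got / attempted < 0.01) {
      mg <- min_feasible_gt(g$ft4_mean, constants)
      stop(sprintf(paste0(
        "Synthetic group '%s': rejection rate above 99%%. At FT4 = %.3g pmol/L ",
        "the feasible capacity region is gt > %.3g pmol/s, and measured TSH in ",
        "(%.3g, %.3g] requires true gt roughly in [%.3g, %.3g] pmol/s; the ",
        "configured lognormal (median %.3g, sdlog %.3g) puts almost no mass there."),
        g$name, g$ft4_mean, mg,
        g$tsh_lo, g$tsh_hi,
        mg * (1 + constants$d_t / g$tsh_hi), mg * (1 + constants$d_t / g$tsh_lo),
        exp(g$gt_meanlog), g$gt_sdlog), call. = FALSE)
    }
  }
  out <- dplyr::bind_rows(acc)[seq_len(n), ]
  # antibodies: Bernoulli by TSH-binned probability, values drawn around the cut-off
  edges <- spec$ab_prob$tsh_hi
  idx <- findInterval(out$tsh, edges[-length(edges)], left.open = TRUE) + 1L
  p <- spec$ab_prob$prob[idx]
  pos <- stats::runif(n) < p
  which_assay <- stats::runif(n) # <0.30 both, <0.75 TPO only, else TG only
  tg_pos <- pos & (which_assay < 0.30 | which_assay >= 0.75)
  tpo_pos <- pos & which_assay < 0.75
  draw_pos <- function(k) 34 * (1 + stats::rlnorm(k, meanlog = log(2), sdlog = 1))
  tg_ab <- stats::runif(n, 1, 30)
  tpo_ab <- stats::runif(n, 1, 30)
  tg_ab[tg_pos] <- draw_pos(sum(tg_pos))
  tpo_ab[tpo_pos] <- draw_pos(sum(tpo_pos))
  out$age <- round(stats::runif(n, g$age_lo, g$age_hi), 2)
  out$sex <- ifelse(stats::runif(n) < g$male_prob, "M", "F")
  out$bmi_sds <- round(stats::rnorm(n, g$bmi_sds_mean, g$bmi_sds_sd), 2)
  out$tg_ab <- round(tg_ab, 1)
  out$tpo_ab <- round(tpo_ab, 1)
  out$group <- g$name
  out
}

#' Generate a synthetic cohort
#'
#' Draws, per subject: a true FT4 from the group Normal (truncated to
#' positive values), a true secretory capacity from the group lognormal
#' (rejecting draws infeasible at that FT4), the implied true TSH via
#' [invert_gt()], and multiplicative lognormal assay noise on both analytes;
#' subjects are rejected and redrawn until measured TSH lies in the group's
#' admissible range (and measured FT4 in its range, where one is set).
#' Antibody status is assigned by Bernoulli draws with TSH-dependent
#' probability; positive assays receive values above the 34 IU/mL cut-off,
#' negative ones below. The result is deterministic for a fixed spec.
#'
#' @param spec A [synthetic_spec()] or [stratified_synthetic_spec()] object.
#' @param constants A [spina_constants()] object.
#' @return An object of class `synthetic_cohort`: a list with `subjects`
#'   (tibble: id, group, age, sex, bmi_sds, tsh, ft4, tg_ab, tpo_ab) and
#'   `truth` (tibble: id, group, gt_true_pmol_s, tsh_true, ft4_true), plus
#'   the spec used.
#' @examples
#' cohort <- generate_cohort(synthetic_spec(seed = 7))
#' head(cohort$subjects)
#' @export
generate_cohort <- function(spec, constants = spina_constants()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  rows <- lapply(seq_len(nrow(spec$groups)), function(i) {
    generate_group(spec$groups[i, ], spec, constants)
  })
  all <- dplyr::bind_rows(rows)
  all$id <- sprintf("S%04d", seq_len(nrow(all)))
  subjects <- tibble::tibble(
    id = all$id, group = all$group, age = all$age, sex = all$sex,
    bmi = NA_real_, bmi_sds = all$bmi_sds,
    tsh = all$tsh, ft4 = all$ft4, tg_ab = all$tg_ab, tpo_ab = all$tpo_ab
  )
  truth <- tibble::tibble(
    id = all$id, group = all$group,
    gt_true_pmol_s = all$gt_true, tsh_true = all$tsh_true, ft4_true = all$ft4_true
  )
  structure(list(subjects = subjects, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic thyroid cohort: %d subjects in %d group(s), seed %d\n",
              nrow(x$subjects), nrow(x$spec$groups), x$spec$seed))
  print(dplyr::count(x$subjects, .data$group))
  invisible(x)
}

#' Qualitative stratum ordering of median secretory capacity
#'
#' Checks the orderings reported for this kind of cohort on the per-stratum
#' medians of actual GT. The *core* ordering matches the headline findings:
#' Q1 above Q2, the pooled upper two euthyroid quartiles (Q3 and Q4
#' combined, which is how SH is compared against the upper euthyroid range)
#' above mild SH, and mild SH above severe SH. The *full* ordering is the
#' stricter monotone chain Q1 > Q2 >= Q3 >= Q4 > mild SH > severe SH.
#'
#' @param analysis A `thyro_analysis` from [analyze_cohort()].
#' @return A list with logical elements `core` and `full` (`NA` when a
#'   stratum is empty).
#' @export
stratum_gt_ordering <- function(analysis) {
  stopifnot(inherits(analysis, "thyro_analysis"))
  s <- analysis$strata
  m <- stats::setNames(s$gt_actual_median, as.character(s$stratum))[stratum_levels]
  if (anyNA(m)) return(list(core = NA, full = NA))
  aug <- analysis$subjects
  upper2 <- stats::median(aug$gt_actual_pmol_s[aug$stratum %in% c("Q3", "Q4")])
  core <- m[["Q1"]] > m[["Q2"]] && upper2 > m[["mild_SH"]] &&
    m[["mild_SH"]] > m[["severe_SH"]]
  full <- m[["Q1"]] > m[["Q2"]] && m[["Q2"]] >= m[["Q3"]] && m[["Q3"]] >= m[["Q4"]] &&
    m[["Q4"]] > m[["mild_SH"]] && m[["mild_SH"]] > m[["severe_SH"]]
  list(core = core, full = full)
}

#' Parameter-recovery experiment for the cohort pipeline
#'
#' Repeatedly generates cohorts from `spec`, runs the full analysis
#' pipeline, and compares the estimated per-stratum median secretory
#' capacity (from noisy measured TSH/FT4) against the generating truth (the
#' median of the hidden true GT of the same subjects). Also records how
#' often the qualitative stratum ordering of median GT is recovered, in the
#' two forms checked by [stratum_gt_ordering()].
#'
#' @param spec A [synthetic_spec()] or [stratified_synthetic_spec()];
#'   replicate `r` uses seed `spec$seed + r`.
#' @param n_replicates Number of replicate cohorts (>= 1).
#' @param constants A [spina_constants()] object.
#' @return A list with `per_replicate` (tibble: replicate, stratum, n,
#'   gt_est_median, gt_true_median, rel_err), `summary` (per-stratum bias in
#'   percent, RMSE of the median in pmol/s, and the largest absolute
#'   relative error in percent), and `ordering` (recovery rates of the core
#'   and full orderings).
#' @export
recovery_experiment <- function(spec, n_replicates, constants = spina_constants()) {
  stopifnot(inherits(spec, "synthetic_spec"), n_replicates >= 1)
  reps <- lapply(seq_len(n_replicates), function(r) {
    spec_r <- spec
    spec_r$seed <- spec$seed + r
    cohort <- generate_cohort(spec_r, constants)
    fit <- analyze_cohort(cohort$subjects, constants)
    joined <- dplyr::inner_join(
      fit$subjects[, c("id", "stratum", "gt_actual_pmol_s")],
      cohort$truth[, c("id", "gt_true_pmol_s")], by = "id"
    )
    per_stratum <- joined |>
      dplyr::group_by(stratum = factor(.data$stratum, levels = stratum_levels),
                      .drop = FALSE) |>
      dplyr::summarise(
        n = dplyr::n(),
        gt_est_median = stats::median(.data$gt_actual_pmol_s),
        gt_true_median = stats::median(.data$gt_true_pmol_s),
        .groups = "drop"
      ) |>
      dplyr::mutate(replicate = r,
                    rel_err = (.data$gt_est_median - .data$gt_true_median) /
                      .data$gt_true_median)
    ord <- stratum_gt_ordering(fit)
    list(per_stratum = per_stratum, core = ord$core, full = ord$full)
  })
  per_replicate <- dplyr::bind_rows(lapply(reps, `[[`, "per_stratum"))
  summary <- per_replicate |>
    dplyr::filter(.data$n > 0) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      bias_pct = 100 * mean(.data$rel_err),
      rmse = sqrt(mean((.data$gt_est_median - .data$gt_true_median)^2)),
      max_abs_rel_err_pct = 100 * max(abs(.data$rel_err)),
      .groups = "drop"
    )
  list(
    per_replicate = per_replicate,
    summary = summary,
    ordering = tibble::tibble(
      core_rate = mean(vapply(reps, `[[`, TRUE, "core")),
      full_rate = mean(vapply(reps, `[[`, TRUE, "full"))
    )
  )
}
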