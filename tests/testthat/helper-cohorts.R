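# Small in-code fixtures shared across test files.

# A minimal hand-built cohort spanning all six strata: 8 euthyroid subjects
# with equally spaced TSH (quartiles of size 2), one mild and one severe SH.
tiny_cohort <- function() {
  tibble::tibble(
    id = sprintf("T%02d", 1:10),
    age = c(rep(8, 8), 7, 6),
    sex = rep(c("M", "F"), 5),
    bmi = NA_real_,
    bmi_sds = 0,
    tsh = c(seq(0.8, 4.3, length.out = 8), 6.7, 10.23),
    ft4 = c(rep(16.3, 8), 15.7, 15.7),
    tg_ab = c(50, rep(10, 9)),
    tpo_ab = rep(10, 10)
  )
}

# A stratum of n subjects with identical hormone values, n_pos of them
# antibody positive; used for positivity-percentage arithmetic.
positivity_stratum <- function(n, n_pos, tsh = 6.7, ft4 = 15.7) {
  tibble::tibble(
    id = sprintf("P%03d", seq_len(n)),
    tsh = tsh, ft4 = ft4,
    tg_ab = c(rep(100, n_pos), rep(5, n - n_pos)),
    tpo_ab = 5
  )
}
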