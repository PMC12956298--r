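#' Default per-group covariate distributions
#'
#' Group-wise means and SDs used by [generate_subject_table()]: global
#' cognitive T-score (GlobalT), age (years), education (years), relative
#' mean displacement (RMD, mm), and the male / non-White proportions.
#' Values mirror the demographic structure of a four-group HIV x marijuana
#' cohort study (HIV-MJ- control, HIV+MJ-, HIV-MJ+, HIV+MJ+).
#'
#' @return a data.frame, one row per group.
#' @export
default_group_profiles <- function() {
  data.frame(
    group      = c("HIV-MJ-", "HIV+MJ-", "HIV-MJ+", "HIV+MJ+"),
    hiv        = c(0L, 1L, 0L, 1L),
    mj         = c(0L, 0L, 1L, 1L),
    globalT_mean = c(50.45, 48.85, 50.59, 47.27),
    globalT_sd   = c(5.91, 5.29, 5.65, 5.21),
    age_mean   = c(38.86, 39.09, 36.43, 37.81),
    age_sd     = c(9.23, 8.09, 7.83, 8.68),
    edu_mean   = c(16.24, 15.35, 14.33, 14.22),
    edu_sd     = c(2.13, 2.60, 2.38, 2.41),
    rmd_mean   = c(0.10, 0.10, 0.10, 0.11),
    rmd_sd     = c(0.03, 0.05, 0.04, 0.05),
    p_male     = c(44 / 59, 51 / 62, 41 / 53, 53 / 63),
    p_nonwhite = c(35 / 59, 38 / 62, 36 / 53, 45 / 63),
    stringsAsFactors = FALSE
  )
}

#' Generate a balanced synthetic subject table
#'
#' Draws `n_per_group` subjects in each of the four HIV x MJ cells with
#' covariates from group-specific normal / Bernoulli distributions
#' ([default_group_profiles()]). RMD is drawn from a normal truncated to
#' (0, rmd_max) so all generated subjects pass the motion QC rule by
#' default. Deterministic given `seed`.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param seed integer seed.
#' @param profiles optional replacement for [default_group_profiles()]
#'   (same columns).
#' @param rmd_max upper truncation for RMD draws (mm).
#' @return data.frame of class `subject_table` with columns subject_id,
#'   group, hiv, mj, globalT, age, sex (1 = male), race (1 = non-White),
#'   education, rmd.
#' @export
generate_subject_table <- function(n_per_group, seed = 1L, profiles = NULL,
                                   rmd_max = 0.3) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (is.null(profiles)) profiles <- default_group_profiles()
  set.seed(seed)
  rows <- lapply(seq_len(nrow(profiles)), function(g) {
    pr <- profiles[g, ]
    rmd <- numeric(n_per_group)
    for (i in seq_len(n_per_group)) {
      repeat {
        r <- rnorm(1, pr$rmd_mean, pr$rmd_sd)
        if (r > 0 && r < rmd_max) break
      }
      rmd[i] <- r
    }
    data.frame(
      subject_id = sprintf("s%d%03d", g, seq_len(n_per_group)),
      group = pr$group, hiv = pr$hiv, mj = pr$mj,
      globalT = rnorm(n_per_group, pr$globalT_mean, pr$globalT_sd),
      age = rnorm(n_per_group, pr$age_mean, pr$age_sd),
      sex = rbinom(n_per_group, 1, pr$p_male),
      race = rbinom(n_per_group, 1, pr$p_nonwhite),
      education = rnorm(n_per_group, pr$edu_mean, pr$edu_sd),
      rmd = rmd,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(all(out$rmd >= 0), all(is.finite(out$globalT)))
  class(out) <- c("subject_table", "data.frame")
  out
}

#' Motion quality-control filter
#'
#' Retains subjects whose relative mean displacement (RMD) is strictly
#' below `rmd_threshold` mm; excluded subjects are logged with the reason.
#'
#' @param subjects a subject table (needs subject_id and rmd columns).
#' @param rmd_threshold QC threshold in mm (default 0.3, strict `<`).
#' @return list with `retained` (subject table subset) and `excluded`
#'   (data.frame subject_id, rmd, reason).
#' @export
qc_filter_subjects <- function(subjects, rmd_threshold = 0.3) {
  if (nrow(subjects) == 0) {
    return(list(retained = subjects,
                excluded = data.frame(subject_id = character(),
                                      rmd = numeric(),
                                      reason = character())))
  }
  keep <- subjects$rmd < rmd_threshold
  excluded <- data.frame(
    subject_id = subjects$subject_id[!keep],
    rmd = subjects$rmd[!keep],
    reason = sprintf("rmd %.4f >= %.4f mm", subjects$rmd[!keep],
                     rmd_threshold),
    stringsAsFactors = FALSE
  )
  list(retained = subjects[keep, , drop = FALSE], excluded = excluded)
}

#' Read / write a subject table as CSV
#' @param subjects subject table.
#' @param path file path.
#' @export
write_subject_table <- function(subjects, path) {
  write.csv(as.data.frame(subjects), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("subject_table", "data.frame")
  out
}
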