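# Repeated-scan precision statistics: paired differences, relative percent
# difference (100 * |v1 - v2| / mean(v1, v2)), paired t-test with 95% CI,
# two-sample rank-sum comparison with Hodges-Lehmann shift, WHO BMI classes,
# and cohort summary tables. All user-facing functions take and return
# tibbles so they chain with the pipe.

#' Pair repeated volume measurements
#'
#' Joins scan 1 and scan 2 of every subject-side and derives the paired
#' precision metrics: `mean_volume = (v1 + v2) / 2`, `abs_diff = |v1 - v2|`,
#' `rel_diff_pct = 100 * abs_diff / mean_volume`. The relative difference is
#' the precision metric for repeated scans: symmetric in the pair and
#' invariant under a common rescaling of both volumes.
#'
#' @param measurements Tibble with columns `subject_id`, `scan_index` (1, 2),
#'   `side`, `variant`, `volume_ml` (from [measure_leg()]).
#' @return Tibble with one row per subject-side: `subject_id`, `side`,
#'   `variant`, `v1`, `v2`, `mean_volume`, `abs_diff`, `rel_diff_pct`.
#' @examples
#' m <- tibble::tibble(subject_id = "s1", scan_index = 1:2, side = "left",
#'                     variant = "complete", volume_ml = c(9045, 8955))
#' pair_measurements(m)  # mean 9000 mL, deviation 90 mL, 1%
#' @export
pair_measurements <- function(measurements) {
  required <- c("subject_id", "scan_index", "side", "variant", "volume_ml")
  if (!all(required %in% names(measurements))) {
    legvol_abort(paste0("measurements need columns: ", paste(required, collapse = ", ")),
                 "legvol_pairing_error")
  }
  bad <- measurements |>
    dplyr::count(.data$subject_id, .data$side, .data$scan_index) |>
    dplyr::filter(.data$n != 1L)
  if (nrow(bad) > 0) {
    legvol_abort(paste0("duplicate scan for subject/side: ",
                        paste(bad$subject_id, bad$side, collapse = "; ")),
                 "legvol_pairing_error")
  }
  counts <- measurements |>
    dplyr::count(.data$subject_id, .data$side) |>
    dplyr::filter(.data$n != 2L)
  if (nrow(counts) > 0) {
    legvol_abort(paste0("missing scan for subject/side: ",
                        paste(counts$subject_id, counts$side, collapse = "; ")),
                 "legvol_pairing_error")
  }
  pairs <- measurements |>
    dplyr::select(dplyr::all_of(required)) |>
    tidyr::pivot_wider(names_from = "scan_index", values_from = "volume_ml",
                       names_prefix = "v") |>
    dplyr::mutate(mean_volume = (.data$v1 + .data$v2) / 2,
                  abs_diff = abs(.data$v1 - .data$v2))
  if (any(pairs$mean_volume <= 0)) {
    legvol_abort("paired mean volume must be positive (both-zero pair?)",
                 "legvol_domain_error")
  }
  dplyr::mutate(pairs, rel_diff_pct = 100 * .data$abs_diff / .data$mean_volume)
}

#' Paired t-test of repeated volume samples
#'
#' Two-sided paired t-test of `v1 - v2` with `df = n - 1` and the 95% CI from
#' the t quantiles, as used to compare repeated whole-body scan volumes. Zero
#' difference variance is flagged (t undefined) while the mean difference is
#' still reported.
#'
#' @param v1,v2 Paired numeric samples of equal length (mL).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `legvol_paired_t` with fields `mean_dif`, `ci95`,
#'   `t_stat`, `df`, `p_value`, `n`, `zero_variance`.
#' @export
paired_t_test <- function(v1, v2, conf_level = 0.95) {
  if (length(v1) != length(v2)) {
    legvol_abort("paired samples must have equal length", "legvol_sample_size")
  }
  n <- length(v1)
  if (n < 2L) legvol_abort("paired t-test needs n >= 2", "legvol_sample_size")
  d <- v1 - v2
  if (stats::sd(d) == 0) {
    res <- list(mean_dif = mean(d), ci95 = c(mean(d), mean(d)),
                t_stat = NA_real_, df = n - 1L, p_value = NA_real_,
                n = n, zero_variance = TRUE)
    return(structure(res, class = "legvol_paired_t"))
  }
  tt <- stats::t.test(v1, v2, paired = TRUE, conf.level = conf_level)
  structure(list(mean_dif = unname(tt$estimate), ci95 = as.numeric(tt$conf.int),
                 t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, n = n, zero_variance = FALSE),
            class = "legvol_paired_t")
}

#' @export
print.legvol_paired_t <- function(x, ...) {
  cat(sprintf("Paired t-test: mean dif %.3f mL (95%% CI %.3f to %.3f), t(%d) = %s, p = %s%s\n",
              x$mean_dif, x$ci95[1], x$ci95[2], x$df,
              if (is.na(x$t_stat)) "NA" else sprintf("%.3f", x$t_stat),
              if (is.na(x$p_value)) "NA" else sprintf("%.3g", x$p_value),
              if (x$zero_variance) " [zero difference variance]" else ""))
  invisible(x)
}

#' Two-sample rank-sum comparison
#'
#' Wilcoxon rank-sum / Mann-Whitney comparison of two independent samples
#' (e.g. relative differences of the complete vs limited visibility
#' workflows). `W` is the Mann-Whitney statistic of `group_a`: the number of
#' pairs (a, b) with a > b, ties counted 1/2. The p-value is exact (full
#' enumeration) when `n_a + n_b <= 12` and the data are tie-free, otherwise a
#' normal approximation with midranks, tie correction and continuity
#' correction is used. The location-shift estimate is the Hodges-Lehmann
#' median of all pairwise differences a - b, with its CI obtained by test
#' inversion.
#'
#' @param group_a,group_b Numeric samples.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`); default `NULL`
#'   applies the size/ties rule above.
#' @param conf_level Confidence level for the shift CI.
#' @return Object of class `legvol_rank_sum` with fields `W`, `p_value`,
#'   `hl_shift`, `ci95`, `exact`, `n_a`, `n_b`.
#' @export
rank_sum_test <- function(group_a, group_b, exact = NULL, conf_level = 0.95) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    legvol_abort("both groups must be non-empty", "legvol_sample_size")
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  if (is.null(exact)) exact <- (length(group_a) + length(group_b) <= 12L) && !ties
  if (length(unique(c(group_a, group_b))) == 1L) {
    # all observations identical: no evidence of a shift in any direction
    return(structure(list(W = length(group_a) * length(group_b) / 2,
                          p_value = 1, hl_shift = 0,
                          ci95 = c(NA_real_, NA_real_), exact = FALSE,
                          n_a = length(group_a), n_b = length(group_b)),
                     class = "legvol_rank_sum"))
  }
  wt <- tryCatch(
    suppressWarnings(
      stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE,
                         conf.int = TRUE, conf.level = conf_level)),
    error = function(e)
      # shift CI is undefined for degenerate samples (e.g. all differences
      # equal); keep the test itself
      suppressWarnings(
        stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE,
                           conf.int = FALSE)))
  hl <- stats::median(as.numeric(outer(group_a, group_b, "-")))
  structure(list(W = unname(wt$statistic), p_value = wt$p.value,
                 hl_shift = hl,
                 ci95 = if (is.null(wt$conf.int)) c(NA_real_, NA_real_) else
                   as.numeric(wt$conf.int),
                 exact = exact, n_a = length(group_a), n_b = length(group_b)),
            class = "legvol_rank_sum")
}

#' @export
print.legvol_rank_sum <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): W = %g, p = %.4g, shift = %.4g (95%% CI %.4g to %.4g)\n",
              if (x$exact) "exact" else "normal approximation",
              x$W, x$p_value, x$hl_shift, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' WHO BMI classification
#'
#' Half-open bins partitioning the positive line: underweight below 18.5,
#' normal [18.5, 25), pre-obesity [25, 30), obesity I [30, 35), obesity II
#' [35, 40), obesity III from 40 up. The published class edges leave printed
#' gaps (24.9 vs 25.0); half-open intervals close them deterministically, and
#' a boundary value such as 25.0 falls in the upper class.
#'
#' @param bmi Numeric vector, kg/m^2, positive.
#' @return Factor with levels `underweight`, `normal`, `pre-obesity`,
#'   `obesity I`, `obesity II`, `obesity III`.
#' @examples
#' classify_bmi(c(26.4, 55.8, 25.0))
#' @export
classify_bmi <- function(bmi) {
  if (any(!is.finite(bmi) | bmi <= 0)) {
    legvol_abort("BMI must be positive and finite", "legvol_domain_error")
  }
  cut(bmi, breaks = c(0, 18.5, 25, 30, 35, 40, Inf), right = FALSE,
      labels = c("underweight", "normal", "pre-obesity",
                 "obesity I", "obesity II", "obesity III"))
}

#' Cohort summary of repeated leg volumes
#'
#' Per cohort (all subjects, and each workflow variant) and per side: mean and
#' SD of the first and second scan volumes, the mean paired difference with
#' its 95% CI (paired t), and mean, SD and range of the relative percent
#' difference.
#'
#' @param records Subject tibble with columns `subject_id`, `variant` (and
#'   optionally demographics).
#' @param pairs Paired-measurement tibble from [pair_measurements()].
#' @return Tibble with one row per cohort x side.
#' @export
cohort_summary <- function(records, pairs) {
  if (nrow(pairs) == 0L) legvol_abort("empty cohort", "legvol_empty_result")
  pairs <- dplyr::inner_join(pairs,
                             dplyr::select(records, "subject_id", subject_variant = "variant"),
                             by = "subject_id")
  if (nrow(pairs) == 0L) legvol_abort("no overlap between records and pairs",
                                      "legvol_empty_result")
  one <- function(df, label) {
    df |>
      dplyr::group_by(.data$side) |>
      dplyr::group_modify(function(g, key) {
        tt <- paired_t_test(g$v1, g$v2)
        tibble::tibble(n = nrow(g),
                       v1_mean = mean(g$v1), v1_sd = stats::sd(g$v1),
                       v2_mean = mean(g$v2), v2_sd = stats::sd(g$v2),
                       mean_dif = tt$mean_dif,
                       ci_low = tt$ci95[1], ci_high = tt$ci95[2],
                       rel_mean = mean(g$rel_diff_pct),
                       rel_sd = stats::sd(g$rel_diff_pct),
                       rel_min = min(g$rel_diff_pct),
                       rel_max = max(g$rel_diff_pct))
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(cohort = label, .before = 1)
  }
  out <- list(one(pairs, "all"))
  for (v in sort(unique(pairs$subject_variant))) {
    out[[length(out) + 1L]] <- one(dplyr::filter(pairs, .data$subject_variant == v), v)
  }
  dplyr::bind_rows(out)
}

#' Demographic summary by cohort
#'
#' Mean, SD and range of age and BMI, and the sex split, for the whole cohort
#' and each workflow variant subgroup.
#'
#' @param records Subject tibble with `subject_id`, `age`, `sex`, `bmi`,
#'   `variant`.
#' @return Tibble with one row per cohort.
#' @export
demographic_summary <- function(records) {
  one <- function(df, label) {
    tibble::tibble(cohort = label, n = nrow(df),
                   n_female = sum(df$sex == "female"),
                   n_male = sum(df$sex == "male"),
                   age_mean = mean(df$age), age_sd = stats::sd(df$age),
                   age_min = min(df$age), age_max = max(df$age),
                   bmi_mean = mean(df$bmi), bmi_sd = stats::sd(df$bmi),
                   bmi_min = min(df$bmi), bmi_max = max(df$bmi))
  }
  dplyr::bind_rows(c(list(one(records, "all")),
                     lapply(sort(unique(records$variant)), function(v)
                       one(dplyr::filter(records, .data$variant == v), v))))
}

#' Compare workflow variants on relative difference
#'
#' Per side, rank-sum comparison of the relative percent differences of the
#' complete-visibility vs limited-visibility subgroups.
#'
#' @param pairs Paired-measurement tibble (with `variant` column).
#' @return Tibble with one row per side: `W`, `p_value`, `hl_shift`, CI.
#' @export
compare_variants <- function(pairs) {
  pairs |>
    dplyr::group_by(.data$side) |>
    dplyr::group_modify(function(g, key) {
      a <- g$rel_diff_pct[g$variant == "complete"]
      b <- g$rel_diff_pct[g$variant == "limited"]
      if (length(a) == 0L || length(b) == 0L) {
        return(tibble::tibble(W = NA_real_, p_value = NA_real_,
                              hl_shift = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, n_complete = length(a),
                              n_limited = length(b)))
      }
      rs <- rank_sum_test(a, b)
      tibble::tibble(W = rs$W, p_value = rs$p_value, hl_shift = rs$hl_shift,
                     ci_low = rs$ci95[1], ci_high = rs$ci95[2],
                     n_complete = length(a), n_limited = length(b))
    }) |>
    dplyr::ungroup()
}

# ---- broom-style tidiers ----------------------------------------------------

#' Tidy a paired t-test result
#' @param x A `legvol_paired_t`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.legvol_paired_t <- function(x, ...) {
  tibble::tibble(estimate = x$mean_dif, conf.low = x$ci95[1],
                 conf.high = x$ci95[2], statistic = x$t_stat,
                 df = x$df, p.value = x$p_value)
}

#' Tidy a rank-sum result
#' @param x A `legvol_rank_sum`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.legvol_rank_sum <- function(x, ...) {
  tibble::tibble(estimate = x$hl_shift, conf.low = x$ci95[1],
                 conf.high = x$ci95[2], statistic = x$W, p.value = x$p_value,
                 method = if (x$exact) "exact" else "normal approximation")
}

#' Glance at a paired t-test result
#' @param x A `legvol_paired_t`.
#' @param ... Unused.
#' @return One-row tibble with sample size and flags.
#' @export
glance.legvol_paired_t <- function(x, ...) {
  tibble::tibble(n = x$n, zero_variance = x$zero_variance)
}
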