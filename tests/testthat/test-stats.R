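test_that("pairing computes mean, absolute and relative difference", {
  m <- tibble::tibble(subject_id = "s1", scan_index = 1:2, side = "left",
                      variant = "complete", volume_ml = c(9045, 8955))
  p <- pair_measurements(m)
  expect_identical(p$mean_volume, 9000)
  expect_identical(p$abs_diff, 90)
  expect_identical(p$rel_diff_pct, 1)
})

test_that("pairing rejects duplicates, missing scans and zero volumes", {
  base <- tibble::tibble(subject_id = "s1", scan_index = c(1L, 1L),
                         side = "left", variant = "complete",
                         volume_ml = c(1, 2))
  expect_error(pair_measurements(base), class = "legvol_pairing_error")
  expect_error(pair_measurements(base[1, ]), class = "legvol_pairing_error")
  zz <- tibble::tibble(subject_id = "s1", scan_index = 1:2, side = "left",
                       variant = "complete", volume_ml = c(0, 0))
  expect_error(pair_measurements(zz), class = "legvol_domain_error")
  expect_error(pair_measurements(tibble::tibble(a = 1)),
               class = "legvol_pairing_error")
})

test_that("paired t-test reproduces the hand-computed example", {
  # d = (1, -1, 1, 1): mean 0.5, sd 1, se 0.5 -> t = 1 with df = 3
  v2 <- c(10, 10, 10, 10)
  v1 <- v2 + c(1, -1, 1, 1)
  tt <- paired_t_test(v1, v2)
  expect_equal(tt$t_stat, 1, tolerance = 1e-12)
  expect_identical(tt$df, 3)
  expect_equal(tt$mean_dif, 0.5, tolerance = 1e-12)
  expect_equal(tt$p_value, 2 * stats::pt(-1, 3), tolerance = 1e-12)
  expect_equal(tt$ci95, 0.5 + c(-1, 1) * stats::qt(0.975, 3) * 0.5,
               tolerance = 1e-12)
})

test_that("zero difference variance is flagged instead of dividing by zero", {
  tt <- paired_t_test(c(5, 6, 7), c(4, 5, 6))
  expect_true(tt$zero_variance)
  expect_identical(tt$mean_dif, 1)
  expect_true(is.na(tt$t_stat))
  expect_error(paired_t_test(1, 1), class = "legvol_sample_size")
  expect_error(paired_t_test(1:3, 1:4), class = "legvol_sample_size")
})

test_that("rank-sum reproduces the smallest exact case", {
  rs <- rank_sum_test(c(1, 2), c(3, 4))
  expect_identical(unname(rs$W), 0)
  expect_equal(rs$p_value, 1 / 3, tolerance = 1e-12)  # 2 of C(4,2)=6 labelings
  expect_true(rs$exact)
  expect_equal(rs$hl_shift, -2, tolerance = 1e-12)
})

test_that("exact rank-sum agrees with full enumeration for all sizes up to 6", {
  set.seed(3)
  for (na in 1:3) for (nb in na:3) {
    a <- stats::rnorm(na)
    b <- stats::rnorm(nb) + 0.5
    rs <- rank_sum_test(a, b)
    or <- rank_sum_oracle(a, b)
    expect_equal(unname(rs$W), or$W, tolerance = 1e-12,
                 info = paste(na, nb))
    expect_equal(rs$p_value, or$p_value, tolerance = 1e-12,
                 info = paste(na, nb))
  }
})

test_that("Hodges-Lehmann shift is the median pairwise difference", {
  a <- c(1.2, 3.4, 2.2)
  b <- c(0.5, 1.8)
  rs <- rank_sum_test(a, b)
  expect_equal(rs$hl_shift, stats::median(as.numeric(outer(a, b, "-"))),
               tolerance = 1e-12)
})

test_that("ties and large samples fall back to the normal approximation", {
  a <- c(1, 2, 2, 3)
  b <- c(2, 3, 4, 5)
  rs <- rank_sum_test(a, b)
  expect_false(rs$exact)
  big <- rank_sum_test(stats::rnorm(10), stats::rnorm(10))
  expect_false(big$exact)
})

test_that("degenerate samples keep the test but drop the shift CI", {
  rs <- rank_sum_test(rep(0, 5), rep(0, 6))
  expect_true(is.na(rs$ci95[1]))
  expect_true(is.finite(rs$p_value))
})

test_that("BMI classes are half-open and cover boundaries deterministically", {
  got <- classify_bmi(c(17, 18.5, 24.9, 25.0, 29.9, 30.0, 35.0, 40.0, 55.8, 26.4))
  expect_identical(as.character(got),
                   c("underweight", "normal", "normal", "pre-obesity",
                     "pre-obesity", "obesity I", "obesity II", "obesity III",
                     "obesity III", "pre-obesity"))
  expect_error(classify_bmi(c(25, -1)), class = "legvol_domain_error")
  expect_error(classify_bmi(NA_real_), class = "legvol_domain_error")
})

test_that("cohort summary aggregates per cohort and side", {
  set.seed(9)
  records <- tibble::tibble(subject_id = sprintf("s%d", 1:6),
                            variant = rep(c("complete", "limited"), each = 3))
  meas <- tidyr::expand_grid(subject_id = records$subject_id,
                             scan_index = 1:2, side = c("left", "right"))
  meas$variant <- records$variant[match(meas$subject_id, records$subject_id)]
  meas$volume_ml <- 9000 + stats::rnorm(nrow(meas), sd = 50)
  pairs <- pair_measurements(meas)
  sm <- cohort_summary(records, pairs)
  expect_setequal(unique(sm$cohort), c("all", "complete", "limited"))
  expect_equal(nrow(sm), 6)  # 3 cohorts x 2 sides
  all_left <- sm[sm$cohort == "all" & sm$side == "left", ]
  expect_identical(all_left$n, 6L)
  pl <- pairs[pairs$side == "left", ]
  expect_equal(all_left$v1_mean, mean(pl$v1), tolerance = 1e-12)
  expect_equal(all_left$rel_max, max(pl$rel_diff_pct), tolerance = 1e-12)
  cmp <- compare_variants(pairs)
  expect_equal(nrow(cmp), 2)
  expect_true(all(is.finite(cmp$p_value)))
  dm <- demographic_summary(tibble::tibble(
    subject_id = records$subject_id, variant = records$variant,
    age = c(30, 40, 50, 35, 45, 55), sex = rep(c("female", "male"), 3),
    bmi = c(22, 24, 26, 31, 33, 38)))
  expect_equal(dm$n, c(6L, 3L, 3L))
})

test_that("tidiers return broom-shaped tibbles", {
  tt <- paired_t_test(c(2, 3, 5), c(1, 1, 2))
  td <- tidy(tt)
  expect_true(all(c("estimate", "conf.low", "conf.high", "statistic",
                    "p.value") %in% names(td)))
  expect_identical(glance(tt)$n, 3L)
  rs <- rank_sum_test(c(1, 2), c(3, 4))
  expect_identical(tidy(rs)$method, "exact")
})
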