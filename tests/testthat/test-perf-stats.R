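make_volume <- function(slope, days = 21, dt_d = 0.1) {
  t_d <- seq(0, days, by = dt_d)
  v <- data.frame(time_d = t_d, volume_mL_STP = slope * t_d, flag = "ok")
  class(v) <- c("volume_trace", "data.frame")
  v
}

test_that("weekly rates are normalized by the daily COD load", {
  # slope 26.6 mL/d over 1.33 gCOD/L/d * 0.2 L = 0.266 gCOD/d -> 100
  cfg <- reactor_config(olr_gCOD_L_d = 1.33, working_volume_mL = 200)
  wk <- weekly_rates(make_volume(26.6), cfg)
  expect_equal(wk$week_index, 1:3)
  expect_equal(wk$rate_mL_d, rep(26.6, 3), tolerance = 1e-9)
  expect_equal(wk$rate_mL_d_gCOD, rep(100, 3), tolerance = 1e-9)
  # halving the load doubles the normalized rate
  cfg2 <- reactor_config(olr_gCOD_L_d = 1.33 / 2, working_volume_mL = 200)
  wk2 <- weekly_rates(make_volume(26.6), cfg2)
  expect_equal(wk2$rate_mL_d_gCOD, 2 * wk$rate_mL_d_gCOD)
  # a truncated final week with too few points is dropped with a warning
  expect_warning(wk3 <- weekly_rates(make_volume(5, days = 7.1), cfg),
                 "omitted")
  expect_equal(wk3$week_index, 1)
})

test_that("Kruskal-Wallis reproduces the hand-computed statistic", {
  # ranks 1..9, mean ranks 2/5/8: H = 12/90 * 3*(4 + 25 + 64) - 30 = 7.2
  kw <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2L)
  expect_equal(kw$p_value, stats::pchisq(7.2, 2, lower.tail = FALSE))
})

test_that("tie-corrected H and p agree with stats::kruskal.test", {
  cases <- list(
    list(c(1, 2, 2, 3), c(5, 5, 5, 7), c(8, 9, 2, 5)),
    list(rnorm(8), rnorm(6), rnorm(10), rnorm(5)),
    list(c(1, 1, 1, 2), c(1, 2, 2, 2))
  )
  set.seed(7)
  for (groups in cases) {
    mine <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(unlist(groups),
                               rep(seq_along(groups), lengths(groups)))
    expect_equal(mine$H, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value)
    expect_equal(mine$df, unname(ref$parameter))
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(11)
  groups <- list(rnorm(6), rnorm(9, 1), rnorm(7, 2))
  h0 <- kruskal_wallis(groups)$H
  expect_equal(kruskal_wallis(lapply(groups, exp))$H, h0)
  expect_equal(kruskal_wallis(lapply(groups, function(x) 3 * x - 10))$H, h0)
})

test_that("degenerate and invalid group lists are handled", {
  allsame <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(allsame$H, 0)
  expect_equal(allsame$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  expect_error(kruskal_wallis(list(1:3, numeric())), "nonempty")
})

test_that("Dunn z values match the rank formula on untied data", {
  # groups 1:4 / 5:8 / 9:12: mean ranks 2.5, 6.5, 10.5;
  # sigma^2 = N(N+1)/12 = 13, pair SE = sqrt(13/2) = 2.54951
  dn <- dunn_posthoc(list(A = 1:4, B = 5:8, C = 9:12), adjust_method = "none")
  expect_equal(dn$z, c(-4, -8, -4) / sqrt(6.5), tolerance = 1e-9)
  expect_equal(dn$p_raw, 2 * stats::pnorm(-abs(dn$z)))
  # only the extreme pair can reach significance with n = 4 per group
  dh <- dunn_posthoc(list(A = 1:4, B = 5:8, C = 9:12), "holm")
  expect_lt(dh$p_adjusted[dh$group_i == "A" & dh$group_j == "C"], 0.05)
  expect_gt(min(dh$p_adjusted[dh$group_i != "A" | dh$group_j != "C"]), 0.05)
})

test_that("Dunn test is antisymmetric and respects adjustment ordering", {
  set.seed(5)
  g <- list(a = rnorm(6), b = rnorm(8, 0.5), c = rnorm(7, 1))
  d1 <- dunn_posthoc(g, "none")
  swapped <- dunn_posthoc(list(a = g$b, b = g$a, c = g$c), "none")
  expect_equal(swapped$z[1], -d1$z[1])
  expect_equal(swapped$p_raw[1], d1$p_raw[1])
  for (m in c("holm", "bonferroni")) {
    dm <- dunn_posthoc(g, m)
    expect_true(all(dm$p_adjusted >= dm$p_raw - 1e-15))
  }
  # identical groups compare as z = 0, p = 1
  same <- dunn_posthoc(list(x = c(1, 2, 3), y = c(1, 2, 3)), "none")
  expect_equal(same$z, 0)
  expect_equal(same$p_raw, 1)
})

test_that("post-hoc runs only on a significant omnibus test unless forced", {
  set.seed(2)
  null_groups <- list(rnorm(5, 0, 1e-3) + 10, rnorm(5, 0, 1e-3) + 10,
                      rnorm(5, 0, 1e-3) + 10)
  cmp <- compare_groups(null_groups)
  expect_gt(cmp$p_value, 0.05)
  expect_null(cmp$pairwise)
  cmp2 <- compare_groups(null_groups, force_posthoc = TRUE)
  expect_s3_class(cmp2$pairwise, "dunn_test")
  sep <- compare_groups(list(1:4, 5:8, 9:12))
  expect_lt(sep$p_value, 0.05)
  expect_equal(nrow(sep$pairwise), 3)
})

test_that("weekly comparison reproduces the replicated-inoculum layout", {
  # three inocula in four replicates, two weeks, clear separation
  design <- data.frame(reactor_id = paste0("R", 1:12),
                       group = rep(c("INOC_A", "INOC_B", "INOC_C"), each = 4))
  rates <- expand.grid(reactor_id = paste0("R", 1:12), week_index = 1:2,
                       stringsAsFactors = FALSE)
  base <- rep(c(100, 200, 300), each = 4)
  set.seed(31)
  rates$rate_mL_d_gCOD <- base[match(rates$reactor_id, design$reactor_id)] +
    rnorm(nrow(rates), 0, 5)
  cmp <- compare_weekly(rates, design)
  expect_equal(cmp$summary$week_index, 1:2)
  expect_true(all(cmp$summary$p_value < 0.05))
  expect_equal(unique(cmp$pairwise$week_index), 1:2)
  # with four replicates only the extreme pair can clear holm at 0.05
  expect_true(all(cmp$summary$n_significant_pairs == 1))
  expect_error(compare_weekly(rates, design[-1, ]), "missing from design")
})
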