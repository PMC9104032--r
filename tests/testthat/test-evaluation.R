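test_that("adjusted-Wald chance bound reproduces the 20-trial 70% limit", {
  b <- chance_upper_bound(20, 2, 0.05)
  expect_equal(b$upper_pct, 70)
  expect_equal(b$upper, 70.07, tolerance = 1e-3)
  # direct closed-form evaluation as oracle, including another alpha
  direct <- function(n, k, alpha) {
    z <- stats::qnorm(1 - alpha / 2)
    pt <- (n / k + z^2 / 2) / (n + z^2)
    100 * (pt + z * sqrt(pt * (1 - pt) / (n + z^2)))
  }
  expect_equal(chance_upper_bound(20, 2, 0.01)$upper, direct(20, 2, 0.01), tolerance = 1e-12)
  expect_equal(chance_upper_bound(37, 4, 0.05)$upper, direct(37, 4, 0.05), tolerance = 1e-12)
  expect_error(chance_upper_bound(20, 2, 1.2), "alpha")
})

test_that("chance bound shrinks with trials, widens with confidence, brackets 1/k", {
  ns <- c(5, 10, 20, 50, 200, 1000)
  uppers <- vapply(ns, function(n) chance_upper_bound(n, 2)$upper, numeric(1))
  expect_true(all(diff(uppers) < 0))
  expect_lt(chance_upper_bound(1e7, 2)$upper - 50, 0.05) # limit is 100/k
  b05 <- chance_upper_bound(20, 2, 0.05)
  b01 <- chance_upper_bound(20, 2, 0.01)
  expect_gt(b01$upper, b05$upper)
  for (b in list(b05, b01)) {
    expect_lt(b$lower, 50)
    expect_gt(b$upper, 50)
  }
})

test_that("signed-rank layer reproduces the published session statistics", {
  tab <- read_accuracy_table()
  expect_equal(nrow(tab), 12L)
  expect_equal(sum(is.na(tab$online)), 3L)
  expect_equal(tab$subject[is.na(tab$online)], c("B", "I", "K"))

  w_cal70 <- wilcoxon_one_sample(tab$calibration, 70)
  expect_equal(w_cal70$t_plus, 78)
  expect_equal(w_cal70$r_rb, 1)
  expect_lt(w_cal70$p_value, 0.01)

  w_cal50 <- wilcoxon_one_sample(tab$calibration, 50)
  expect_equal(w_cal50$t_plus, 78)
  expect_equal(w_cal50$r_rb, 1)
  expect_lt(w_cal50$p_value, 0.001)

  w_onl50 <- wilcoxon_one_sample(tab$online, 50)
  expect_equal(w_onl50$t_plus, 31)
  expect_equal(w_onl50$n_effective, 8L) # subject A sits exactly at 50
  expect_equal(w_onl50$r_rb, 26 / 36)
  expect_equal(round(w_onl50$r_rb, 2), 0.72)
  # the two-sided p is 0.078; the published significance claim for this
  # comparison corresponds to the one-sided reading
  expect_equal(w_onl50$p_exact, 0.078125, tolerance = 1e-9)
  expect_lt(w_onl50$p_value / 2, 0.05)

  w_onl70 <- wilcoxon_one_sample(tab$online, 70)
  expect_equal(w_onl70$t_plus, 6)
  expect_equal(round(w_onl70$p_normal, 3), 0.107)
})

test_that("T+ + T- identity and r_rb range hold over random inputs", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(3:15, 1)
    v <- sample(30:100, n, replace = TRUE)
    mu <- sample(40:80, 1)
    if (all(v == mu)) next
    w <- wilcoxon_one_sample(v, mu)
    expect_equal(w$t_plus + w$t_minus, w$n_effective * (w$n_effective + 1) / 2)
    expect_gte(w$r_rb, -1)
    expect_lte(w$r_rb, 1)
    # antisymmetry under reflection of values about mu
    w_ref <- wilcoxon_one_sample(2 * mu - v, mu)
    expect_equal(w_ref$r_rb, -w$r_rb)
    expect_equal(w_ref$p_exact, w$p_exact, tolerance = 1e-12)
  }
  expect_equal(wilcoxon_one_sample(c(71, 73, 90), 70)$r_rb, 1)
  expect_error(wilcoxon_one_sample(c(70, 70), 70), "undefined")
})

test_that("exact enumeration agrees with 2^n brute force, incl. midrank ties", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    # coarse grid forces frequent ties and zeros
    v <- sample(seq(40, 90, by = 5), n, replace = TRUE)
    mu <- 65
    if (all(v == mu)) next
    w <- wilcoxon_one_sample(v, mu, method = "exact")
    expect_equal(w$p_exact, brute_force_signed_rank_p(v, mu), tolerance = 1e-12)
  }
  # and with no ties it matches the reference exact implementation
  v <- c(81, 66, 92, 55, 73, 88, 61, 78)
  w <- wilcoxon_one_sample(v, 70, method = "exact")
  ref <- stats::wilcox.test(v, mu = 70, exact = TRUE)
  expect_equal(w$p_exact, ref$p.value, tolerance = 1e-12)
})

test_that("group summaries reproduce the published means and SDs", {
  tab <- read_accuracy_table()
  g_cal <- group_summary(tab$calibration)
  expect_equal(round(g_cal$mean, 2), 88.58)
  expect_equal(round(g_cal$sd, 2), 8.49)
  g_onl <- group_summary(tab$online)
  expect_equal(g_onl$n, 9L)
  expect_equal(round(g_onl$mean, 2), 61)
  expect_equal(round(g_onl$sd, 2), 14.89)
  expect_equal(group_summary(c(5, 5, 5))$sd, 0)
  expect_error(group_summary(c(1, NA)), "at least 2")
})

test_that("below-chance flagging uses strict inequality against the upper bound", {
  bound <- chance_upper_bound(20, 2, 0.05)
  res <- data.frame(
    subject_id = c("C", "X", "Y"),
    accuracy = c(42, bound$upper, 95)
  )
  out <- flag_below_chance(res, bound)
  expect_equal(out$below_chance, c(TRUE, FALSE, FALSE))
  all_above <- flag_below_chance(data.frame(accuracy = c(80, 90)), bound)
  expect_false(any(all_above$below_chance))
})

test_that("reproduce_results recomputes every printed quantity with a verdict", {
  rep <- reproduce_results()
  r <- rep$report
  matched <- r[!is.na(r$match), ]
  expect_true(all(matched$match))
  expect_gte(nrow(matched), 14L)
  # the normal-approximation p reproduces the print; the exact p differs
  expect_equal(
    r$computed[r$quantity == "p online vs 70 (normal approx, cc)"], 0.107
  )
  p_exact <- r$computed[r$quantity == "p online vs 70 (exact enumeration)"]
  expect_false(isTRUE(all.equal(p_exact, 0.107)))
  expect_output(print(rep), "MATCH")
})
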