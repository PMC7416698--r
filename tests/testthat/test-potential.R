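# Treatment potential, ETDRS arithmetic, Kruskal-Wallis comparison.

test_that("decimal/logMAR conversion", {
  expect_equal(decimal_to_logmar(0.2), 0.69897, tolerance = 1e-5)
  expect_equal(decimal_to_logmar(1.0), 0)
  expect_equal(decimal_to_logmar(0.71), 0.148742, tolerance = 1e-5)
  expect_error(decimal_to_logmar(0), "positive")
})

test_that("ETDRS lines gained reproduce the clinical worked examples", {
  expect_equal(etdrs_lines_gained(0.2, va_from_onl(90)), 6L)
  expect_equal(etdrs_lines_gained(0.2, va_from_onl(59)), 4L)
  expect_equal(etdrs_lines_gained(0.37, 0.37), 0L)

  # antisymmetry on the chart grid
  for (pair in list(c(0.2, 0.8), c(0.125, 0.5), c(0.32, 0.63))) {
    expect_equal(etdrs_lines_gained(pair[1], pair[2]),
                 -etdrs_lines_gained(pair[2], pair[1]))
  }

  # half-grid ties round toward better acuity (lower logMAR)
  tie <- 10^-0.25 # logMAR exactly 0.25 -> rounds to 0.2
  expect_equal(etdrs_lines_gained(0.2, tie), 5L)
})

test_that("nearest_chart_line snaps to standard Snellen denominators", {
  expect_equal(nearest_chart_line(va_from_onl(90)), "20/25")
  expect_equal(nearest_chart_line(va_from_onl(59)), "20/40")
  expect_equal(nearest_chart_line(1.0), "20/20")
  expect_equal(nearest_chart_line(0.2), "20/100")
  expect_match(nearest_chart_line(3), "off-chart")
  expect_match(nearest_chart_line(0.02), "off-chart")
})

test_that("treatment potential: ND floor for FS, logMAR delta for VA", {
  p90 <- predict_cf(
    fit_log_model(c(25, 60, 120), -12.01 + 17.38 * log10(c(25, 60, 120)),
                  "FS"), rep(90, 3))
  tp <- treatment_potential("ND", p90, "FS", subject_id = "P13",
                            method = "CF")
  expect_equal(tp$delta, -12.01 + 17.38 * log10(90), tolerance = 1e-9)
  expect_equal(tp$delta_log_units, tp$delta / 10)
  expect_equal(tp$measured_floored, 0)

  # FS at the thinner reference ONL still exceeds 1.5 log units above the floor
  p59 <- predict_cf(fit_log_model(c(25, 60, 120),
                                  -12.01 + 17.38 * log10(c(25, 60, 120)),
                                  "FS"), rep(59, 3))
  tp59 <- treatment_potential(NA, p59, "FS")
  expect_gte(tp59$delta_log_units, 1.5)

  # measured equal to predicted -> zero delta
  tp0 <- treatment_potential(p90$value, p90, "FS")
  expect_equal(tp0$delta, 0)

  # VA: delta on the logMAR scale plus chart outputs
  vfit <- fit_log_model(c(25, 60, 120), -1.07 + 0.91 * log10(c(25, 60, 120)),
                        "VA")
  pv <- predict_cf(vfit, rep(90, 3))
  tpv <- treatment_potential(0.2, pv, "VA")
  expect_equal(tpv$delta, decimal_to_logmar(0.2) - decimal_to_logmar(pv$value))
  expect_equal(tpv$lines_gained, 6L)
  expect_equal(tpv$snellen_predicted, "20/25")

  expect_error(treatment_potential("ND", pv, "VA"), "non-detectable VA")
  expect_error(treatment_potential(-2, p90, "FS"), ">= 0")

  # configurable perimeter floor
  tpf <- treatment_potential("ND", p90, "FS", nd_floor = 5)
  expect_equal(tpf$delta, p90$value - 5)
})

test_that("Kruskal-Wallis H matches stats::kruskal.test across random data", {
  set.seed(91)
  for (k in 1:10) {
    v <- sample(1:8, 15, replace = TRUE) # heavy ties
    g <- rep(c("a", "b", "c"), each = 5)
    ours <- kruskal_wallis_test(v, g)
    ref <- stats::kruskal.test(v, factor(g))
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_chisq, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis handles degenerate groups and validates input", {
  ident <- kruskal_wallis_test(rep(2, 9), rep(c("a", "b", "c"), 3))
  expect_equal(ident$H, 0)
  expect_equal(ident$p_chisq, 1)
  expect_error(kruskal_wallis_test(1:4, rep("a", 4)), "2 groups")
  expect_error(kruskal_wallis_test(1:4, c("a", "a", "a", "b")),
               "at least 2 observations")
})

test_that("compare_groups summarises and tests per genotype and target", {
  set.seed(95)
  pot <- expand.grid(subject_id = sprintf("P%02d", 1:8),
                     group = c("BCM_deletion", "BCM_C203R"),
                     target = "FS", method = c("I", "II", "CF"),
                     stringsAsFactors = FALSE)
  pot$delta <- rnorm(nrow(pot), 18, 2)
  # inject a method effect in the C203R group only
  sel <- pot$group == "BCM_C203R" & pot$method == "I"
  pot$delta[sel] <- pot$delta[sel] - 6
  out <- compare_groups(pot, n_perm = 500, seed = 1)
  expect_equal(nrow(out$summary), 6)
  expect_equal(nrow(out$tests), 2)
  c2 <- out$tests[out$tests$group == "BCM_C203R", ]
  del <- out$tests[out$tests$group == "BCM_deletion", ]
  expect_lt(c2$p_chisq, 0.05)
  expect_gt(del$p_chisq, 0.05)
  # permutation p agrees with the chi-square approximation to first order
  expect_lt(abs(del$p_perm - del$p_chisq), 0.25)
  expect_error(compare_groups(pot[0, ]), "empty|columns")
})

test_that("equal potentials across methods report no difference", {
  pot <- expand.grid(subject_id = sprintf("P%02d", 1:6),
                     group = "BCM_deletion", target = "VA",
                     method = c("I", "II", "CF"), stringsAsFactors = FALSE)
  pot$delta <- rep(rnorm(6, 0.3, 0.05), 3) # same per subject for all methods
  out <- compare_groups(pot)
  expect_equal(out$tests$H, 0, tolerance = 1e-10)
  expect_equal(out$tests$p_chisq, 1)
})
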