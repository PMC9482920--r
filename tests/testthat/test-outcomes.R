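test_that("Kaplan-Meier matches hand product-limit computations", {
  # all censored: survival stays at 1
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # all events at distinct times
  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$survival, c(2 / 3, 1 / 3, 0))
  # censoring exactly at an event time: censored subject at risk through it
  km2 <- km_estimate(c(1, 2, 2, 3), c(1, 1, 0, 1))
  expect_equal(km2$survival[km2$time == 2], 3 / 4 * 2 / 3)
  expect_equal(km2$survival[km2$time == 3], 3 / 4 * 2 / 3 * 0)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "positive")
})

test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  set.seed(13)
  t <- rexp(40)
  km <- km_estimate(t, rep(1, 40))
  ecdf_surv <- 1 - ecdf(t)(km$time)
  expect_equal(km$survival, ecdf_surv, tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 1e-12))  # non-increasing
})

test_that("log-rank is zero for identical groups and invariant to relabeling", {
  t <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e <- rep(1, 8)
  g <- rep(c("x", "y"), each = 4)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  set.seed(3)
  t2 <- rexp(30); e2 <- rbinom(30, 1, 0.8); g2 <- rep(c("x", "y"), 15)
  lr_a <- logrank_test(t2, e2, g2)
  lr_b <- logrank_test(t2, e2, ifelse(g2 == "x", "y", "x"))
  expect_equal(lr_a$chisq, lr_b$chisq)
  expect_error(logrank_test(t2, e2, rep("x", 30)), "2 groups")
})

test_that("log-rank p agrees with a permutation oracle on a small toy", {
  set.seed(8)
  t <- c(rexp(12, 1), rexp(12, 2.5))
  e <- rbinom(24, 1, 0.9)
  g <- rep(c("slow", "fast"), each = 12)
  lr <- logrank_test(t, e, g)
  p_perm <- oracle_logrank_perm_p(t, e, g)
  expect_lt(abs(lr$p_value - p_perm), 0.05)
})

test_that("Cox coefficient matches direct partial-likelihood maximization", {
  t <- c(4, 3, 1, 1.5, 2.5, 5)
  e <- c(1, 1, 1, 1, 1, 0)
  x <- c(0, 1, 1, 0, 1, 0)
  rec <- data.frame(time = t, event = e, biomarker_group = x,
                    arm = c("A", "B", "A", "B", "A", "B"))
  fit <- survival::coxph(survival::Surv(t, e) ~ x, ties = "efron")
  beta_oracle <- oracle_cox_beta(t, e, x)
  expect_equal(unname(coef(fit)), beta_oracle, tolerance = 1e-5)
})

test_that("interaction Cox fit reports per-term HRs and flags degenerate designs", {
  set.seed(21)
  n <- 400
  rec <- data.frame(
    arm = rep(c("A", "B"), each = n / 2),
    biomarker_group = factor(rep(c("wt_like", "mutant_like"), times = n / 2),
                             levels = c("wt_like", "mutant_like")),
    age = rnorm(n, 60, 8))
  pos <- rec$biomarker_group == "mutant_like" & rec$arm == "B"
  rec$time <- rexp(n, 0.05 * ifelse(pos, 3, 1))
  rec$event <- 1L
  fit <- fit_cox_interaction(rec, covariates = "age")
  expect_s3_class(fit, "cox_interaction")
  it <- fit$table[fit$table$term == fit$interaction_term, ]
  expect_gt(it$hr, 1.8)
  expect_lt(it$p_value, 0.01)
  expect_true(all(fit$table$ci_lo <= fit$table$hr &
                    fit$table$hr <= fit$table$ci_hi))
  rec$flat <- 1
  expect_error(fit_cox_interaction(rec, covariates = "flat"), "constant")
})

test_that("ORR mapping is total over RECIST categories and Fisher-checked", {
  expect_error(orr_compare(c("CR", "PR", "SD", "PD"), rep("g1", 4)),
               "2 non-empty groups")

  resp <- c("CR", "PR", "SD", "PD", "PR", "PR", "PR", "CR")
  grp <- rep(c("mutant_like", "wt_like"), each = 4)
  res <- orr_compare(resp, grp)
  expect_equal(unname(res$orr["mutant_like"]), 0.5)
  expect_equal(unname(res$orr["wt_like"]), 1.0)
  # both groups all responders: p = 1
  allr <- orr_compare(rep(c("CR", "PR"), 4), rep(c("a", "b"), each = 4))
  expect_equal(allr$p_value, 1)
  # 4/9 vs 8/9 toy against the enumeration oracle
  resp2 <- c(rep("PR", 4), rep("PD", 5), rep("CR", 8), "SD")
  grp2 <- rep(c("mut", "wt"), each = 9)
  res2 <- orr_compare(resp2, grp2)
  expect_equal(res2$p_value, oracle_fisher_p(5, 4, 1, 8), tolerance = 1e-9)
  expect_error(orr_compare(c("CR", "XX"), c("a", "b")), "CR, PR, SD")
})

test_that("PDX response classification applies the documented boundaries", {
  expect_identical(as.character(classify_pdx_response(c(-60, 0, 35, 34.9,
                                                        -50))),
                   c("PR", "SD", "PD", "SD", "PR"))
  expect_error(classify_pdx_response(0, pr_threshold = 40,
                                     pd_threshold = 35), "below")
  expect_error(classify_pdx_response(NaN), "finite")
  expect_identical(attr(classify_pdx_response(0,
                                              responders_include_sd = FALSE),
                        "responder_classes"), "PR")
  expect_identical(attr(classify_pdx_response(0), "responder_classes"),
                   c("PR", "SD"))
})

test_that("rank-sum comparison is exact for small untied groups", {
  x <- c(1.2, 3.1, 2.4)
  y <- c(5.5, 4.2, 6.0)
  rs <- rank_sum_compare(c(x, y), rep(c("a", "b"), each = 3))
  expect_true(rs$exact)
  expect_equal(rs$p_value, oracle_ranksum_exact_p(x, y))
  expect_equal(rs$p_value, 0.1)  # most extreme of the 20 arrangements
  # large groups: normal approximation, still two-sided
  set.seed(4)
  big <- rank_sum_compare(c(rnorm(50), rnorm(50, 1)),
                          rep(c("a", "b"), each = 50))
  expect_false(big$exact)
  expect_lt(big$p_value, 0.01)
  expect_warning(flat <- rank_sum_compare(rep(1, 10),
                                          rep(c("a", "b"), 5)),
                 "identical")
  expect_equal(flat$p_value, 1)
})
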