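## a small fitted signature on simulated data, reused across tests
sig_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) {
      ex <- simulate_expression_cohort(
        expr_sim_config(n_samples = 120, n_genes = 400, effect_size = 1.5,
                        seed = 33))
      fx <<- list(ex = ex, log_expr = normalize_counts(ex$counts),
                  sig = fit_signature(normalize_counts(ex$counts),
                                      ex$annotations))
    }
    fx
  }
})

test_that("two-gene PC1 matches the closed-form 2x2 eigendecomposition", {
  m <- matrix(c(1, 2, 4, 7,
                2, 1, 6, 9), nrow = 2, byrow = TRUE,
              dimnames = list(c("gu", "gd"), paste0("s", 1:4)))
  model <- structure(list(up_genes = "gu", down_genes = "gd",
                          gene_means = rowMeans(m),
                          gene_sds = apply(m, 1, sd),
                          loadings = c(gu = 1, gd = 0) / 1,
                          orientation_sign = 1,
                          mode = "refit_per_cohort"),
                     class = "expr_signature")
  sc <- score_samples(m, model)
  # closed form: correlation matrix of two z-vectors has PC1 along
  # (1, sign(r))/sqrt(2); scores are z %*% v, oriented up-minus-down
  z <- t((m - rowMeans(m)) / apply(m, 1, sd))
  r <- cor(z[, 1], z[, 2])
  v <- c(1, sign(r)) / sqrt(2)
  expected <- drop(z %*% v)
  contrast <- z[, "gu"] - z[, "gd"]
  expected <- expected * sign(cor(expected, contrast))
  expect_equal(sc$score, unname(expected), tolerance = 1e-9)
})

test_that("single-gene scoring in relaxed mode is the oriented z-score", {
  m <- matrix(c(1, 3, 5, 7), 1, 4,
              dimnames = list("gu", paste0("s", 1:4)))
  m <- rbind(m, other = c(2, 2, 2, 2)) # zero-variance gene gets dropped
  model <- structure(list(up_genes = c("gu", "other"),
                          down_genes = character(0),
                          gene_means = rowMeans(m), gene_sds = c(1, 1),
                          loadings = c(gu = 1, other = 0),
                          orientation_sign = 1, mode = "refit_per_cohort"),
                     class = "expr_signature")
  expect_message(sc <- score_samples(m, model, min_genes = 1L), "dropped")
  z <- (m["gu", ] - mean(m["gu", ])) / sd(m["gu", ])
  expect_equal(sc$score, unname(z), tolerance = 1e-9)
  expect_error(score_samples(m, model, min_genes = 2L), "fewer than 2")
})

test_that("mutant samples score higher than wild type on simulated cohorts", {
  fx <- sig_fixture()
  mut <- fx$ex$annotations$arid1a_status == "mutant"
  expect_gt(mean(fx$sig$scores$score[mut]),
            mean(fx$sig$scores$score[!mut]))
})

test_that("scores are invariant to per-gene affine transforms and permute with samples", {
  fx <- sig_fixture()
  le <- fx$log_expr
  sc0 <- score_samples(le, fx$sig)
  le2 <- le
  g <- fx$sig$up_genes[1]
  le2[g, ] <- 3 * le2[g, ] + 7   # positive rescale + shift: z unchanged
  sc2 <- score_samples(le2, fx$sig)
  expect_equal(sc2$score, sc0$score, tolerance = 1e-9)
  perm <- sample(ncol(le))
  scp <- score_samples(le[, perm], fx$sig)
  expect_equal(scp$score, sc0$score[perm], tolerance = 1e-9)
})

test_that("orientation is deterministic across repeated runs", {
  fx <- sig_fixture()
  s1 <- score_samples(fx$log_expr, fx$sig)
  s2 <- score_samples(fx$log_expr, fx$sig)
  expect_identical(s1, s2)
  # and the oriented score always correlates positively with the contrast
  z <- t(scale(t(fx$log_expr[c(fx$sig$up_genes, fx$sig$down_genes), ])))
  contrast <- colMeans(z[fx$sig$up_genes, , drop = FALSE]) -
    colMeans(z[fx$sig$down_genes, , drop = FALSE])
  expect_gt(cor(s1$score, contrast), 0)
})

test_that("refit and frozen modes agree in rank order on the fitting cohort", {
  fx <- sig_fixture()
  refit <- score_samples(fx$log_expr, fx$sig, mode = "refit_per_cohort")
  frozen <- score_samples(fx$log_expr, fx$sig, mode = "frozen_projection")
  expect_equal(order(refit$score), order(frozen$score))
  expect_gt(cor(refit$score, frozen$score, method = "spearman"), 0.999)
})

test_that("signature JSON round-trips and scores identically", {
  fx <- sig_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(fx$sig, path)
  back <- read_signature(path)
  expect_identical(back$up_genes, fx$sig$up_genes)
  expect_equal(back$loadings, fx$sig$loadings)
  expect_equal(score_samples(fx$log_expr, back, mode = "frozen_projection"),
               score_samples(fx$log_expr, fx$sig,
                             mode = "frozen_projection"),
               tolerance = 1e-12)
})

test_that("quartile stratification uses strict cutoffs", {
  s <- 1:8
  st <- stratify_quartiles(s)
  expect_equal(sum(st$group == "mutant_like"), 2L)
  expect_identical(st$group[7:8], c("mutant_like", "mutant_like"))
  st4 <- stratify_quartiles(c(10, 20, 30, 40))
  expect_equal(sum(st4$group == "mutant_like"), 1L)
  # ties exactly at the Q3 cutoff fall on the wild-type side (strict >)
  q3 <- quantile(1:8, 0.75, type = 7)
  tied <- stratify_quartiles(c(1:8, q3))
  expect_identical(tied$group[9], "wt_like")
  # sort-based oracle: mutant-like = strictly above the 75th percentile
  set.seed(6)
  v <- rnorm(37)
  sto <- stratify_quartiles(v)
  expect_identical(sto$group == "mutant_like",
                   v > quantile(v, 0.75, type = 7, names = FALSE))
  expect_error(stratify_quartiles(rep(1, 10)), "identical")
  expect_error(stratify_quartiles(1:3), "at least 4")
})

test_that("quartile enrichment peaks in Q4 on simulated cohorts", {
  fx <- sig_fixture()
  st <- stratify_quartiles(fx$sig$scores)
  qe <- quartile_mutant_enrichment(st, fx$ex$annotations$arid1a_status)
  expect_identical(names(which.max(qe$quartile_fractions)), "Q4")
  expect_lt(qe$wilcoxon$p_value, 1e-4)
})

test_that("exact rank-sum mode inside quartile enrichment matches enumeration", {
  st <- data.frame(score = c(1.2, 3.4, 2.2, 0.1, 5.5, 4.1),
                   quartile = c("Q1", "Q4", "Q2", "Q1", "Q4", "Q3"))
  labels <- c("mutant", "WT", "mutant", "WT", "mutant", "WT")
  qe <- quartile_mutant_enrichment(st, labels)
  x <- st$score[labels == "mutant"]
  y <- st$score[labels != "mutant"]
  expect_equal(qe$wilcoxon$p_value, oracle_ranksum_exact_p(x, y))
})

test_that("group ANOVA satisfies the F = t^2 identity and ranks shifted contrasts first", {
  set.seed(7)
  s <- rnorm(40)
  g <- rep(c("a", "b"), 20)
  an <- group_anova(s, g)
  tt <- t.test(s[g == "a"], s[g == "b"], var.equal = TRUE)
  expect_equal(an$f_value, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(an$p_value, tt$p.value, tolerance = 1e-9)
  expect_equal(an$df, 1L)

  s4 <- c(rnorm(30), rnorm(30), rnorm(30), rnorm(30, mean = 2))
  g4 <- rep(c("wt_MSS", "wt_MSI", "mut_MSS", "mut_MSI"), each = 30)
  an4 <- group_anova(s4, g4)
  expect_lt(an4$p_value, 1e-6)
  pw <- an4$pairwise
  top <- pw[order(pw$p_adjusted), ][1:3, ]
  expect_true(all(grepl("mut_MSI", paste(top$group1, top$group2))))

  # singleton group: its pairwise comparisons are NA, others computed
  g1 <- c(rep("a", 10), rep("b", 10), "c")
  an1 <- group_anova(c(rnorm(20), 1), g1)
  expect_true(all(is.na(an1$pairwise$p_value[an1$pairwise$group1 == "c" |
                                               an1$pairwise$group2 == "c"])))
})

test_that("fitted signature methods print, summarize, predict and expose loadings", {
  fx <- sig_fixture()
  expect_output(print(fx$sig), "up")
  expect_output(summary(fx$sig), "mutant mean")
  expect_equal(coef(fx$sig),
               fx$sig$orientation_sign * fx$sig$loadings)
  pr <- predict(fx$sig, fx$log_expr)
  expect_equal(pr$score, fx$sig$scores$score, tolerance = 1e-9)
})
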