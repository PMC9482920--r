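## Independent reference implementations used as test oracles. These are
## deliberately brute-force / closed-form and share no code with the package.

## Two-tailed Fisher exact p by exhaustive hypergeometric enumeration over
## all tables with the observed margins. Table layout: [a b; c d].
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b   # row 1 total ("white")
  n <- c + d   # row 2 total ("black")
  k <- a + c   # column 1 total (drawn)
  support <- max(0L, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Conditional maximum-likelihood odds ratio: solves E_psi[A] = a under the
## noncentral hypergeometric distribution by bisection on log(psi).
oracle_fisher_cmle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0L, k - n):min(m, k)
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  lbase <- dhyper(support, m, n, k, log = TRUE)
  expect_a <- function(logpsi) {
    lw <- lbase + support * logpsi
    w <- exp(lw - max(lw))
    sum(support * w) / sum(w)
  }
  uniroot(function(lp) expect_a(lp) - a, c(-40, 40), tol = 1e-10)$root |>
    exp()
}

## Benjamini-Hochberg step-up reference: p * m / rank with cumulative
## minimum from the largest p downwards, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / rank(p, ties.method = "first")[o]))
  adj[order(o)]
}

## Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_ranksum_exact_p <- function(x, y) {
  vals <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(vals), nx)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ws <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

## Cox partial likelihood for a single covariate, no ties: direct numeric
## maximization of the written-out likelihood.
oracle_cox_beta <- function(time, event, x) {
  loglik <- function(beta) {
    ord <- order(time)
    time <- time[ord]; event <- event[ord]; x <- x[ord]
    ll <- 0
    for (i in seq_along(time)) {
      if (event[i] == 1) {
        risk <- time >= time[i]
        ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
      }
    }
    ll
  }
  optimize(loglik, c(-10, 10), maximum = TRUE, tol = 1e-9)$maximum
}

## Permutation log-rank p: proportion of label reassignments whose log-rank
## chi-square is at least the observed one.
oracle_logrank_perm_p <- function(time, event, group, n_perm = 2000,
                                  seed = 11) {
  obs <- logrank_test(time, event, group)$chisq
  set.seed(seed)
  stats <- replicate(n_perm,
    logrank_test(time, event, sample(group))$chisq)
  mean(stats >= obs - 1e-12)
}

## Mann-Whitney AUC of scores for separating a binary label.
score_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

demo_cfg_path <- function() {
  system.file("extdata/demo_config.yaml", package = "resistsig")
}

## Small long-format variant table used across selection tests.
toy_variants <- function() {
  data.frame(
    patient_id = rep(c("p1", "p2", "p3"), times = c(6, 4, 2)),
    arm = rep(c("A", "B", "A"), times = c(6, 4, 2)),
    timepoint = c("PRE", "PRE", "PRE", "EOT", "EOT", "EOT",
                  "PRE", "PRE", "EOT", "EOT",
                  "PRE", "PRE"),
    gene = c("TP53", "KRAS", "APC", "TP53", "KRAS", "APC",
             "TP53", "ARID1A", "TP53", "ARID1A",
             "TP53", "KRAS"),
    variant_id = c("TP53_v1", "KRAS_v1", "APC_v1",
                   "TP53_v1", "KRAS_v1", "APC_v1",
                   "TP53_v1", "ARID1A_v1", "TP53_v1", "ARID1A_v1",
                   "TP53_v1", "KRAS_v1"),
    effect_class = c("nonsyn_snv", "nonsyn_snv", "synonymous",
                     "nonsyn_snv", "nonsyn_snv", "synonymous",
                     "nonsyn_snv", "indel", "nonsyn_snv", "indel",
                     "nonsyn_snv", "nonsyn_snv"),
    maf_percent = c(10, 1, 2, 8, 6, 1.6,
                    20, 0.5, 10, 15,
                    5, 1),
    stringsAsFactors = FALSE)
}
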