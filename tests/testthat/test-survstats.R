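test_that("even grouping follows the remainder rule and orders groups by score", {
  g8 <- even_groups(stats::setNames(8:1, letters[1:8]), 4)
  expect_equal(as.integer(table(g8)), c(2, 2, 2, 2))
  g10 <- even_groups(stats::setNames(runif(10), letters[1:10]), 4)
  expect_equal(as.integer(table(g10)), c(3, 3, 2, 2))
  # group-wise mean scores strictly increase on random distinct-score fixtures
  set.seed(41)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    k <- sample(2:5, 1)
    sc <- stats::setNames(sample(seq_len(200), n), paste0("s", 1:n))
    g <- quiet(even_groups(sc, k))
    means <- tapply(sc, g, mean)
    expect_true(all(diff(means) > 0))
    expect_lte(diff(range(table(g))), 1)
  }
  expect_error(even_groups(1:3, 5), "fewer samples")
  expect_error(even_groups(1:3, 1), "n_groups")
})

test_that("log-rank matches a hand-computed observed-minus-expected table", {
  # all three events in group A precede all censoring in B
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 0, 0, 0)
  grp <- factor(rep(c("A", "B"), each = 3))
  # hand calculation over the three event times
  o_minus_e <- (1 - 3 / 6) + (1 - 2 / 5) + (1 - 1 / 4)
  v <- (3 / 6) * (3 / 6) + (2 / 5) * (3 / 5) + (1 / 4) * (3 / 4)
  expected_chisq <- o_minus_e^2 / v
  lr <- km_logrank(grp, time, event)
  expect_equal(lr$chisq, expected_chisq, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  # identical groups: statistic ~ 0, p ~ 1
  t2 <- rep(c(1, 3, 5, 7), 2); e2 <- rep(c(1, 0, 1, 1), 2)
  lr2 <- km_logrank(rep(c("A", "B"), each = 4), t2, e2)
  expect_lt(lr2$chisq, 1e-10)
  expect_gt(lr2$p, 0.99)
  # KM table is per group with survival in [0, 1]
  expect_true(all(lr$km$survival <= 1 & lr$km$survival >= 0))
})

test_that("log-rank has power against a latent-driven hazard at n = 200", {
  rejections <- 0L
  for (rep in 1:20) {
    set.seed(500 + rep)
    n <- 200
    u <- runif(n)
    time <- rexp(n, rate = 0.003 * exp(3 * u))
    event <- rep(1L, n)
    g <- quiet(even_groups(stats::setNames(u, paste0("s", 1:n)), 4))
    lr <- km_logrank(g, time, event)
    if (lr$p < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections, 18L) # >= 90% rejection
})

test_that("cox fit reports Efron-tie likelihoods, pseudo-R2, and is replication-invariant", {
  set.seed(61)
  n <- 100
  x <- rnorm(n)
  time <- rexp(n, exp(0.5 * x) * 0.01)
  event <- rbinom(n, 1, 0.8)
  f1 <- cox_fit(data.frame(x = x), time, event)
  expect_lte(f1$loglik_null, f1$loglik)
  expect_equal(f1$pseudo_r2,
               1 - exp((2 / n) * (f1$loglik_null - f1$loglik)))
  # duplicating the dataset leaves coefficients unchanged; exact under the
  # Breslow tie convention (Efron's correction treats the created ties)
  f1b <- cox_fit(data.frame(x = x), time, event, ties = "breslow")
  f2b <- cox_fit(data.frame(x = rep(x, 2)), rep(time, 2), rep(event, 2),
                 ties = "breslow")
  expect_equal(unname(f1b$coef), unname(f2b$coef), tolerance = 1e-6)
  expect_error(cox_fit(data.frame(x = rep(1, n)), time, event), "constant")
})

test_that("cox fit recovers the generative hazard coefficient and honest nulls", {
  # recovery: log-hazard = 0.03 * (100 u), n = 500, mean over 10 replicates
  coefs <- vapply(1:10, function(r) {
    syn <- quiet(generate_cohort(n_samples = 500, n_genes = 2, n_informative = 1,
                                 seed = 700 + r))
    cox_fit(data.frame(score = 100 * syn$latent), syn$clin$time,
            syn$clin$event)$coef
  }, numeric(1))
  expect_lt(abs(mean(coefs) - 0.03), 0.2 * 0.03)
  # null covariate: 95% CI covers 0 in >= 90% of 20 replicates
  covered <- 0L
  for (r in 1:20) {
    set.seed(900 + r)
    n <- 120
    time <- rexp(n, 0.02); event <- rbinom(n, 1, 0.8)
    f <- cox_fit(data.frame(z = rnorm(n)), time, event)
    ci <- log(f$conf_int[, c("lower .95", "upper .95")])
    if (ci[1] <= 0 && 0 <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, 18L)
})

test_that("nested model comparison: identical models, noise models, invariants", {
  set.seed(71)
  n <- 150
  x <- rnorm(n)
  time <- rexp(n, 0.01 * exp(0.8 * x))
  event <- rbinom(n, 1, 0.85)
  # A = B: adding either adds nothing; adequacy 1 both sides
  same <- compare_models(data.frame(x = x), data.frame(x = x), time, event)
  expect_lt(same$lr_add_a_to_b, 1e-6)
  expect_gt(same$p_add_a_to_b, 0.999)
  expect_equal(same$adequacy_a, 1, tolerance = 1e-8)
  expect_equal(same$adequacy_b, 1, tolerance = 1e-8)
  # noise A: adequacy_a ~ 0 and LR(add B to A) ~ LR(B vs null), 20 replicates
  adq <- numeric(20); lr_gap <- numeric(20)
  for (r in 1:20) {
    set.seed(40 + r)
    x <- rnorm(n)
    time <- rexp(n, 0.01 * exp(0.8 * x))
    event <- rbinom(n, 1, 0.85)
    z <- rnorm(n)
    cmp <- compare_models(data.frame(z = z), data.frame(x = x), time, event)
    adq[r] <- cmp$adequacy_a
    lr_b_vs_null <- 2 * (cmp$loglik_b - cmp$loglik_null)
    lr_gap[r] <- abs(cmp$lr_add_b_to_a - lr_b_vs_null) / lr_b_vs_null
    # invariants on every fit
    expect_gte(cmp$loglik_full, max(cmp$loglik_a, cmp$loglik_b) - 1e-8)
    expect_gte(min(cmp$loglik_a, cmp$loglik_b), cmp$loglik_null - 1e-8)
    expect_gte(cmp$lr_add_a_to_b, 0)
    expect_gte(cmp$lr_add_b_to_a, 0)
    expect_true(cmp$adequacy_a >= 0 && cmp$adequacy_a <= 1)
    expect_true(cmp$adequacy_b >= 0 && cmp$adequacy_b <= 1)
  }
  expect_lt(mean(adq), 0.15)
  expect_lt(mean(lr_gap), 0.1)
})

test_that("Mann-Whitney agrees with the enumeration oracle and its symmetries", {
  r <- quiet(group_compare(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 20) # only the two extreme splits of C(6,3)
  expect_equal(r$p, mw_exact_oracle(c(1, 2, 3), c(4, 5, 6)))
  # identical groups: exact p = 1
  expect_equal(quiet(group_compare(c(2, 2, 5), c(2, 2, 5)))$p, 1)
  # swapping group names mirrors U about n1*n2/2
  x <- c(3, 1, 4, 1, 5); y <- c(9, 2, 6)
  a <- quiet(group_compare(x, y)); b <- quiet(group_compare(y, x))
  expect_equal(abs(a$U - length(x) * length(y) / 2),
               abs(b$U - length(x) * length(y) / 2))
  expect_equal(a$p, b$p)
  expect_error(group_compare(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney normal approximation holds its type-I error at n = 20", {
  set.seed(2024)
  n_rep <- 5000
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    x <- rnorm(10); y <- rnorm(10)
    p <- group_compare(x, y, exact_limit = 1)$p # force the approximation
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / n_rep, 0.07)
})
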