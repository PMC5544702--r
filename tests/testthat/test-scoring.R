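oracle_cfg <- function(...) clear_config(n_boot = 1, subset_fraction = 1, ...)

test_that("gene filter implements the >threshold-in->=fraction rule", {
  m <- matrix(10, 3, 5, dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
  expect_identical(quiet(filter_genes(m, 8, 0.10)), paste0("g", 1:3))
  m0 <- matrix(0, 3, 5, dimnames = dimnames(m))
  expect_error(quiet(filter_genes(m0, 8, 0.10)), "every gene")
  # gene A exceeds the cutoff in exactly 1 of 10 samples (= ceil(0.1*10)),
  # gene B in none; brute-force count is the oracle
  set.seed(4)
  m2 <- matrix(stats::runif(50, 5, 7.5), 5, 10,
               dimnames = list(c("gA", "gB", "gC", "gD", "gE"), paste0("s", 1:10)))
  m2["gA", 3] <- 9
  m2["gB", ] <- 5
  m2[c("gC", "gD", "gE"), 1:2] <- 9
  kept <- quiet(filter_genes(m2, 8, 0.10))
  brute <- rownames(m2)[vapply(rownames(m2),
    function(g) sum(m2[g, ] > 8) >= ceiling(0.10 * 10), logical(1))]
  expect_identical(kept, brute)
  expect_true("gA" %in% kept)
  expect_false("gB" %in% kept)
})

test_that("reference centroids equal per-gene median/mean of member samples", {
  m <- toy_expr(4, 5)
  cl <- toy_clin(colnames(m), grade = c(1, 1, 1, 4, 4))
  m["g01", 1:3] <- c(1, 2, 9)
  rss_med <- build_rss(m, cl, "grade", 1, 4, statistic = "median")
  rss_mean <- build_rss(m, cl, "grade", 1, 4, statistic = "mean")
  expect_equal(unname(rss_med$profile_low["g01"]), 2)
  expect_equal(unname(rss_mean$profile_low["g01"]), 4)
  # single-member extremes: centroid is that column exactly
  cl1 <- toy_clin(colnames(m), grade = c(1, 2, 2, 2, 4))
  rss1 <- build_rss(m, cl1, "grade", 1, 4)
  expect_equal(rss1$profile_low, m[, 1])
  expect_equal(rss1$profile_high, m[, 5])
  # size extremes are the bottom/top quartiles, matching a sort-based oracle
  cl2 <- toy_clin(colnames(toy_expr(4, 8)), grade = rep(c(1, 4), 4))
  cl2$size <- c(1, 2, 3, 4, 5, 6, 7, 8)
  m8 <- toy_expr(4, 8)
  rss_sz <- build_rss(m8, cl2, "size")
  qs <- sort(cl2$size)
  expect_setequal(rss_sz$members_low,
                  cl2$sample_id[cl2$size <= qs[ceiling(0.25 * 8)]])
  expect_setequal(rss_sz$members_high,
                  cl2$sample_id[cl2$size >= qs[8 - ceiling(0.25 * 8) + 1]])
  expect_error(build_rss(m, toy_clin(colnames(m), grade = rep(2, 5)), "grade", 1, 4),
               "extreme")
})

test_that("raw score matches the brute-force correlation-distance ratio", {
  # 6-gene toy from explicit sum-formula Pearson
  low <- c(1, 2, 3, 4, 5, 6); high <- c(6, 5, 4, 3, 2, 1)
  s <- c(1, 2, 3, 4, 5, 7)
  rss <- structure(list(gene_ids = paste0("g", 1:6),
                        profile_low = stats::setNames(low, paste0("g", 1:6)),
                        profile_high = stats::setNames(high, paste0("g", 1:6)),
                        n_low = 1, n_high = 1, clinical_axis = "grade"),
                   class = "clear_rss")
  expected <- (1 - pearson_by_hand(s, low)) / (1 - pearson_by_hand(s, high))
  got <- raw_score(stats::setNames(s, paste0("g", 1:6)), rss, oracle_cfg())
  expect_equal(got, expected, tolerance = 1e-12)
  # sample identical to the low profile: distance floored at epsilon, CS ~ 0
  got0 <- raw_score(stats::setNames(low, paste0("g", 1:6)), rss, oracle_cfg())
  expect_lt(got0, 1e-6)
  expect_gte(got0, 0)
})

test_that("swapping the two centroids returns the reciprocal score", {
  set.seed(21)
  genes <- paste0("g", 1:20)
  rss <- structure(list(gene_ids = genes,
                        profile_low = stats::setNames(rnorm(20, 9), genes),
                        profile_high = stats::setNames(rnorm(20, 9), genes),
                        n_low = 2, n_high = 2, clinical_axis = "grade"),
                   class = "clear_rss")
  swapped <- rss
  swapped$profile_low <- rss$profile_high
  swapped$profile_high <- rss$profile_low
  for (i in 1:5) {
    s <- stats::setNames(rnorm(20, 9), genes)
    a <- raw_score(s, rss, oracle_cfg())
    b <- raw_score(s, swapped, oracle_cfg())
    expect_equal(a, 1 / b, tolerance = 1e-12)
  }
})

test_that("scaling maps to [1,100] by the stated affine formula", {
  sc <- scale_scores(c(0.2, 0.5, 1.0))
  expect_equal(sc$scaled, c(1, 38.125, 100))
  expect_equal(sc$scale_min, 0.2)
  expect_equal(sc$scale_max, 1.0)
  expect_warning(deg <- scale_scores(c(3, 3)), "50.5")
  expect_equal(deg$scaled, c(50.5, 50.5))
  expect_error(scale_scores(1), "at least 2")
})

test_that("cohort scoring is seed-deterministic, order-invariant, and bounded", {
  m <- toy_expr(30, 12, seed = 31)
  cl <- toy_clin(colnames(m), grade = rep(c(1, 2, 3, 4), 3))
  rss <- build_rss(m, cl, "grade", 1, 4)
  cfg <- clear_config(seed = 99, n_boot = 20)
  r1 <- score_cohort(m, rss, cfg)
  r2 <- score_cohort(m, rss, cfg)
  expect_identical(r1$raw_scores, r2$raw_scores)
  expect_true(all(r1$scaled_scores >= 1 & r1$scaled_scores <= 100))
  expect_equal(min(r1$scaled_scores), 1)
  expect_equal(max(r1$scaled_scores), 100)
  expect_equal(sum(r1$scaled_scores == 1), 1)
  expect_equal(sum(r1$scaled_scores == 100), 1)
  # per-sample seeding: shuffling the cohort leaves each sample's score intact
  perm <- sample(ncol(m))
  r3 <- score_cohort(m[, perm], rss, cfg)
  expect_equal(stats::setNames(r3$raw_scores, r3$sample_ids)[r1$sample_ids],
               stats::setNames(r1$raw_scores, r1$sample_ids))
  # a copy of the low centroid attains the cohort minimum raw score
  m2 <- cbind(m, low_copy = rss$profile_low)
  colnames(m2)[ncol(m2)] <- "low_copy"
  r4 <- score_cohort(m2, rss, cfg)
  expect_equal(which.min(r4$raw_scores), which(r4$sample_ids == "low_copy"))
  expect_error(score_cohort(m[, 1, drop = FALSE], rss, cfg), "at least 2")
})

test_that("raw scores recover the latent ordering on a synthetic cohort", {
  syn <- quiet(generate_cohort(n_samples = 50, n_genes = 300,
                               n_informative = 20, seed = 5))
  res <- quiet(clear_score_pipeline(syn$expr, syn$clin,
                                    cfg = clear_config(seed = 5)))
  rho <- stats::cor(res$raw_scores, syn$latent[res$sample_ids],
                    method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("projection onto a fitted score reuses seeds, clamps, and guards overlap", {
  syn <- quiet(generate_cohort(n_samples = 40, n_genes = 200,
                               n_informative = 15, seed = 8))
  fitted <- quiet(clear_score_pipeline(syn$expr, syn$clin,
                                       cfg = clear_config(seed = 8)))
  # re-scoring members reproduces their fitted scaled scores exactly
  proj <- quiet(score_new_samples(syn$expr[fitted$rss$gene_ids, 1:5], fitted))
  expect_equal(proj$clear_score,
               fitted$scaled_scores[match(proj$sample_id, fitted$sample_ids)],
               tolerance = 1e-12)
  # 20 held-out samples on the same disease axis track the latent truth
  held <- quiet(generate_cohort(n_samples = 20, seed = 9,
                                archetypes = list(low = syn$archetype_low,
                                                  high = syn$archetype_high)))
  proj2 <- quiet(score_new_samples(held$expr, fitted))
  expect_true(all(proj2$clear_score >= 1 & proj2$clear_score <= 100))
  expect_gt(stats::cor(proj2$clear_score, held$latent[proj2$sample_id],
                       method = "spearman"), 0.7)
  # <50% gene overlap is a hard error
  few <- syn$expr[fitted$rss$gene_ids[1:10], 1:3]
  expect_error(quiet(score_new_samples(few, fitted)), "50%")
})

test_that("raw_corr distance kind is available and differs from the default", {
  low <- c(1, 2, 3, 4, 5, 6); high <- c(6, 5, 4, 3, 2, 1)
  genes <- paste0("g", 1:6)
  rss <- structure(list(gene_ids = genes,
                        profile_low = stats::setNames(low, genes),
                        profile_high = stats::setNames(high, genes),
                        n_low = 1, n_high = 1, clinical_axis = "grade"),
                   class = "clear_rss")
  s <- stats::setNames(c(1, 2, 3, 4, 5, 7), genes)
  got <- raw_score(s, rss, oracle_cfg(distance_kind = "raw_corr"))
  expect_equal(got, stats::cor(s, low) / stats::cor(s, high), tolerance = 1e-12)
})
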