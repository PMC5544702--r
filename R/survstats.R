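## survstats: survival validation and model comparison.
##
## Kaplan-Meier / log-rank and Cox proportional-hazards fits are backed by
## the survival package (Efron tie convention); the even-grouping rule, the
## nested likelihood-ratio comparison with its adequacy index, and the
## Mann-Whitney U test are implemented here.

#' Split samples into even groups along the score scale
#'
#' Samples are sorted ascending by score (ties broken by sample id, logged)
#' and cut into `n_groups` contiguous blocks whose sizes differ by at most
#' one, earlier groups taking the extra sample. Labels Q1..Qn ascend in
#' score.
#'
#' @param scores numeric vector, named by sample id (names optional).
#' @param n_groups number of groups (>= 2).
#' @return factor of labels Q1..Qn, one per input score, in input order.
#' @export
even_groups <- function(scores, n_groups) {
  n <- length(scores)
  if (n_groups < 2) stop("n_groups must be >= 2")
  if (n < n_groups) stop("fewer samples (", n, ") than groups (", n_groups, ")")
  ids <- names(scores) %||% as.character(seq_len(n))
  if (anyDuplicated(rank(scores, ties.method = "min")) &&
      any(duplicated(scores)))
    clear_log("survstats", "tied scores at a group boundary resolved by sample-id order")
  ord <- order(scores, ids)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  lab_sorted <- rep(paste0("Q", seq_len(n_groups)), times = sizes)
  labels <- character(n)
  labels[ord] <- lab_sorted
  factor(labels, levels = paste0("Q", seq_len(n_groups)))
}

#' Kaplan-Meier curves and the k-group log-rank test
#'
#' Product-limit survival estimates per group plus the log-rank chi-square
#' statistic with k - 1 degrees of freedom.
#'
#' @param groups factor of group labels per sample.
#' @param time follow-up time (months).
#' @param event 1 = event, 0 = censored.
#' @return list with `km` (data.frame: group, time, n_risk, n_event,
#'   survival), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(groups, time, event) {
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) == 0)) stop("every group must contain >= 1 sample")
  if (nlevels(groups) < 2) stop("log-rank needs >= 2 non-empty groups")
  sf <- survival::survfit(survival::Surv(time, event) ~ groups)
  ss <- summary(sf)
  grp <- if (is.null(ss$strata)) rep(levels(groups)[1], length(ss$time))
         else sub("^groups=", "", as.character(ss$strata))
  km <- data.frame(group = grp, time = ss$time, n_risk = ss$n.risk,
                   n_event = ss$n.event, survival = ss$surv,
                   stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- length(sd$n) - 1L
  list(km = km, chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with the reporting this package uses
#'
#' Partial-likelihood fit (Efron ties) reporting log-likelihoods, Wald and
#' score (log-rank) tests, and the Cox-Snell style pseudo-R2
#' 1 - exp((2/n)(loglik_null - loglik_model)).
#'
#' @param covariates data.frame (or vector) of per-sample covariates.
#' @param time,event survival outcome.
#' @param ties tie convention, default `"efron"`.
#' @return list: `fit` (coxph object), `loglik_null`, `loglik`, `coef`,
#'   `wald_p`, `score_p`, `pseudo_r2`, `n`.
#' @export
cox_fit <- function(covariates, time, event, ties = "efron") {
  X <- as.data.frame(covariates)
  if (any(vapply(X, function(v) length(unique(v)) == 1L, logical(1))))
    stop("constant covariate supplied; drop it before fitting")
  if (sum(event) < ncol(stats::model.matrix(~ ., X)) - 1L)
    stop("fewer events than covariates; fit is unidentifiable")
  dat <- cbind(X, .time = time, .event = event)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                         ties = ties)
  if (!is.null(fit$fail)) stop("proportional-hazards fit failed: ", fit$fail)
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 50))
    stop("divergent coefficient suggests separation; consider penalization")
  s <- summary(fit)
  n <- fit$n
  list(fit = fit,
       loglik_null = fit$loglik[1], loglik = fit$loglik[2],
       coef = stats::coef(fit),
       conf_int = s$conf.int,
       wald_p = unname(s$waldtest["pvalue"]),
       score_p = unname(s$sctest["pvalue"]),
       pseudo_r2 = 1 - exp((2 / n) * (fit$loglik[1] - fit$loglik[2])),
       n = n)
}

.loglik_null <- function(time, event) {
  ## null partial log-likelihood via any single-covariate fit's loglik[1]
  suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ rep(0:1, length.out = length(time)),
                    init = 0, control = survival::coxph.control(iter.max = 0))
  )$loglik[1]
}

#' Nested likelihood-ratio comparison of two covariate models
#'
#' Fits the null, A-only, B-only and A+B proportional-hazards models on the
#' same samples and reports: the LR chi-square for adding A to B (df =
#' number of A parameters) and vice versa; the adequacy index of each subset
#' model, (loglik_subset - loglik_null) / (loglik_full - loglik_null) — the
#' fraction of the full model's prognostic information the subset captures;
#' and pseudo-R2 per model. Nested log-likelihood monotonicity is enforced:
#' an apparent violation triggers a refit at tighter tolerance and then an
#' error if it persists.
#'
#' @param model_a,model_b data.frames (or vectors) of covariates on the same
#'   samples.
#' @param time,event survival outcome.
#' @return list of class `clear_model_comparison`; see fields in the
#'   description.
#' @export
compare_models <- function(model_a, model_b, time, event) {
  A <- as.data.frame(model_a); B <- as.data.frame(model_b)
  if (ncol(A) == 1 && identical(names(A), "model_a")) names(A) <- "a"
  if (ncol(B) == 1 && identical(names(B), "model_b")) names(B) <- "b"
  names(A) <- paste0("A_", names(A)); names(B) <- paste0("B_", names(B))
  if (nrow(A) != nrow(B) || nrow(A) != length(time))
    stop("model covariates must cover the same samples")
  fit_ll <- function(X, tol = 1e-9) {
    dat <- cbind(X, .time = time, .event = event)
    f <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                         ties = "efron",
                         control = survival::coxph.control(eps = tol,
                                                           iter.max = 50))
    f$loglik[2]
  }
  ll_null <- .loglik_null(time, event)
  df_a <- ncol(stats::model.matrix(~ ., A)) - 1L
  df_b <- ncol(stats::model.matrix(~ ., B)) - 1L
  compute <- function(tol) {
    c(a = fit_ll(A, tol), b = fit_ll(B, tol), full = fit_ll(cbind(A, B), tol))
  }
  ll <- compute(1e-9)
  if (ll["full"] < max(ll["a"], ll["b"]) - 1e-8 ||
      min(ll["a"], ll["b"]) < ll_null - 1e-8) {
    clear_log("survstats", "nested log-likelihood violation; refitting at tighter tolerance")
    ll <- compute(1e-12)
    if (ll["full"] < max(ll["a"], ll["b"]) - 1e-6)
      stop("nested log-likelihood monotonicity violated beyond tolerance")
  }
  ## guard against residual epsilon-level non-monotonicity
  ll["full"] <- max(ll)
  lr_add_a_to_b <- 2 * (ll["full"] - ll["b"])
  lr_add_b_to_a <- 2 * (ll["full"] - ll["a"])
  denom <- ll["full"] - ll_null
  adequacy <- function(ll_sub)
    if (denom <= 0) 1 else min(1, max(0, (ll_sub - ll_null) / denom))
  n <- length(time)
  pr2 <- function(ll_m) 1 - exp((2 / n) * (ll_null - ll_m))
  structure(list(
    loglik_null = ll_null, loglik_a = unname(ll["a"]),
    loglik_b = unname(ll["b"]), loglik_full = unname(ll["full"]),
    lr_add_a_to_b = unname(lr_add_a_to_b), df_add_a_to_b = df_a,
    p_add_a_to_b = stats::pchisq(lr_add_a_to_b, df_a, lower.tail = FALSE),
    lr_add_b_to_a = unname(lr_add_b_to_a), df_add_b_to_a = df_b,
    p_add_b_to_a = stats::pchisq(lr_add_b_to_a, df_b, lower.tail = FALSE),
    adequacy_a = adequacy(ll["a"]), adequacy_b = adequacy(ll["b"]),
    pseudo_r2_a = pr2(ll["a"]), pseudo_r2_b = pr2(ll["b"]),
    pseudo_r2_full = pr2(ll["full"])), class = "clear_model_comparison")
}

#' Two-group Mann-Whitney U comparison of scores
#'
#' Two-sided Mann-Whitney U test. When the number of group assignments
#' choose(n, n1) is at most `exact_limit` the p-value is computed by exact
#' permutation enumeration of U over all splits of the observed (possibly
#' tied) values; otherwise the normal approximation with tie correction and
#' continuity correction is used. Group medians are reported.
#'
#' @param x,y numeric score vectors for the two groups.
#' @param exact_limit enumeration cap (default 20000 splits).
#' @return list: `U` (for group x), `p`, `method`, `median_x`, `median_y`.
#' @export
group_compare <- function(x, y, exact_limit = 20000) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (choose(n1 + n2, n1) <= exact_limit) {
    ## exact permutation null of U over all splits of the observed ranks
    splits <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
    }
    method <- "normal approximation (tie + continuity corrected)"
  }
  list(U = U, p = p, method = method,
       median_x = stats::median(x), median_y = stats::median(y))
}
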