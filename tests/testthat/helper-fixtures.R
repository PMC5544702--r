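# Small in-code fixtures shared across test files.

# deterministic toy expression matrix (genes x samples)
toy_expr <- function(n_genes = 6, n_samples = 4, seed = 11, base = 10) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_samples, mean = base, sd = 1),
              n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

toy_clin <- function(sample_ids, grade = NULL, seed = 12) {
  set.seed(seed)
  n <- length(sample_ids)
  data.frame(sample_id = sample_ids,
             grade = grade %||% sample(c(1, 4), n, replace = TRUE),
             stage = sample(1:4, n, replace = TRUE),
             size = round(stats::runif(n, 2, 12), 1),
             time = round(stats::rexp(n, 0.02), 2),
             event = stats::rbinom(n, 1, 0.6),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Pearson from sums, independent of stats::cor
pearson_by_hand <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Kendall tau by explicit pair enumeration (tie-free fixtures)
kendall_by_inversions <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / choose(n, 2)
}

# Mann-Whitney exact two-sided p by enumerating group assignments;
# U computed by pairwise comparison counting (ties count 1/2)
mw_exact_oracle <- function(x, y) {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  obs <- abs(u_of(x, y) - mu)
  splits <- utils::combn(length(pooled), n1)
  us <- apply(splits, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= obs - 1e-12)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
quiet_msg <- function(expr) suppressMessages(expr) # keep warnings visible
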