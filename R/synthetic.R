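## synthetic_data: seeded cohort and multi-region generators with known
## ground truth, emulating a log-intensity microarray cohort whose samples
## lie on a continuum between two expression archetypes.
##
## Generative model: each sample carries a latent aggressiveness u in [0, 1];
## expression = (1 - u) * A_low + u * A_high + gene-level Gaussian noise,
## where the archetypes share a Normal(9, 1) background and differ by 2
## log-units on the informative genes. Grade, stage and size are monotone
## (noisy, for stage/size) transforms of u; survival is exponential with
## log-hazard proportional to u. Everything is reproducible bit-exactly from
## (params, seed) under the Mersenne-Twister PRNG.

#' Generate a synthetic expression cohort with ground truth
#'
#' @param n_samples cohort size (default 200).
#' @param n_genes total genes (default 1000).
#' @param n_informative genes loading on the latent axis (default 30),
#'   effect size 2 log-units between archetypes.
#' @param noise_sd per-gene Gaussian noise SD, log-units (default 1).
#' @param hazard_coef log-hazard slope per unit of the 0-100 latent scale
#'   (default 0.03); baseline hazard 0.003 events/month.
#' @param censor_rate exponential censoring rate, events/month (default
#'   0.005).
#' @param seed integer seed.
#' @param max_retry regenerations allowed when a tiny cohort lacks both
#'   latent extremes (u < 0.25 and u > 0.75), default 10.
#' @param archetypes optional list with `low` and `high` named archetype
#'   vectors from a previous generation, so new samples share the same gene
#'   geometry (same disease axis); overrides `n_genes`/`n_informative`.
#' @return list of class `clear_synthetic`: `expr`, `clin`, `latent`
#'   (named), `informative_genes`, `archetype_low`, `archetype_high`,
#'   `generator_params`.
#' @export
generate_cohort <- function(n_samples = 200, n_genes = 1000,
                            n_informative = 30, noise_sd = 1,
                            hazard_coef = 0.03, censor_rate = 0.005,
                            seed = 1L, max_retry = 10L, archetypes = NULL) {
  if (n_informative > n_genes) stop("n_informative must be <= n_genes")
  if (min(n_samples, n_genes, n_informative) < 1) stop("counts must be positive")
  params <- list(n_samples = n_samples, n_genes = n_genes,
                 n_informative = n_informative, noise_sd = noise_sd,
                 hazard_coef = hazard_coef, censor_rate = censor_rate,
                 seed = as.integer(seed))
  base_hazard <- 0.003
  for (attempt in seq_len(max_retry + 1L)) {
    out <- with_seed(seed + (attempt - 1L) * 7919L, {
      u <- stats::runif(n_samples)
      sample_ids <- sprintf("S%03d", seq_len(n_samples))
      if (is.null(archetypes)) {
        gene_ids <- sprintf("gene%04d", seq_len(n_genes))
        informative <- sort(sample.int(n_genes, n_informative))
        background <- stats::rnorm(n_genes, mean = 9, sd = 1)
        a_low <- background
        a_high <- background
        a_high[informative] <- a_high[informative] + 2
      } else {
        a_low <- unname(archetypes$low)
        a_high <- unname(archetypes$high)
        gene_ids <- names(archetypes$low)
        n_genes <- length(a_low)
        informative <- which(a_high != a_low)
      }
      mean_expr <- outer(a_low, 1 - u) + outer(a_high, u)
      expr <- mean_expr + matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                                 n_genes, n_samples)
      dimnames(expr) <- list(gene_ids, sample_ids)
      grade <- pmin(1 + floor(4 * u), 4)
      stage <- pmin(pmax(1 + floor(4 * (u + stats::rnorm(n_samples, sd = 0.08))), 1), 4)
      size <- pmax(0.5, 2 + 10 * u + stats::rnorm(n_samples, sd = 1))
      rate <- base_hazard * exp(hazard_coef * 100 * u)
      t_event <- stats::rexp(n_samples, rate = rate)
      t_cens <- if (censor_rate > 0) stats::rexp(n_samples, rate = censor_rate)
                else rep(Inf, n_samples)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
      clin <- data.frame(sample_id = sample_ids, grade = grade, stage = stage,
                         size = size, time = time, event = event,
                         stringsAsFactors = FALSE)
      list(expr = expr, clin = as_clinical_table(clin),
           latent = stats::setNames(u, sample_ids),
           informative_genes = gene_ids[informative],
           archetype_low = stats::setNames(a_low, gene_ids),
           archetype_high = stats::setNames(a_high, gene_ids))
    })
    if (any(out$latent < 0.25) && any(out$latent > 0.75)) break
    if (attempt > max_retry)
      stop("could not generate a cohort covering both latent extremes")
    warning("cohort missing a latent extreme; regenerating (attempt ",
            attempt + 1L, ")", call. = FALSE)
  }
  out$generator_params <- params
  class(out) <- "clear_synthetic"
  out
}

#' Generate synthetic multi-region tumors
#'
#' Each tumor draws a latent center from Normal(0.5, `inter_sd`) truncated to
#' [0, 1]; each of its regions perturbs that center by Normal(0, `intra_sd`),
#' truncated likewise. Region expression and clinical fields are generated
#' exactly as in [generate_cohort()] from the region latents. When
#' `regions_per_tumor` is `NULL`, counts are drawn uniformly from 4..9 with
#' rejection until they sum to `round(6.5 * n_tumors)` — 65 regions for 10
#' tumors, matching the multi-region layout the heterogeneity analysis was
#' designed around.
#'
#' @param n_tumors number of tumors (default 10).
#' @param regions_per_tumor integer scalar or vector of region counts, or
#'   `NULL` to draw them (see above).
#' @param inter_sd SD of tumor latent centers (default 0.15).
#' @param intra_sd SD of region latents around their center (default 0.05).
#' @param n_genes,n_informative,noise_sd,hazard_coef,censor_rate,archetypes
#'   as in [generate_cohort()]; pass a main cohort's archetypes to place the
#'   regions on that cohort's disease axis.
#' @param seed integer seed.
#' @return `clear_synthetic` list whose `clin` carries `tumor_id`, plus
#'   `tumor_centers` (named by tumor id).
#' @export
generate_multiregion <- function(n_tumors = 10, regions_per_tumor = NULL,
                                 inter_sd = 0.15, intra_sd = 0.05,
                                 n_genes = 1000, n_informative = 30,
                                 noise_sd = 1, hazard_coef = 0.03,
                                 censor_rate = 0.005, seed = 1L,
                                 archetypes = NULL) {
  if (inter_sd < 0 || intra_sd < 0) stop("inter_sd and intra_sd must be >= 0")
  if (!is.null(regions_per_tumor)) {
    regions_per_tumor <- rep_len(as.integer(regions_per_tumor), n_tumors)
    if (any(regions_per_tumor < 1)) stop("regions_per_tumor must be >= 1")
  }
  with_seed(seed, {
    if (is.null(regions_per_tumor)) {
      target <- round(6.5 * n_tumors)
      for (try in 1:1000) {
        regions_per_tumor <- sample(4:9, n_tumors, replace = TRUE)
        if (sum(regions_per_tumor) == target) break
      }
      if (sum(regions_per_tumor) != target)
        clear_log("synthetic", "region-count rejection cap reached; total = ",
                  sum(regions_per_tumor))
    }
    n_regions <- sum(regions_per_tumor)
    tumor_ids <- sprintf("T%02d", seq_len(n_tumors))
    trunc01 <- function(x) pmin(pmax(x, 0), 1)
    centers <- trunc01(stats::rnorm(n_tumors, 0.5, inter_sd))
    tumor_of <- rep(tumor_ids, times = regions_per_tumor)
    u <- trunc01(rep(centers, times = regions_per_tumor) +
                   stats::rnorm(n_regions, 0, intra_sd))
    region_idx <- unlist(lapply(regions_per_tumor, seq_len))
    sample_ids <- sprintf("%s_R%d", tumor_of, region_idx)
    if (is.null(archetypes)) {
      gene_ids <- sprintf("gene%04d", seq_len(n_genes))
      informative <- sort(sample.int(n_genes, n_informative))
      background <- stats::rnorm(n_genes, mean = 9, sd = 1)
      a_low <- background
      a_high <- background
      a_high[informative] <- a_high[informative] + 2
    } else {
      a_low <- unname(archetypes$low)
      a_high <- unname(archetypes$high)
      gene_ids <- names(archetypes$low)
      n_genes <- length(a_low)
      informative <- which(a_high != a_low)
    }
    expr <- outer(a_low, 1 - u) + outer(a_high, u) +
      matrix(stats::rnorm(n_genes * n_regions, sd = noise_sd), n_genes, n_regions)
    dimnames(expr) <- list(gene_ids, sample_ids)
    rate <- 0.003 * exp(hazard_coef * 100 * u)
    t_event <- stats::rexp(n_regions, rate = rate)
    t_cens <- if (censor_rate > 0) stats::rexp(n_regions, rate = censor_rate)
              else rep(Inf, n_regions)
    clin <- data.frame(sample_id = sample_ids,
                       grade = pmin(1 + floor(4 * u), 4),
                       stage = pmin(pmax(1 + floor(4 * (u + stats::rnorm(n_regions, sd = 0.08))), 1), 4),
                       size = pmax(0.5, 2 + 10 * u + stats::rnorm(n_regions, sd = 1)),
                       time = pmin(t_event, t_cens),
                       event = as.integer(t_event <= t_cens),
                       tumor_id = tumor_of, stringsAsFactors = FALSE)
    structure(list(expr = expr, clin = as_clinical_table(clin),
                   latent = stats::setNames(u, sample_ids),
                   informative_genes = gene_ids[informative],
                   archetype_low = stats::setNames(a_low, gene_ids),
                   archetype_high = stats::setNames(a_high, gene_ids),
                   tumor_centers = stats::setNames(centers, tumor_ids),
                   generator_params = list(n_tumors = n_tumors,
                                           regions_per_tumor = regions_per_tumor,
                                           inter_sd = inter_sd, intra_sd = intra_sd,
                                           n_genes = n_genes,
                                           n_informative = n_informative,
                                           noise_sd = noise_sd,
                                           hazard_coef = hazard_coef,
                                           censor_rate = censor_rate,
                                           seed = as.integer(seed))),
              class = "clear_synthetic")
  })
}
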