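## heterogeneity: score stability under reference resampling, and
## intra- vs intertumoral heterogeneity of multi-region scores.

#' Raw median absolute deviation
#'
#' median(|x - median(x)|) with no consistency constant by default — the MAD
#' is used descriptively here, not as a robust sigma estimate. Pass
#' `constant = 1.4826` for normal consistency.
#'
#' @param x numeric vector.
#' @param constant scale constant (default 1).
#' @return non-negative scalar.
#' @export
mad_raw <- function(x, constant = 1) {
  constant * stats::median(abs(x - stats::median(x)))
}

#' Score stability under reference-set resampling
#'
#' Draws `n_replicates` bootstrap resamples (with replacement) of the
#' members of each clinical-extreme group, rebuilds the centroid pair from
#' each resample, rescores the whole cohort, and summarises each sample's
#' raw-score variation across replicates by the MAD. Replicates are required
#' to be unique membership combinations, enforced by rejection up to a retry
#' cap (then allowed, with a warning). With a single member on both extremes
#' resampling is degenerate: MADs are trivially 0, with a warning.
#'
#' @param expr genes x samples matrix (filtered genes).
#' @param clin clinical table covering the samples.
#' @param axis clinical factor anchoring the extremes.
#' @param n_replicates number of resampled reference pairs (the published
#'   procedure used 500).
#' @param cfg `clear_config`.
#' @param low,high extreme values (see [build_rss()]).
#' @return list of class `clear_stability`: `sample_ids`, `per_sample_mad`
#'   (raw-score units), `n_replicates`, `replicate_scores` (samples x
#'   replicates matrix).
#' @export
rss_stability <- function(expr, clin, axis = "grade", n_replicates = 500,
                          cfg = clear_config(), low = NULL, high = NULL) {
  base <- build_rss(expr, clin, axis = axis, low = low, high = high,
                    statistic = cfg$centroid_statistic)
  if (base$n_low < 2 && base$n_high < 2)
    warning("only one sample per extreme; resampling is degenerate and MADs are 0",
            call. = FALSE)
  fun <- if (cfg$centroid_statistic == "median") stats::median else mean
  seen <- character(0)
  reps <- with_seed(cfg$seed, {
    draws <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      tries <- 0L
      repeat {
        ml <- sort(sample(base$members_low, base$n_low, replace = TRUE))
        mh <- sort(sample(base$members_high, base$n_high, replace = TRUE))
        key <- paste(c(ml, "|", mh), collapse = ",")
        tries <- tries + 1L
        if (base$n_low == 1L && base$n_high == 1L) break # single combination exists
        if (!key %in% seen) { seen <- c(seen, key); break }
        if (tries >= 50L) {
          warning("could not find a unique reference combination after 50 tries; reusing one",
                  call. = FALSE)
          break
        }
      }
      draws[[r]] <- list(ml = ml, mh = mh)
    }
    draws
  })
  score_one <- function(d) {
    rss <- base
    rss$profile_low <- apply(expr[, d$ml, drop = FALSE], 1L, fun)
    rss$profile_high <- apply(expr[, d$mh, drop = FALSE], 1L, fun)
    if (stats::sd(rss$profile_low) == 0 || stats::sd(rss$profile_high) == 0)
      return(rep(NA_real_, ncol(expr)))
    vapply(colnames(expr), function(id)
      raw_score(expr[, id], rss, cfg, seed = per_sample_seed(cfg$seed, id)),
      numeric(1))
  }
  mat <- vapply(reps, score_one, numeric(ncol(expr)))
  mat <- matrix(mat, nrow = ncol(expr),
                dimnames = list(colnames(expr), NULL))
  mads <- apply(mat, 1L, function(v) mad_raw(v[is.finite(v)]))
  structure(list(sample_ids = colnames(expr), per_sample_mad = unname(mads),
                 n_replicates = n_replicates, replicate_scores = mat),
            class = "clear_stability")
}

#' Intra- versus intertumoral heterogeneity of region scores
#'
#' Given one score per tumor region and the region-to-tumor mapping: per
#' tumor, the median score and the MAD across its regions; the pooled MAD of
#' all regions; the Pearson correlation (with p) between per-tumor median
#' score and per-tumor MAD (tumors with >= 2 regions); and a one-way ANOVA
#' comparing absolute deviations from each region's own tumor median
#' ("intra") against absolute deviations from the pooled median ("inter") —
#' a reconstruction of the published dispersion comparison. A permutation
#' alternative (`perm_p`, tumor labels shuffled) is reported alongside.
#'
#' @param region_scores numeric scores, one per region.
#' @param region_to_tumor tumor id per region.
#' @param n_perm permutation replicates for the alternative test (default
#'   1000; set 0 to skip).
#' @return list of class `clear_heterogeneity`: `per_tumor` (data.frame
#'   tumor_id, n_regions, median_score, mad), `pooled_mad`,
#'   `mad_score_correlation` (r, p), `inter_vs_intra_p`, `perm_p`.
#' @export
multiregion_heterogeneity <- function(region_scores, region_to_tumor,
                                      n_perm = 1000) {
  tumor <- as.character(region_to_tumor)
  if (length(tumor) != length(region_scores))
    stop("one tumor id per region score required")
  if (length(unique(tumor)) < 2) stop("need >= 2 tumors")
  counts <- table(tumor)
  if (all(counts < 2)) stop("every tumor has a single region; MAD undefined")
  per_tumor <- data.frame(
    tumor_id = names(counts),
    n_regions = as.integer(counts),
    median_score = as.numeric(tapply(region_scores, tumor, stats::median)[names(counts)]),
    mad = as.numeric(tapply(region_scores, tumor, mad_raw)[names(counts)]),
    stringsAsFactors = FALSE)
  pooled_mad <- mad_raw(region_scores)
  multi <- per_tumor[per_tumor$n_regions >= 2, ]
  corr <- if (nrow(multi) >= 3 && stats::sd(multi$mad) > 0 &&
              stats::sd(multi$median_score) > 0) {
    ct <- stats::cor.test(multi$median_score, multi$mad, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value)
  } else list(r = NA_real_, p = NA_real_)
  ## dispersion comparison: |dev from own tumor median| vs |dev from pooled median|
  tumor_median <- stats::setNames(per_tumor$median_score, per_tumor$tumor_id)
  intra_dev <- abs(region_scores - tumor_median[tumor])
  inter_dev <- abs(region_scores - stats::median(region_scores))
  dev <- c(intra_dev, inter_dev)
  grp <- factor(rep(c("intra", "inter"), each = length(region_scores)))
  anova_p <- stats::anova(stats::lm(dev ~ grp))[["Pr(>F)"]][1]
  perm_p <- NA_real_
  if (n_perm > 0) {
    obs <- mean(inter_dev) - mean(intra_dev)
    perm <- with_seed(sum(utf8ToInt("heterogeneity")), {
      vapply(seq_len(n_perm), function(i) {
        sh <- sample(tumor)
        med <- tapply(region_scores, sh, stats::median)
        mean(inter_dev) - mean(abs(region_scores - med[sh]))
      }, numeric(1))
    })
    perm_p <- (sum(perm >= obs) + 1) / (n_perm + 1)
  }
  structure(list(per_tumor = per_tumor, pooled_mad = pooled_mad,
                 mad_score_correlation = corr,
                 inter_vs_intra_p = anova_p, perm_p = perm_p),
            class = "clear_heterogeneity")
}
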