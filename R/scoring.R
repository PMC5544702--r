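## scoring: the continuous-score core.
##
## A sample's raw score is the bootstrap average, over m random gene subsets,
## of the ratio d(sample, low centroid) / d(sample, high centroid), where d
## is a correlation distance to a reference centroid anchored at a clinical
## extreme (grade 1 vs grade 4 by default). Raw scores are then min-max
## scaled to [1, 100] on the cohort that fitted them.

#' Filter genes by expression prevalence
#'
#' Keeps genes whose log expression exceeds `threshold` in at least
#' `ceiling(fraction * n_samples)` samples — the published training filter
#' (cutoff 8, fraction 0.10). Input gene order is preserved.
#'
#' @param expr genes x samples matrix.
#' @param threshold log-expression cutoff.
#' @param fraction minimum proportion of samples above the cutoff.
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(expr, threshold = 8, fraction = 0.10) {
  as_expression_matrix(expr)
  need <- ceiling(fraction * ncol(expr))
  keep <- rowSums(expr > threshold) >= need
  if (!any(keep))
    stop("gene filter removed every gene; relax threshold (", threshold,
         ") or fraction (", fraction, ")")
  clear_log("scoring", sprintf("gene filter: kept %d / %d genes (> %g in >= %d samples)",
                               sum(keep), nrow(expr), threshold, need))
  rownames(expr)[keep]
}

#' Build the pair of reference centroids (RSS profiles)
#'
#' The two reference sample sets (RSSs) are the samples at the two clinical
#' extremes of `axis`: for grade/stage, samples whose value equals `low` /
#' `high` (defaults 1 and 4 for grade, observed min and max for stage); for
#' size, the bottom and top `quantile_cut` quartiles. Per-gene centroids are
#' the median (default) or mean over each set's members. The caller passes
#' the already-filtered matrix; its gene set becomes the profile gene set G.
#'
#' @param expr genes x samples matrix (filtered genes).
#' @param clin clinical table covering `colnames(expr)`.
#' @param axis `"grade"`, `"stage"` or `"size"`.
#' @param low,high extreme values for an ordinal axis; ignored for size.
#' @param statistic `"median"` or `"mean"`.
#' @param quantile_cut tail fraction defining size extremes (default 0.25).
#' @return list of class `clear_rss` with `gene_ids`, `profile_low`,
#'   `profile_high`, `n_low`, `n_high`, `clinical_axis`, and the member
#'   sample ids `members_low` / `members_high`.
#' @export
build_rss <- function(expr, clin, axis = c("grade", "stage", "size"),
                      low = NULL, high = NULL,
                      statistic = c("median", "mean"), quantile_cut = 0.25) {
  axis <- match.arg(axis)
  statistic <- match.arg(statistic)
  clin <- as_clinical_table(clin)
  clin <- clin[match(colnames(expr), clin$sample_id), , drop = FALSE]
  if (anyNA(clin$sample_id))
    stop("clinical table does not cover all expression samples; align first")
  v <- clin[[axis]]
  if (is.null(v)) stop("clinical table has no '", axis, "' column")
  if (axis == "size") {
    qs <- stats::quantile(v, c(quantile_cut, 1 - quantile_cut), na.rm = TRUE,
                          names = FALSE)
    members_low <- clin$sample_id[!is.na(v) & v <= qs[1]]
    members_high <- clin$sample_id[!is.na(v) & v >= qs[2]]
  } else {
    if (is.null(low)) low <- min(v, na.rm = TRUE)
    if (is.null(high)) high <- max(v, na.rm = TRUE)
    members_low <- clin$sample_id[!is.na(v) & v == low]
    members_high <- clin$sample_id[!is.na(v) & v == high]
  }
  if (!length(members_low) || !length(members_high))
    stop("no samples at the ", if (!length(members_low)) "low" else "high",
         " extreme of ", axis)
  fun <- if (statistic == "median") stats::median else mean
  centroid <- function(ids) apply(expr[, ids, drop = FALSE], 1L, fun)
  profile_low <- centroid(members_low)
  profile_high <- centroid(members_high)
  if (stats::sd(profile_low) == 0 || stats::sd(profile_high) == 0)
    stop("constant reference centroid; correlation to it is undefined")
  structure(list(gene_ids = rownames(expr),
                 profile_low = profile_low, profile_high = profile_high,
                 n_low = length(members_low), n_high = length(members_high),
                 members_low = members_low, members_high = members_high,
                 clinical_axis = axis, statistic = statistic),
            class = "clear_rss")
}

## Columnwise Pearson correlation between paired columns of two matrices;
## spearman = pearson on columnwise ranks. Vectorized across bootstrap draws.
.corr_cols <- function(X, Y, method) {
  if (method == "spearman") {
    X <- apply(X, 2L, rank)
    Y <- apply(Y, 2L, rank)
  }
  k <- nrow(X)
  mx <- colMeans(X); my <- colMeans(Y)
  cov <- colSums(X * Y) / k - mx * my
  vx <- colSums(X * X) / k - mx * mx
  vy <- colSums(Y * Y) / k - my * my
  cov / sqrt(vx * vy)
}

## Correlation distance of a vector to both centroids over one gene subset.
.dist_pair <- function(s, rss, idx, cfg) {
  c1 <- stats::cor(s[idx], rss$profile_low[idx], method = cfg$correlation_method)
  c2 <- stats::cor(s[idx], rss$profile_high[idx], method = cfg$correlation_method)
  if (cfg$distance_kind == "one_minus_corr") c(1 - c1, 1 - c2) else c(c1, c2)
}

#' Raw correlation-ratio score of one sample
#'
#' Draws `n_boot` gene subsets of size `round(subset_fraction * |G|)`
#' (without replacement within each draw), computes the correlation distance
#' of the sample to each reference centroid over each subset, and returns the
#' mean of the per-draw ratios d_low / d_high. Distances are floored at
#' `epsilon` so the ratio is always finite; a draw whose correlation is
#' undefined (constant subset) is redrawn and logged, and more than 50%
#' redraws is an error.
#'
#' @param sample_vector named numeric vector over `rss$gene_ids`.
#' @param rss `clear_rss` centroid pair.
#' @param cfg `clear_config`.
#' @param seed seed for this sample's draws (default `cfg$seed`).
#' @return single non-negative raw score.
#' @export
raw_score <- function(sample_vector, rss, cfg = clear_config(), seed = cfg$seed) {
  n <- length(rss$gene_ids)
  if (!is.null(names(sample_vector)))
    sample_vector <- sample_vector[rss$gene_ids]
  if (length(sample_vector) != n || anyNA(sample_vector))
    stop("sample vector must cover every profile gene")
  k <- round(cfg$subset_fraction * n)
  if (k < 3) stop("bootstrap subset of ", k, " genes is too small (< 3)")
  with_seed(seed, {
    B <- cfg$n_boot
    idx <- if (k == n) matrix(seq_len(n), n, B)
           else vapply(seq_len(B), function(b) sample.int(n, k), integer(k))
    idx <- matrix(idx, nrow = k)
    c1 <- .corr_cols(matrix(sample_vector[idx], k),
                     matrix(rss$profile_low[idx], k), cfg$correlation_method)
    c2 <- .corr_cols(matrix(sample_vector[idx], k),
                     matrix(rss$profile_high[idx], k), cfg$correlation_method)
    ## redraw draws whose correlation is undefined (constant subset)
    redraws <- 0L
    max_redraws <- ceiling(0.5 * B)
    for (b in which(!is.finite(c1) | !is.finite(c2))) {
      repeat {
        redraws <- redraws + 1L
        clear_log_verbose("scoring", "redrew degenerate gene subset (draw ", b, ")")
        if (redraws > max_redraws)
          stop("more than 50% of bootstrap draws degenerate; check input variance")
        i2 <- if (k == n) seq_len(n) else sample.int(n, k)
        d <- .dist_pair(sample_vector, rss, i2, cfg)
        if (all(is.finite(d))) break
      }
      if (cfg$distance_kind == "one_minus_corr") {
        c1[b] <- 1 - d[1]; c2[b] <- 1 - d[2]
      } else {
        c1[b] <- d[1]; c2[b] <- d[2]
      }
    }
    if (redraws > 0L)
      clear_log("scoring", redraws, " degenerate draw(s) redrawn")
    d1 <- if (cfg$distance_kind == "one_minus_corr") pmax(1 - c1, cfg$epsilon)
          else ifelse(c1 >= 0, 1, -1) * pmax(abs(c1), cfg$epsilon)
    d2 <- if (cfg$distance_kind == "one_minus_corr") pmax(1 - c2, cfg$epsilon)
          else ifelse(c2 >= 0, 1, -1) * pmax(abs(c2), cfg$epsilon)
    mean(d1 / d2)
  })
}

#' Min-max scale raw scores to [1, 100]
#'
#' Affine map sending the cohort minimum to 1 and maximum to 100:
#' S = (CS - min) / (max - min) * 99 + 1. If all raw scores coincide every
#' sample gets the midpoint 50.5 with a prominent warning.
#'
#' @param raw_scores numeric vector, length >= 2.
#' @return list with `scaled` scores and the fitted `scale_min`, `scale_max`.
#' @export
scale_scores <- function(raw_scores) {
  if (length(raw_scores) < 2) stop("scaling needs at least 2 scores")
  lo <- min(raw_scores); hi <- max(raw_scores)
  if (hi == lo) {
    warning("all raw scores identical; scaled scores degenerate to 50.5",
            call. = FALSE)
    return(list(scaled = rep(50.5, length(raw_scores)),
                scale_min = lo, scale_max = hi))
  }
  list(scaled = (raw_scores - lo) / (hi - lo) * 99 + 1,
       scale_min = lo, scale_max = hi)
}

#' Score a cohort against a fitted centroid pair
#'
#' Computes the raw correlation-ratio score of every sample with a per-sample
#' seed derived from `cfg$seed` and a stable hash of the sample id (so scores
#' do not depend on cohort order or subsetting), then fits the [1, 100]
#' scaling on this cohort.
#'
#' @param expr genes x samples matrix restricted to `rss$gene_ids`.
#' @param rss `clear_rss`.
#' @param cfg `clear_config`.
#' @return list of class `clear_scores`: `sample_ids`, `raw_scores`,
#'   `scaled_scores`, `scale_min`, `scale_max`, `params`, `rss`.
#' @export
score_cohort <- function(expr, rss, cfg = clear_config()) {
  if (ncol(expr) < 2) stop("scoring a cohort needs at least 2 samples")
  if (!identical(rownames(expr), rss$gene_ids))
    expr <- expr[rss$gene_ids, , drop = FALSE]
  ids <- colnames(expr)
  raw <- vapply(ids, function(id)
    raw_score(expr[, id], rss, cfg, seed = per_sample_seed(cfg$seed, id)),
    numeric(1))
  sc <- scale_scores(raw)
  structure(list(sample_ids = ids,
                 raw_scores = unname(raw),
                 scaled_scores = unname(sc$scaled),
                 scale_min = sc$scale_min, scale_max = sc$scale_max,
                 params = cfg, rss = rss),
            class = "clear_scores")
}

#' Project new samples onto a fitted score
#'
#' Scores out-of-cohort samples with the stored config, centroids and
#' per-sample seeding, applies the stored scaling bounds, and clamps to
#' [1, 100] (clamped samples are logged). Requires at least 50% overlap with
#' the fitted gene set; scoring then uses the shared genes.
#'
#' @param expr genes x samples matrix for the new samples.
#' @param fitted `clear_scores` from [score_cohort()].
#' @return data.frame with `sample_id`, `raw_score`, `clear_score`.
#' @export
score_new_samples <- function(expr, fitted) {
  rss <- fitted$rss
  cfg <- fitted$params
  shared <- intersect(rss$gene_ids, rownames(expr))
  if (length(shared) < 0.5 * length(rss$gene_ids))
    stop(sprintf("only %d of %d profile genes present (< 50%%); cannot project",
                 length(shared), length(rss$gene_ids)))
  if (length(shared) < length(rss$gene_ids)) {
    clear_log("scoring", sprintf("projecting on %d shared genes (of %d fitted)",
                                 length(shared), length(rss$gene_ids)))
    rss$gene_ids <- shared
    rss$profile_low <- rss$profile_low[shared]
    rss$profile_high <- rss$profile_high[shared]
  }
  ids <- colnames(expr)
  raw <- vapply(ids, function(id)
    raw_score(expr[shared, id], rss, cfg, seed = per_sample_seed(cfg$seed, id)),
    numeric(1))
  span <- fitted$scale_max - fitted$scale_min
  scaled <- if (span == 0) rep(50.5, length(raw))
            else (raw - fitted$scale_min) / span * 99 + 1
  clamped <- scaled < 1 | scaled > 100
  if (any(clamped)) {
    warning(sum(clamped), " sample(s) outside the fitted score range; clamped to [1, 100]",
            call. = FALSE)
    clear_log("scoring", "clamped: ", paste(ids[clamped], collapse = ", "))
    scaled <- pmin(pmax(scaled, 1), 100)
  }
  data.frame(sample_id = ids, raw_score = unname(raw),
             clear_score = unname(scaled), stringsAsFactors = FALSE)
}

#' End-to-end cohort scoring from raw inputs
#'
#' Convenience wrapper: align samples, apply the gene filter, build the
#' centroid pair on `axis`, and score the cohort.
#'
#' @param expr genes x samples matrix (unfiltered).
#' @param clin clinical table.
#' @param axis clinical factor anchoring the extremes.
#' @param low,high extreme values (see [build_rss()]).
#' @param cfg `clear_config`.
#' @return `clear_scores` (with the clinical table used attached as `clin`).
#' @export
clear_score_pipeline <- function(expr, clin, axis = "grade", low = NULL,
                                 high = NULL, cfg = clear_config()) {
  al <- align_samples(expr, clin)
  genes <- filter_genes(al$expr, cfg$gene_filter_threshold, cfg$gene_filter_fraction)
  ex <- al$expr[genes, , drop = FALSE]
  rss <- build_rss(ex, al$clin, axis = axis, low = low, high = high,
                   statistic = cfg$centroid_statistic)
  res <- score_cohort(ex, rss, cfg)
  res$clin <- al$clin
  res
}
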