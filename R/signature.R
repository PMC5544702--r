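## signature: derive the compact transcript signature driving the score.
##
## Three sample ranking queues (grade-, stage- and size-anchored scores),
## per-gene Spearman and Kendall screens against each queue, intersection of
## the per-queue top/bottom tails, and a survival-based final selection.

#' Build the three clinical ranking queues
#'
#' Scores the cohort three times — extremes anchored on grade, stage and size
#' respectively, sharing one config — and ranks samples ascending by score.
#' Ties are broken by sample id so queues are deterministic. An axis whose
#' extremes cannot be formed is skipped with a warning; fewer than 2 usable
#' queues is an error.
#'
#' @param expr genes x samples matrix (unfiltered; the shared filter is
#'   applied once here).
#' @param clin clinical table.
#' @param cfg `clear_config`.
#' @return named list of queues; each queue is a list with `sample_ids`
#'   (ascending score order) and `axis`.
#' @export
build_queues <- function(expr, clin, cfg = clear_config()) {
  al <- align_samples(expr, clin)
  genes <- filter_genes(al$expr, cfg$gene_filter_threshold, cfg$gene_filter_fraction)
  ex <- al$expr[genes, , drop = FALSE]
  queues <- list()
  for (axis in c("grade", "stage", "size")) {
    q <- tryCatch({
      rss <- build_rss(ex, al$clin, axis = axis,
                       low = if (axis == "grade") 1 else NULL,
                       high = if (axis == "grade") 4 else NULL,
                       statistic = cfg$centroid_statistic)
      sc <- score_cohort(ex, rss, cfg)
      ord <- order(sc$scaled_scores, sc$sample_ids)
      list(sample_ids = sc$sample_ids[ord], axis = axis)
    }, error = function(e) {
      warning("queue for axis '", axis, "' omitted: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(q)) queues[[axis]] <- q
  }
  if (length(queues) < 2)
    stop("fewer than 2 ranking queues could be built; check grade/stage/size data")
  queues
}

#' Rank-correlate every gene with a sample ranking queue
#'
#' For each gene, the Spearman or Kendall correlation between the queue
#' position (1 = lowest score) and the gene's expression across the queued
#' samples. Constant genes get correlation 0 and are flagged.
#'
#' @param expr genes x samples matrix.
#' @param queue queue list from [build_queues()].
#' @param method `"spearman"` or `"kendall"`.
#' @return named numeric vector of correlations with attribute
#'   `constant_genes` (ids recorded as 0).
#' @export
gene_queue_correlation <- function(expr, queue, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  if (!all(queue$sample_ids %in% colnames(expr)))
    stop("queue contains samples absent from the expression matrix")
  ex <- expr[, queue$sample_ids, drop = FALSE]
  pos <- seq_along(queue$sample_ids)
  const <- apply(ex, 1L, stats::sd) == 0
  r <- rep(0, nrow(ex))
  names(r) <- rownames(ex)
  if (any(!const))
    r[!const] <- drop(stats::cor(pos, t(ex[!const, , drop = FALSE]),
                                 method = method))
  if (any(const))
    clear_log("signature", sum(const), " constant gene(s) recorded as correlation 0")
  attr(r, "constant_genes") <- rownames(ex)[const]
  r
}

#' Screen candidate genes across queues
#'
#' Per queue, each gene's screen statistic is the mean of its Spearman and
#' Kendall correlations with the queue. The `top_k_each_tail` most positive
#' and most negative genes of every queue form that queue's candidate set;
#' candidates common to all queues (set intersection) are ranked by mean
#' absolute screen statistic and the first `n_common` returned. An empty
#' intersection falls back to the union, with a warning.
#'
#' @param expr genes x samples matrix (filtered genes).
#' @param queues list of queues from [build_queues()].
#' @param top_k_each_tail genes kept per tail per queue (default 100).
#' @param n_common final candidate count (default 50, the published size).
#' @return list with `candidates` (gene ids, ranked), and `per_gene` — a
#'   data.frame of per-(gene, queue) Spearman/Kendall values.
#' @export
candidate_genes <- function(expr, queues, top_k_each_tail = 100, n_common = 50) {
  if (length(queues) < 2) stop("need at least 2 queues")
  stats_list <- lapply(queues, function(q) {
    sp <- gene_queue_correlation(expr, q, "spearman")
    kd <- gene_queue_correlation(expr, q, "kendall")
    data.frame(gene_id = names(sp), axis = q$axis,
               spearman = unname(sp), kendall = unname(kd),
               screen = unname((sp + kd) / 2), stringsAsFactors = FALSE)
  })
  per_queue_sets <- lapply(stats_list, function(df) {
    ord <- order(df$screen, df$gene_id)
    k <- min(top_k_each_tail, nrow(df))
    union(df$gene_id[utils::tail(ord, k)], df$gene_id[utils::head(ord, k)])
  })
  common <- Reduce(intersect, per_queue_sets)
  if (!length(common)) {
    warning("no genes common to all queue tails; falling back to the union",
            call. = FALSE)
    common <- Reduce(union, per_queue_sets)
  }
  per_gene <- do.call(rbind, stats_list)
  strength <- tapply(abs(per_gene$screen), per_gene$gene_id, mean)
  common <- common[order(-strength[common], common)]
  list(candidates = utils::head(common, n_common), per_gene = per_gene)
}

#' Select the final signature by survival sensitivity
#'
#' For each candidate gene, a univariate Cox proportional-hazards model of
#' survival on that gene's expression (Efron ties); genes are ranked by the
#' score (log-rank) test p-value ascending, ties broken by gene id, and the
#' `n_select` smallest kept. A gene whose model fails to converge gets p = 1
#' and a flag. No multiple-testing correction is applied: this is selection,
#' not inference.
#'
#' @param expr genes x samples matrix.
#' @param candidates character vector of candidate gene ids.
#' @param clin clinical table with `time` and `event`.
#' @param n_select signature size (default 18, the published size).
#' @return list with `signature_genes`, `candidate_genes`, and `per_gene_stats`
#'   (gene_id, coef, surv_p, converged, selected).
#' @export
select_signature <- function(expr, candidates, clin, n_select = 18) {
  if (!length(candidates)) stop("no candidate genes supplied")
  clin <- as_clinical_table(clin)
  al <- align_samples(expr, clin)
  if (is.null(al$clin$time) || is.null(al$clin$event) ||
      all(is.na(al$clin$time)) || all(is.na(al$clin$event)))
    stop("survival selection needs time and event columns")
  candidates <- candidates[candidates %in% rownames(al$expr)]
  surv <- survival::Surv(al$clin$time, al$clin$event)
  stats_df <- do.call(rbind, lapply(candidates, function(g) {
    x <- al$expr[g, ]
    fit <- tryCatch(
      suppressWarnings(survival::coxph(surv ~ x, ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$score) || any(abs(stats::coef(fit)) > 50)) {
      data.frame(gene_id = g, coef = NA_real_, surv_p = 1, converged = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      p <- stats::pchisq(fit$score, df = 1, lower.tail = FALSE)
      data.frame(gene_id = g, coef = unname(stats::coef(fit)), surv_p = p,
                 converged = TRUE, stringsAsFactors = FALSE)
    }
  }))
  if (any(!stats_df$converged))
    clear_log("signature", sum(!stats_df$converged),
              " gene model(s) did not converge; p set to 1")
  ord <- order(stats_df$surv_p, stats_df$gene_id)
  stats_df <- stats_df[ord, , drop = FALSE]
  sel <- utils::head(stats_df$gene_id, n_select)
  stats_df$selected <- stats_df$gene_id %in% sel
  rownames(stats_df) <- NULL
  list(signature_genes = sel, candidate_genes = candidates,
       per_gene_stats = stats_df)
}

#' Full signature derivation pipeline
#'
#' Queues, candidate screen and survival selection in one call, using the
#' shared filter and config throughout.
#'
#' @inheritParams build_queues
#' @inheritParams candidate_genes
#' @inheritParams select_signature
#' @return the [select_signature()] result, with `queues` and the screen's
#'   `per_gene` table attached.
#' @export
derive_signature <- function(expr, clin, cfg = clear_config(),
                             top_k_each_tail = 100, n_common = 50,
                             n_select = 18) {
  al <- align_samples(expr, clin)
  genes <- filter_genes(al$expr, cfg$gene_filter_threshold, cfg$gene_filter_fraction)
  ex <- al$expr[genes, , drop = FALSE]
  queues <- build_queues(al$expr, al$clin, cfg)
  cand <- candidate_genes(ex, queues, top_k_each_tail, n_common)
  res <- select_signature(ex, cand$candidates, al$clin, n_select)
  res$queues <- queues
  res$per_gene <- cand$per_gene
  res
}
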