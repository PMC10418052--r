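#' Consensus call from the two primary models
#'
#' Union = a site called by either primary model; intersection = a
#' site called by both. Vectorised.
#'
#' @param rules_call,forest_call Logical vectors.
#' @param mode `"union"` or `"intersection"`.
#' @return Logical vector.
#' @export
consensus_call <- function(rules_call, forest_call,
                           mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (mode == "union") rules_call | forest_call else rules_call & forest_call
}

#' Score and call every model on a labeled site table
#'
#' Convenience wrapper producing the per-model calls used by
#' [evaluate_predictions()]: rules-based score/call on each site's
#' context, forest probability/call, and the two consensus calls.
#'
#' @param sites data.frame with `context` (25-nt flank windows) and
#'   `label` columns.
#' @param model A trained `cusee_forest`.
#' @param rules_cfg A [rules_config()].
#' @return `sites` with `rules_total`, `call_rules`, `forest_prob`,
#'   `call_forest`, `call_union`, `call_intersection` appended.
#' @export
predict_all_models <- function(sites, model, rules_cfg = rules_config()) {
  sites$rules_total <- context_rules_totals(sites$context, rules_cfg)
  sites$call_rules <- is.finite(sites$rules_total) &
    sites$rules_total >= rules_cfg$call_threshold
  sites <- predict_sites(model, sites)
  sites$call_forest <- sites$forest_call
  sites$forest_call <- NULL
  sites$call_union <- consensus_call(sites$call_rules, sites$call_forest,
                                     "union")
  sites$call_intersection <- consensus_call(sites$call_rules,
                                            sites$call_forest, "intersection")
  sites
}

#' Confusion counts, recall and precision per model
#'
#' @param preds data.frame with one or more logical `call_*` columns.
#' @param labels Binary labels (1 = editing site), one per row of
#'   `preds`; defaults to `preds$label`.
#' @return data.frame, one row per model: `tp`, `fp`, `tn`, `fn`,
#'   `recall`, `precision` (`NA` when no site is called positive).
#' @export
evaluate_predictions <- function(preds, labels = preds$label) {
  stopifnot(nrow(preds) > 0, !is.null(labels),
            length(labels) == nrow(preds))
  lab <- as.integer(labels) == 1L
  call_cols <- grep("^call_", names(preds), value = TRUE)
  if (length(call_cols) == 0L) stop("no call_* columns in preds")
  out <- lapply(call_cols, function(cc) {
    cl <- preds[[cc]]
    tp <- sum(cl & lab); fp <- sum(cl & !lab)
    fn <- sum(!cl & lab); tn <- sum(!cl & !lab)
    data.frame(model = sub("^call_", "", cc), tp = tp, fp = fp,
               tn = tn, fn = fn,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  })
  do.call(rbind, out)
}

#' ROC curve and AUROC
#'
#' Sweeps a threshold over the distinct score values (equal scores form
#' a single threshold, so tied positive/negative pairs receive half
#' credit, the Mann-Whitney convention) and integrates the curve by the
#' trapezoidal rule. Unscored sites may be encoded as `-Inf` to rank
#' below every scored site; `NA` scores are treated the same way.
#'
#' @param scores Numeric ranking statistic (higher = more likely an
#'   editing site).
#' @param labels Binary labels (1 = editing site).
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`)
#'   and `auroc`.
#' @export
roc_auroc <- function(scores, labels) {
  lab <- as.integer(labels) == 1L
  stopifnot(length(scores) == length(lab))
  if (!any(lab) || all(lab))
    stop("ROC needs at least one positive and one negative label")
  scores[is.na(scores)] <- -Inf
  np <- sum(lab); nn <- sum(!lab)
  thr <- sort(unique(scores), decreasing = TRUE)
  grp_pos <- vapply(split(lab, match(scores, thr)), sum, numeric(1))
  grp_n <- vapply(split(lab, match(scores, thr)), length, numeric(1))
  # split() orders groups by threshold index, i.e. descending score
  tp <- cumsum(grp_pos)
  fp <- cumsum(grp_n - grp_pos)
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       auroc = auroc)
}

#' Top up a testing set to the natural class imbalance
#'
#' The proportional benchmark set keeps every site of the testing set
#' (positives unchanged) and adds uniformly sampled non-editing sites
#' from a disjoint pool until the non-editing:editing ratio reaches
#' `ratio` (468:1 by default, the imbalance of the reference editing
#' dataset).
#'
#' @param testing data.frame of labeled sites (`gene`, `position`,
#'   `context`, `label`).
#' @param negative_pool data.frame of additional non-editing sites,
#'   disjoint from `testing` on (`gene`, `position`).
#' @param ratio Target negatives per positive. Default 468.
#' @param seed Integer seed for the uniform draw.
#' @return data.frame: the proportional set.
#' @export
make_proportional_set <- function(testing, negative_pool, ratio = 468,
                                  seed = 1L) {
  key <- function(d) paste(d$gene, d$position, sep = "@")
  if (any(key(negative_pool) %in% key(testing)))
    stop("negative pool overlaps the testing set")
  if (any(negative_pool$label != 0L))
    stop("negative pool must contain only non-editing sites")
  n_pos <- sum(testing$label == 1L)
  need <- round(ratio * n_pos) - sum(testing$label == 0L)
  if (need <= 0L) return(testing)
  if (need >= nrow(negative_pool)) {
    if (need > nrow(negative_pool))
      message("negative pool smaller (", nrow(negative_pool),
              ") than required top-up (", need, "); taking all")
    extra <- negative_pool
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    extra <- negative_pool[sort(sample(nrow(negative_pool), need)), ,
                           drop = FALSE]
  }
  out <- rbind(testing, extra)
  rownames(out) <- NULL
  out
}
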