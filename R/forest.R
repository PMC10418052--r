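# Labeled-site tables use a fixed context convention: a window of
# CONTEXT_FLANK nt on each side of the target cytosine (truncation is
# not allowed for forest features), so the C sits at CONTEXT_FLANK + 1.
CONTEXT_FLANK <- 25L
ENC_UP <- 15L    # nucleotides encoded upstream of the C
ENC_DOWN <- 10L  # nucleotides encoded downstream

#' Configuration for the random-forest model
#'
#' @param n_trees Trees in the forest. Default 500.
#' @param max_depth Optional depth cap (translated to a node-count cap
#'   of `2^max_depth`); `NULL` (default) leaves trees unrestricted.
#' @param seed Integer seed controlling the split, downsampling and
#'   forest growth; the full train-to-predict path is reproducible.
#' @param train_fraction Fraction of sites (per label) in the training
#'   split. Default 0.70.
#' @param downsample_ratio Non-editing sites kept per editing site in
#'   the training set. Default 3.
#' @param hard_negative_fraction Share of the kept training negatives
#'   taken from the negatives scoring highest under the rules-based
#'   model (hard negatives); the remainder are sampled uniformly.
#'   Default 0.5.
#' @param smote Placeholder switch for minority up-sampling; only
#'   `FALSE` is supported.
#' @param prob_threshold Editing call requires probability strictly
#'   greater than this. Default 0.5.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 500L, max_depth = NULL, seed = 1L,
                          train_fraction = 0.70, downsample_ratio = 3,
                          hard_negative_fraction = 0.5, smote = FALSE,
                          prob_threshold = 0.5) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            downsample_ratio >= 1,
            hard_negative_fraction >= 0, hard_negative_fraction <= 1)
  structure(list(
    n_trees = as.integer(n_trees), max_depth = max_depth,
    seed = as.integer(seed), train_fraction = train_fraction,
    downsample_ratio = downsample_ratio,
    hard_negative_fraction = hard_negative_fraction,
    smote = isTRUE(smote), prob_threshold = prob_threshold
  ), class = "forest_config")
}

#' Encode the window around a cytosine as a 50-bit feature vector
#'
#' The 15 nucleotides preceding and 10 following the target cytosine
#' are each encoded as two binary features: `isPurine` (A or G) and
#' `pairsGC` (G or C), giving A = (1,0), G = (1,1), C = (0,1),
#' U/T = (0,0). The target cytosine itself is constant and is not
#' encoded. Sites with insufficient flank raise an error; windows are
#' never zero-padded, since padding would fabricate sequence.
#'
#' @param seq Sequence (`nucseq` or character).
#' @param c_pos 1-based position of the target cytosine; at least 15 nt
#'   must precede it and 10 follow it.
#' @return Integer vector of length 50 (upstream slots first, each slot
#'   contributing `isPurine` then `pairsGC`).
#' @export
encode_window <- function(seq, c_pos) {
  v <- nuc_chars(nucseq(seq), canonical = TRUE)
  if (v[c_pos] != "C")
    stop("target position ", c_pos, " is '", v[c_pos], "', not C")
  if (c_pos - ENC_UP < 1L || c_pos + ENC_DOWN > length(v))
    stop("insufficient flank: need ", ENC_UP, " nt before and ",
         ENC_DOWN, " nt after position ", c_pos)
  w <- v[c(seq(c_pos - ENC_UP, c_pos - 1L), seq(c_pos + 1L, c_pos + ENC_DOWN))]
  bits <- rbind(isPurine = as.integer(w %in% c("A", "G")),
                pairsGC = as.integer(w %in% c("G", "C")))
  out <- as.integer(bits)
  names(out) <- paste0(rep(sprintf("s%02d", seq_len(ENC_UP + ENC_DOWN)),
                           each = 2L), c("_isPurine", "_pairsGC"))
  out
}

# Feature matrix from the `context` column of a site table.
encode_contexts <- function(contexts) {
  t(vapply(contexts, function(ctx) encode_window(ctx, CONTEXT_FLANK + 1L),
           integer(2L * (ENC_UP + ENC_DOWN)), USE.NAMES = FALSE))
}

# Rules-based score for each context (NA-free: sites with no hairpin
# get -Inf so they rank below every scored site).
context_rules_totals <- function(contexts, cfg = rules_config()) {
  vapply(contexts, function(ctx) {
    r <- score_site(ctx, CONTEXT_FLANK + 1L, cfg)
    if (is.null(r$best)) -Inf else as.numeric(r$best$total)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Stratified split and hard-negative-enriched downsampling
#'
#' Splits labeled sites into training and testing sets (stratified by
#' label, seeded), then downsamples the training negatives to
#' `downsample_ratio` per training positive. A fraction
#' `hard_negative_fraction` of the kept negatives are the ones the
#' rules-based model scores highest (hard negatives, which teach the
#' forest to reject plausible-looking hairpins); the rest are drawn
#' uniformly. The testing set is left untouched.
#'
#' @param sites data.frame with columns `gene`, `position`, `context`
#'   (window of 25 nt each side of the C) and `label` (1 = editing,
#'   0 = non-editing). A `rules_total` column is used if present and
#'   computed otherwise.
#' @param cfg A [forest_config()].
#' @param rules_cfg [rules_config()] used when `rules_total` must be
#'   computed.
#' @return list with `train` and `test` data.frames (same columns as
#'   `sites` plus `rules_total`).
#' @export
build_training_set <- function(sites, cfg = forest_config(),
                               rules_cfg = rules_config()) {
  stopifnot(all(c("gene", "position", "context", "label") %in% names(sites)))
  if (length(unique(sites$label)) < 2L)
    stop("sites must contain both editing and non-editing labels")
  if (is.null(sites$rules_total))
    sites$rules_total <- context_rules_totals(sites$context, rules_cfg)
  pos_idx <- which(sites$label == 1L)
  neg_idx <- which(sites$label == 0L)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  tr_pos <- sort(sample(pos_idx, round(cfg$train_fraction * length(pos_idx))))
  tr_neg <- sort(sample(neg_idx, round(cfg$train_fraction * length(neg_idx))))
  te <- setdiff(seq_len(nrow(sites)), c(tr_pos, tr_neg))

  target <- round(cfg$downsample_ratio * length(tr_pos))
  if (target >= length(tr_neg)) {
    if (target > length(tr_neg))
      message("fewer training negatives (", length(tr_neg),
              ") than requested (", target, "); keeping all")
    keep_neg <- tr_neg
  } else {
    n_hard <- round(cfg$hard_negative_fraction * target)
    ord <- tr_neg[order(-sites$rules_total[tr_neg], tr_neg)]
    hard <- ord[seq_len(n_hard)]
    rest <- setdiff(tr_neg, hard)
    unif <- sample(rest, target - n_hard)
    keep_neg <- sort(c(hard, unif))
  }
  list(train = sites[sort(c(tr_pos, keep_neg)), , drop = FALSE],
       test = sites[te, , drop = FALSE])
}

# Save/restore the global RNG state so seeded package functions do not
# perturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Train the random-forest editing-site classifier
#'
#' Fits a random forest on the 50-bit window encodings of the training
#' sites. Growth is seeded, so retraining with the same data and
#' configuration reproduces the model exactly.
#'
#' @param train data.frame of labeled sites (see
#'   [build_training_set()]); both labels must be present.
#' @param cfg A [forest_config()].
#' @return Object of class `cusee_forest`: the fitted forest, the
#'   configuration, and a serialization format version.
#' @export
train_forest <- function(train, cfg = forest_config()) {
  stopifnot(nrow(train) > 0)
  if (length(unique(train$label)) < 2L)
    stop("training set contains a single class; need both labels")
  if (cfg$smote)
    stop("SMOTE up-sampling is not supported; use downsampling ",
         "(downsample_ratio / hard_negative_fraction)")
  x <- encode_contexts(train$context)
  y <- factor(train$label, levels = c(0L, 1L))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  args <- list(x = x, y = y, ntree = cfg$n_trees)
  if (!is.null(cfg$max_depth)) args$maxnodes <- 2L^cfg$max_depth
  rf <- do.call(randomForest::randomForest, args)
  structure(list(rf = rf, config = cfg, format_version = "cusee-forest-1",
                 n_train_pos = sum(train$label == 1L),
                 n_train_neg = sum(train$label == 0L)),
            class = "cusee_forest")
}

#' @export
print.cusee_forest <- function(x, ...) {
  cat(sprintf("<cusee_forest %s> %d trees, trained on %d editing / %d non-editing sites\n",
              x$format_version, x$config$n_trees, x$n_train_pos, x$n_train_neg))
  invisible(x)
}

#' Save / load a trained forest
#'
#' The on-disk format carries a version tag and the training
#' configuration; loading a file with an unknown tag is an error.
#'
#' @param model A `cusee_forest`.
#' @param path File path.
#' @return `save_forest()` returns `path` invisibly; `load_forest()`
#'   returns the model.
#' @export
save_forest <- function(model, path) {
  stopifnot(inherits(model, "cusee_forest"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_forest
#' @export
load_forest <- function(path) {
  model <- readRDS(path)
  if (!identical(model$format_version, "cusee-forest-1"))
    stop("unrecognised forest file format: ",
         if (is.null(model$format_version)) "<missing tag>"
         else model$format_version)
  model
}

#' Forest probability and call for one site
#'
#' @param model A trained `cusee_forest`.
#' @param seq Sequence (`nucseq` or character).
#' @param c_pos 1-based cytosine position.
#' @return list with `prob` (editing probability, `NA` when the site
#'   cannot be encoded), `call` (`TRUE` iff `prob` strictly exceeds the
#'   configured threshold; `FALSE` for a no-call), and `reason`
#'   (`"ok"` or `"insufficient_flank"`).
#' @export
predict_site <- function(model, seq, c_pos) {
  stopifnot(inherits(model, "cusee_forest"))
  fv <- tryCatch(encode_window(seq, c_pos), error = function(e) e)
  if (inherits(fv, "error")) {
    if (grepl("insufficient flank", conditionMessage(fv)))
      return(list(prob = NA_real_, call = FALSE,
                  reason = "insufficient_flank"))
    stop(fv)
  }
  p <- predict_forest_matrix(model, matrix(fv, nrow = 1L))
  list(prob = p, call = p > model$config$prob_threshold, reason = "ok")
}

# Vectorised probability over an encoded feature matrix.
predict_forest_matrix <- function(model, x) {
  colnames(x) <- rownames(model$rf$importance)
  unname(stats::predict(model$rf, x, type = "prob")[, "1"])
}

#' Forest probabilities for a table of sites
#'
#' @param model A trained `cusee_forest`.
#' @param sites data.frame with a `context` column (25-nt flank
#'   windows).
#' @return data.frame `sites` with `forest_prob` and `forest_call`
#'   columns appended.
#' @export
predict_sites <- function(model, sites) {
  p <- predict_forest_matrix(model, encode_contexts(sites$context))
  sites$forest_prob <- p
  sites$forest_call <- p > model$config$prob_threshold
  sites
}
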