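# Leave-one-out cross-validation and ranking metrics.
#
# Each known interaction is masked in turn; topological similarity,
# degree thresholds, features and the pair space are recomputed from the
# masked network, and the held-out pair's confidence score is recorded as
# a positive. Negative scores come from a single full-data fit of all
# unapproved pairs. AUC is the Mann-Whitney statistic of positives vs
# negatives; AUPR is the stepwise area under the precision-recall curve.

#' ROC AUC of positive vs negative scores
#'
#' Mann-Whitney form: the fraction of (positive, negative) pairs where
#' the positive scores higher, ties counted 0.5.
#'
#' @param pos_scores numeric scores of the positives.
#' @param neg_scores numeric scores of the negatives.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores))
    stop("auc needs at least one positive and one negative score")
  np <- length(pos_scores)
  r <- rank(c(pos_scores, neg_scores))   # midranks handle ties as 0.5
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg_scores))
}

#' Area under the stepwise precision-recall curve
#'
#' Scores are processed in descending order in tie blocks (all scores
#' equal within a block are added atomically, which makes the result
#' independent of within-block order). At every block containing
#' positives, the precision after the block is weighted by the recall
#' increment and accumulated; no interpolation between points.
#'
#' @inheritParams auc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores))
    stop("aupr needs at least one positive and one negative score")
  np <- length(pos_scores)
  labels <- c(rep(TRUE, np), rep(FALSE, length(neg_scores)))
  scores <- c(pos_scores, neg_scores)
  blocks <- sort(unique(scores), decreasing = TRUE)
  tp <- 0; fp <- 0; area <- 0
  for (s in blocks) {
    in_block <- scores == s
    bp <- sum(labels & in_block)
    bn <- sum(!labels & in_block)
    tp <- tp + bp; fp <- fp + bn
    if (bp > 0) area <- area + (bp / np) * (tp / (tp + fp))
  }
  area
}

#' Leave-one-out cross-validation of the pair-space pipeline
#'
#' For each known interaction: mask it, recompute matching-index
#' similarities and degree thresholds on the masked network, rebuild all
#' pair features, refit the pair space, and record the held-out pair's
#' confidence score. Unapproved pairs are scored once from the full-data
#' fit. Pooled positives and negatives give AUC and AUPR.
#'
#' @param net an [interaction_network()] with at least 2 known
#'   interactions.
#' @param Sd,St primary similarity matrices aligned to the network.
#' @param combiner a [combiner_spec()] or combiner string.
#' @param k retained PCA components for scoring (default 4).
#' @param progress print fold progress every `progress` folds (0 = quiet).
#' @return List of class `eval_result`: `positive_scores`,
#'   `negative_scores`, `auc`, `aupr`, `config`.
#' @export
loocv <- function(net, Sd, St, combiner = "adaptive", k = 4L,
                  progress = 0L) {
  comb <- parse_combiner(combiner)
  known <- which(net$A == 1L, arr.ind = TRUE)
  if (nrow(known) < 2L)
    stop("LOOCV needs at least 2 known interactions")

  full_feats <- feature_matrix(net, Sd, St, comb)
  full_space <- fit_pair_space(full_feats, k)
  full_scores <- confidence_scores(full_space, full_feats)
  neg <- !full_feats$is_known
  negative_scores <- stats::setNames(
    full_scores[neg],
    paste(full_feats$drug_id[neg], full_feats$target_id[neg], sep = "|"))

  Tn <- ncol(net$A)
  positive_scores <- numeric(nrow(known))
  names(positive_scores) <- paste(net$drug_ids[known[, 1L]],
                                  net$target_ids[known[, 2L]], sep = "|")
  for (f in seq_len(nrow(known))) {
    y <- known[f, 1L]; x <- known[f, 2L]
    A2 <- net$A
    A2[y, x] <- 0L
    net2 <- interaction_network(A2, net$drug_ids, net$target_ids)
    feats2 <- feature_matrix(net2, Sd, St, comb)
    space2 <- fit_pair_space(feats2, k)
    sc2 <- confidence_scores(space2, feats2)
    positive_scores[f] <- sc2[(y - 1L) * Tn + x]
    if (progress > 0L && f %% progress == 0L)
      message("loocv fold ", f, "/", nrow(known))
  }
  structure(list(positive_scores = positive_scores,
                 negative_scores = negative_scores,
                 auc = auc(positive_scores, negative_scores),
                 aupr = aupr(positive_scores, negative_scores),
                 config = list(combiner = comb, k = as.integer(k),
                               cv = "loo")),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result (%s, combiner %s, k=%d): AUC %.4f, AUPR %.4f (%d pos / %d neg)\n",
              x$config$cv, x$config$combiner$kind, x$config$k,
              x$auc, x$aupr,
              length(x$positive_scores), length(x$negative_scores)))
  invisible(x)
}

#' Seeded k-fold cross-validation over known interactions
#'
#' Alternative to [loocv()]: known interactions are shuffled into
#' `nfolds` folds; each fold is masked jointly and its pairs are scored
#' from the masked fit. Negatives are scored from the full-data fit as in
#' LOOCV.
#'
#' @inheritParams loocv
#' @param nfolds number of folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @return An `eval_result` list.
#' @export
kfold_cv <- function(net, Sd, St, combiner = "adaptive", k = 4L,
                     nfolds = 5L, seed = 0L) {
  comb <- parse_combiner(combiner)
  known <- which(net$A == 1L, arr.ind = TRUE)
  if (nrow(known) < nfolds)
    stop("need at least as many known interactions as folds")
  full_feats <- feature_matrix(net, Sd, St, comb)
  full_space <- fit_pair_space(full_feats, k)
  full_scores <- confidence_scores(full_space, full_feats)
  neg <- !full_feats$is_known
  negative_scores <- stats::setNames(
    full_scores[neg],
    paste(full_feats$drug_id[neg], full_feats$target_id[neg], sep = "|"))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(nfolds), nrow(known)))

  Tn <- ncol(net$A)
  positive_scores <- numeric(nrow(known))
  names(positive_scores) <- paste(net$drug_ids[known[, 1L]],
                                  net$target_ids[known[, 2L]], sep = "|")
  for (f in seq_len(nfolds)) {
    held <- which(fold_of == f)
    A2 <- net$A
    A2[known[held, , drop = FALSE]] <- 0L
    net2 <- interaction_network(A2, net$drug_ids, net$target_ids)
    feats2 <- feature_matrix(net2, Sd, St, comb)
    space2 <- fit_pair_space(feats2, k)
    sc2 <- confidence_scores(space2, feats2)
    positive_scores[held] <-
      sc2[(known[held, 1L] - 1L) * Tn + known[held, 2L]]
  }
  structure(list(positive_scores = positive_scores,
                 negative_scores = negative_scores,
                 auc = auc(positive_scores, negative_scores),
                 aupr = aupr(positive_scores, negative_scores),
                 config = list(combiner = comb, k = as.integer(k),
                               cv = sprintf("%dfold", nfolds), seed = seed)),
            class = "eval_result")
}

# save/restore the global RNG state so evaluation helpers do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Compare similarity/combiner variants under LOOCV
#'
#' Runs [loocv()] for every combination of the requested combiner
#' variants and tabulates AUC and AUPR. Deterministic given its inputs.
#'
#' @inheritParams loocv
#' @param combiners character vector of combiner strings, e.g.
#'   `c("adaptive", "linear:0.5", "primary", "topo")`.
#' @return data.frame: `combiner`, `auc`, `aupr`, `n_pos`, `n_neg`.
#' @export
compare_protocol <- function(net, Sd, St, combiners = c("adaptive",
                                                        "linear:0.5"),
                             k = 4L) {
  rows <- lapply(combiners, function(cb) {
    res <- loocv(net, Sd, St, cb, k)
    data.frame(combiner = cb, auc = res$auc, aupr = res$aupr,
               n_pos = length(res$positive_scores),
               n_neg = length(res$negative_scores),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
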