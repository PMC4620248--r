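# The drug-target pair space: PCA over the 4-score feature vectors of all
# pairs. The confidence score of a pair is the Euclidean distance of its
# projection to the origin of the principal-component space (the centered
# mean of the cloud). Unapproved pairs gather near the origin; known
# interactions sit far from it, so large distances flag likely
# interactions among the unapproved pairs.

#' Fit the PCA pair space on feature vectors
#'
#' Covariance PCA (mean-centered, no variance scaling: the four scores
#' share the `[0, 1]` scale) over the filled feature vectors of all pairs,
#' known and unapproved. Component signs are fixed by making the first
#' nonzero loading of each component positive, so exported coordinates are
#' reproducible.
#'
#' @param features a `pair_features` data.frame from [feature_matrix()].
#' @param k number of retained components, 1-4 (default 4, which makes the
#'   confidence score an exact distance to the feature mean).
#' @return List of class `pair_space`: `center` (4-vector), `components`
#'   (`k` x 4, orthonormal rows), `explained_variance` (length `k`,
#'   nonincreasing), `k`.
#' @export
fit_pair_space <- function(features, k = 4L) {
  X <- as.matrix(features[, SCORE_NAMES])
  if (nrow(X) < 2L)
    stop("need at least 2 feature vectors to fit the pair space")
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > 4L)
    stop("k must be an integer in 1..4")
  k <- as.integer(k)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pc$rotation                       # 4 x m, m <= 4
  ev <- pc$sdev^2
  m <- ncol(rot)
  if (m < 4L) {                            # pad rank-deficient fits
    resid <- diag(4) - rot %*% t(rot)    # projector onto the missing space
    add <- svd(resid, nu = 4L - m, nv = 0)$u
    rot <- cbind(rot, add)
    ev <- c(ev, rep(0, 4L - m))
  }
  for (j in seq_len(ncol(rot))) {
    nz <- which(abs(rot[, j]) > 1e-12)
    if (length(nz) && rot[nz[1L], j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(center = pc$center,
                 components = t(rot)[seq_len(k), , drop = FALSE],
                 explained_variance = ev[seq_len(k)],
                 k = k),
            class = "pair_space")
}

#' @export
print.pair_space <- function(x, ...) {
  cat(sprintf("pair_space: k = %d, explained variance %s\n", x$k,
              paste(signif(x$explained_variance, 4), collapse = ", ")))
  invisible(x)
}

#' Distance-to-origin confidence scores
#'
#' Projects each feature vector into the fitted pair space and returns the
#' Euclidean norm of the projection, i.e. the distance to the PC-space
#' origin. With `k = 4` this equals the distance between the raw 4-vector
#' and the training mean.
#'
#' @param space a fitted [fit_pair_space()] object.
#' @param features a `pair_features` data.frame.
#' @return Numeric vector of nonnegative scores, one per row of
#'   `features`.
#' @export
confidence_scores <- function(space, features) {
  stopifnot(inherits(space, "pair_space"))
  X <- as.matrix(features[, SCORE_NAMES])
  proj <- sweep(X, 2L, space$center) %*% t(space$components)
  unname(sqrt(rowSums(proj^2)))
}

#' Pair-space coordinates of all pairs
#'
#' @param space a fitted [fit_pair_space()] object.
#' @param features a `pair_features` data.frame.
#' @return data.frame: `drug_id`, `target_id`, `is_known`, `motif`,
#'   `PC1..PCk`, `score`.
#' @export
pair_space_coordinates <- function(space, features) {
  X <- as.matrix(features[, SCORE_NAMES])
  proj <- sweep(X, 2L, space$center) %*% t(space$components)
  colnames(proj) <- paste0("PC", seq_len(space$k))
  cbind(features[, c("drug_id", "target_id", "is_known", "motif")],
        as.data.frame(proj),
        score = sqrt(rowSums(proj^2)))
}

#' Rank unapproved pairs as interaction candidates
#'
#' Keeps the pairs with no known interaction, sorts them by confidence
#' score descending (ties broken by drug then target identifier,
#' lexicographically) and assigns ranks 1..m.
#'
#' @param net an [interaction_network()].
#' @param features a `pair_features` data.frame for `net`'s pairs.
#' @param scores confidence scores aligned to `features` rows.
#' @param top_k optional truncation: keep only the `top_k` best.
#' @return data.frame: `rank`, `drug_id`, `target_id`, `score`.
#' @export
rank_candidates <- function(net, features, scores, top_k = NULL) {
  stopifnot(inherits(net, "interaction_network"),
            nrow(features) == length(scores))
  keep <- !features$is_known
  df <- data.frame(drug_id = features$drug_id[keep],
                   target_id = features$target_id[keep],
                   score = scores[keep],
                   stringsAsFactors = FALSE)
  ord <- order(-df$score, df$drug_id, df$target_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  if (!is.null(top_k)) df <- utils::head(df, top_k)
  if (nrow(df)) df <- cbind(rank = seq_len(nrow(df)), df)
  else df <- data.frame(rank = integer(0), drug_id = character(0),
                        target_id = character(0), score = numeric(0))
  rownames(df) <- NULL
  df
}
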