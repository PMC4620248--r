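# Topological similarity and similarity combination.
#
# The matching index (MI) between two drugs counts both the targets they
# share and the targets interacting with neither, normalized by the number
# of targets, giving a complete similarity metric on [0, 1]:
#   MI(d_i, d_j) = (T - |d_i| - |d_j| + 2 |d_i n d_j|) / T
# and symmetrically for targets with denominator D.

#' Matching-index topological similarity
#'
#' Computes the MI similarity between all drugs (or all targets) of a DTI
#' network. MI rewards both shared neighbors and jointly-absent neighbors:
#' two drugs with identical target sets have MI 1; two drugs whose disjoint
#' target sets cover all targets have MI 0.
#'
#' @param net an [interaction_network()].
#' @param side `"drugs"` or `"targets"`: which node set to compare.
#' @return A [similarity_matrix()] over the chosen node set.
#' @examples
#' net <- interaction_network(rbind(c(1, 1, 0, 0), c(0, 1, 1, 0)),
#'                            c("d1", "d2"), paste0("t", 1:4))
#' mi_similarity(net, "drugs")$S["d1", "d2"]  # (4 - 2 - 2 + 2) / 4 = 0.5
#' @export
mi_similarity <- function(net, side = c("drugs", "targets")) {
  side <- match.arg(side)
  stopifnot(inherits(net, "interaction_network"))
  A <- net$A
  if (side == "drugs") {
    n_opp <- ncol(A)
    shared <- tcrossprod(A)          # D x D counts of shared targets
    deg <- rowSums(A)
    ids <- net$drug_ids
  } else {
    n_opp <- nrow(A)
    shared <- crossprod(A)           # T x T counts of shared drugs
    deg <- colSums(A)
    ids <- net$target_ids
  }
  S <- (n_opp - outer(deg, deg, `+`) + 2 * shared) / n_opp
  diag(S) <- 1
  similarity_matrix(S, ids)
}

#' Degree thresholds for the adaptive combination rule
#'
#' The adaptive rule gates on the degree of the anchoring node relative to
#' two thresholds computed over all anchoring nodes (zero-degree nodes
#' included): `u = 0.5 * max(degrees)` and `l = mean(degrees)`.
#' `anchor_side = "targets"` uses target degrees (gating drug-drug
#' similarity); `anchor_side = "drugs"` uses drug degrees (gating
#' target-target similarity).
#'
#' @param net an [interaction_network()].
#' @param anchor_side `"targets"` or `"drugs"`.
#' @return List of class `degree_thresholds` with elements `u`, `l`,
#'   `degrees`.
#' @export
degree_thresholds <- function(net, anchor_side = c("targets", "drugs")) {
  anchor_side <- match.arg(anchor_side)
  stopifnot(inherits(net, "interaction_network"))
  degrees <- if (anchor_side == "targets") target_degrees(net)
             else drug_degrees(net)
  if (!length(degrees)) stop("no anchoring nodes on side ", anchor_side)
  structure(list(u = 0.5 * max(degrees), l = mean(degrees),
                 degrees = degrees, anchor_side = anchor_side),
            class = "degree_thresholds")
}

# Branch of the adaptive rule for a given anchor degree, by fixed
# evaluation order: (1) g >= u -> primary; (2) l < g < u -> elementwise
# max; (3) g <= l -> topological. First match wins, which resolves
# boundary overlaps such as g = u = l.
adaptive_branch <- function(anchor_degree, thr) {
  g <- anchor_degree
  if (g >= thr$u) "primary"
  else if (thr$l < g && g < thr$u) "max"
  else "topo"
}

#' Degree-adaptive similarity combination
#'
#' Selects between the primary (chemical/sequence) similarity, the
#' elementwise maximum, and the topological similarity according to the
#' degree `g` of the anchoring node: primary when `g >= u`, elementwise
#' max when `l < g < u`, topological when `g <= l` (branches evaluated in
#' that order).
#'
#' @param primary primary-view [similarity_matrix()].
#' @param topo topological [similarity_matrix()] with identical id order.
#' @param anchor_degree nonnegative degree of the anchoring node.
#' @param thr a [degree_thresholds()] object.
#' @return The branch-selected [similarity_matrix()].
#' @export
adaptive_similarity <- function(primary, topo, anchor_degree, thr) {
  stopifnot(inherits(primary, "similarity_matrix"),
            inherits(topo, "similarity_matrix"),
            inherits(thr, "degree_thresholds"))
  if (!identical(primary$ids, topo$ids))
    stop("primary and topological similarity matrices must share the same ",
         "identifier order")
  if (anchor_degree < 0) stop("anchor_degree must be nonnegative")
  switch(adaptive_branch(anchor_degree, thr),
         primary = primary,
         max = similarity_matrix(pmax(primary$S, topo$S), primary$ids),
         topo = topo)
}

#' Linearly weighted similarity combination
#'
#' Baseline combination `alpha * primary + (1 - alpha) * topo`.
#'
#' @inheritParams adaptive_similarity
#' @param alpha weight on the primary similarity, in `[0, 1]`.
#' @return A [similarity_matrix()].
#' @export
linear_combination <- function(primary, topo, alpha) {
  stopifnot(inherits(primary, "similarity_matrix"),
            inherits(topo, "similarity_matrix"))
  if (!identical(primary$ids, topo$ids))
    stop("primary and topological similarity matrices must share the same ",
         "identifier order")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single number in [0, 1]")
  similarity_matrix(alpha * primary$S + (1 - alpha) * topo$S, primary$ids)
}
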