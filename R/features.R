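# Within-score / between-score features of drug-target pairs.
#
# For a pair (d_y, t_x) the four scores are
#   C_t^w: max target similarity between t_x and the targets of d_y,
#   C_t^b: max target similarity between t_x and the non-targets of d_y,
#   C_d^w: max drug similarity between d_y and the drugs of t_x,
#   C_d^b: max drug similarity between d_y and the non-drugs of t_x.
# A score over an empty set is null; null entries are recorded in a mask
# and then filled with 1 (the bottom-line strategy). For a known pair the
# pair itself is excluded from the interacting sets, so its motif dictates
# the null pattern: drug-centered pairs lose C_d^w, target-centered pairs
# lose C_t^w, single pairs lose both within-scores.

MOTIF_LEVELS <- c("multiple", "drug_centered", "target_centered", "single")
SCORE_NAMES <- c("ctw", "ctb", "cdw", "cdb")

#' Combiner specification
#'
#' Describes how the primary (chemical/sequence) and topological
#' similarities are merged when computing pair features: the degree
#' adaptive rule, a linearly weighted baseline, or one view alone.
#'
#' @param kind one of `"adaptive"`, `"linear"`, `"primary"`, `"topo"`.
#' @param alpha weight on the primary similarity for `kind = "linear"`.
#' @return List of class `combiner_spec`.
#' @export
combiner_spec <- function(kind = c("adaptive", "linear", "primary", "topo"),
                          alpha = NULL) {
  kind <- match.arg(kind)
  if (kind == "linear") {
    if (is.null(alpha) || !is.numeric(alpha) || length(alpha) != 1L ||
        is.na(alpha) || alpha < 0 || alpha > 1)
      stop("linear combiner requires alpha in [0, 1]")
  } else alpha <- NULL
  structure(list(kind = kind, alpha = alpha), class = "combiner_spec")
}

#' Parse a combiner string such as "adaptive" or "linear:0.5"
#'
#' @param text combiner specification string: `"adaptive"`, `"primary"`,
#'   `"topo"`, or `"linear:<alpha>"`.
#' @return A [combiner_spec()].
#' @export
parse_combiner <- function(text) {
  if (inherits(text, "combiner_spec")) return(text)
  parts <- strsplit(text, ":", fixed = TRUE)[[1L]]
  if (parts[1L] == "linear") {
    if (length(parts) != 2L)
      stop("linear combiner must be written linear:<alpha>")
    alpha <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(alpha)) stop("cannot parse alpha in combiner \"", text, "\"")
    combiner_spec("linear", alpha)
  } else if (length(parts) == 1L &&
             parts %in% c("adaptive", "primary", "topo")) {
    combiner_spec(parts)
  } else stop("unknown combiner \"", text, "\"")
}

#' Classify the local motif of a known interaction
#'
#' Every known interaction belongs to one of four topological motifs
#' determined by the degrees of its two endpoints (counted including the
#' pair itself): `multiple` (both degrees > 1), `drug_centered` (target
#' degree 1, drug degree > 1), `target_centered` (drug degree 1, target
#' degree > 1), `single` (both degrees 1).
#'
#' @param net an [interaction_network()].
#' @param drug_index row index of the drug.
#' @param target_index column index of the target.
#' @return One of `"multiple"`, `"drug_centered"`, `"target_centered"`,
#'   `"single"`.
#' @export
classify_motif <- function(net, drug_index, target_index) {
  stopifnot(inherits(net, "interaction_network"))
  if (net$A[drug_index, target_index] != 1L)
    stop("motifs are defined for known interactions only; pair (",
         net$drug_ids[drug_index], ", ", net$target_ids[target_index],
         ") is unapproved")
  deg_d <- sum(net$A[drug_index, ])
  deg_t <- sum(net$A[, target_index])
  if (deg_d > 1L && deg_t > 1L) "multiple"
  else if (deg_t == 1L && deg_d > 1L) "drug_centered"
  else if (deg_d == 1L && deg_t > 1L) "target_centered"
  else "single"
}

# max over a column subset per row; empty subset (or excluded-only) -> -Inf
rowmax_cols <- function(M, cols) {
  if (!length(cols)) return(rep(-Inf, nrow(M)))
  out <- M[, cols[1L]]
  for (j in cols[-1L]) out <- pmax(out, M[, j])
  out
}

#' Within- and between-score of a queried target against a drug
#'
#' `C_t^w` is the maximum similarity between target `x` and the targets
#' interacting with drug `i`; `C_t^b` the maximum against the targets not
#' interacting with drug `i`. With `exclude_pair = TRUE` the queried
#' target is removed from the interacting set (used when scoring a known
#' pair against the rest of the network); the queried target is never
#' compared with itself in the complement. Empty sets yield `NA` (null).
#'
#' @param net an [interaction_network()].
#' @param St target-target [similarity_matrix()] aligned to
#'   `net$target_ids`.
#' @param target_index queried target `x`.
#' @param drug_index anchoring drug `i`.
#' @param exclude_pair remove `x` from the interacting set first?
#' @return Named numeric vector `c(ctw =, ctb =)`; `NA` marks null.
#' @export
target_view_scores <- function(net, St, target_index, drug_index,
                               exclude_pair = FALSE) {
  stopifnot(inherits(net, "interaction_network"),
            inherits(St, "similarity_matrix"))
  x <- target_index
  inter <- which(net$A[drug_index, ] == 1L)
  if (exclude_pair) inter <- setdiff(inter, x)
  comp <- setdiff(seq_len(ncol(net$A)), union(which(net$A[drug_index, ] == 1L), x))
  ctw <- if (length(inter)) max(St$S[x, inter]) else NA_real_
  ctb <- if (length(comp)) max(St$S[x, comp]) else NA_real_
  c(ctw = ctw, ctb = ctb)
}

#' Within- and between-score of a queried drug against a target
#'
#' Mirror of [target_view_scores()] with drugs and targets swapped:
#' `C_d^w` is the maximum similarity between drug `y` and the drugs
#' interacting with target `j`; `C_d^b` the maximum against the drugs not
#' interacting with target `j`.
#'
#' @param net an [interaction_network()].
#' @param Sd drug-drug [similarity_matrix()] aligned to `net$drug_ids`.
#' @param drug_index queried drug `y`.
#' @param target_index anchoring target `j`.
#' @param exclude_pair remove `y` from the interacting set first?
#' @return Named numeric vector `c(cdw =, cdb =)`; `NA` marks null.
#' @export
drug_view_scores <- function(net, Sd, drug_index, target_index,
                             exclude_pair = FALSE) {
  stopifnot(inherits(net, "interaction_network"),
            inherits(Sd, "similarity_matrix"))
  y <- drug_index
  inter <- which(net$A[, target_index] == 1L)
  if (exclude_pair) inter <- setdiff(inter, y)
  comp <- setdiff(seq_len(nrow(net$A)), union(which(net$A[, target_index] == 1L), y))
  cdw <- if (length(inter)) max(Sd$S[y, inter]) else NA_real_
  cdb <- if (length(comp)) max(Sd$S[y, comp]) else NA_real_
  c(cdw = cdw, cdb = cdb)
}

# Effective similarity matrices under a combiner.
#
# Returns St_for_drug: list over drugs y of the target-target matrix used
# when scoring pairs anchored on d_y (adaptive rule gated by deg(d_y)
# against drug-degree thresholds), and Sd_for_target: list over targets x
# of the drug-drug matrix gated by deg(t_x) against target-degree
# thresholds. Under non-adaptive combiners the matrix is anchor
# independent. Matrices are plain numeric with the diagonal set to -Inf
# so that a node is never compared with itself.
effective_similarities <- function(net, Sd, St, comb) {
  noself <- function(sim) { M <- sim$S; diag(M) <- -Inf; M }
  topo_needed <- comb$kind != "primary"
  Sd_topo <- if (topo_needed) mi_similarity(net, "drugs") else NULL
  St_topo <- if (topo_needed) mi_similarity(net, "targets") else NULL
  if (comb$kind == "adaptive") {
    thr_t <- degree_thresholds(net, "targets")   # gates drug-drug sim
    thr_d <- degree_thresholds(net, "drugs")     # gates target-target sim
    sd_var <- list(primary = noself(Sd),
                   max = pmax(noself(Sd), noself(Sd_topo)),
                   topo = noself(Sd_topo))
    st_var <- list(primary = noself(St),
                   max = pmax(noself(St), noself(St_topo)),
                   topo = noself(St_topo))
    b_target <- vapply(target_degrees(net), adaptive_branch, "", thr = thr_t)
    b_drug <- vapply(drug_degrees(net), adaptive_branch, "", thr = thr_d)
    list(Sd_for_target = lapply(b_target, function(b) sd_var[[b]]),
         St_for_drug = lapply(b_drug, function(b) st_var[[b]]))
  } else {
    one <- switch(comb$kind,
      primary = list(Sd = noself(Sd), St = noself(St)),
      topo = list(Sd = noself(Sd_topo), St = noself(St_topo)),
      linear = list(
        Sd = noself(linear_combination(Sd, Sd_topo, comb$alpha)),
        St = noself(linear_combination(St, St_topo, comb$alpha))))
    list(Sd_for_target = rep(list(one$Sd), ncol(net$A)),
         St_for_drug = rep(list(one$St), nrow(net$A)))
  }
}

#' Feature table for all drug-target pairs
#'
#' Computes the four-score feature vector of every pair of the network
#' (row-major: all targets of the first drug, then the second, ...).
#' Known pairs are scored with the pair itself excluded from the
#' interacting sets and carry their motif label; unapproved pairs have
#' `motif = NA`. Null scores are filled with 1 and flagged in the
#' `null_*` columns.
#'
#' @param net an [interaction_network()].
#' @param Sd,St primary drug-drug / target-target similarities aligned to
#'   the network (see [align_inputs()]).
#' @param combiner a [combiner_spec()] or string accepted by
#'   [parse_combiner()].
#' @return data.frame of class `pair_features` with one row per pair:
#'   `drug_id`, `target_id`, `is_known`, `motif`, `ctw`, `ctb`, `cdw`,
#'   `cdb`, `null_ctw`, `null_ctb`, `null_cdw`, `null_cdb`.
#' @export
feature_matrix <- function(net, Sd, St, combiner = "adaptive") {
  comb <- parse_combiner(combiner)
  stopifnot(inherits(net, "interaction_network"),
            inherits(Sd, "similarity_matrix"),
            inherits(St, "similarity_matrix"))
  if (!identical(Sd$ids, net$drug_ids) || !identical(St$ids, net$target_ids))
    stop("similarity matrices are not aligned to the network; ",
         "call align_inputs() first")
  A <- net$A
  D <- nrow(A); Tn <- ncol(A)
  eff <- effective_similarities(net, Sd, St, comb)

  ctw <- ctb <- cdw <- cdb <- matrix(NA_real_, D, Tn)
  for (y in seq_len(D)) {
    M <- eff$St_for_drug[[y]]            # T x T, diag -Inf
    P <- which(A[y, ] == 1L)
    Q <- which(A[y, ] == 0L)
    ctw[y, ] <- rowmax_cols(M, P)
    ctb[y, ] <- rowmax_cols(M, Q)
  }
  for (x in seq_len(Tn)) {
    N <- eff$Sd_for_target[[x]]          # D x D, diag -Inf
    U <- which(A[, x] == 1L)
    V <- which(A[, x] == 0L)
    cdw[, x] <- rowmax_cols(N, U)
    cdb[, x] <- rowmax_cols(N, V)
  }

  deg_d <- drug_degrees(net); deg_t <- target_degrees(net)
  known <- A == 1L
  motif <- matrix(NA_character_, D, Tn)
  dd <- matrix(deg_d, D, Tn)
  tt <- matrix(deg_t, D, Tn, byrow = TRUE)
  motif[known & dd > 1L & tt > 1L] <- "multiple"
  motif[known & dd > 1L & tt == 1L] <- "drug_centered"
  motif[known & dd == 1L & tt > 1L] <- "target_centered"
  motif[known & dd == 1L & tt == 1L] <- "single"

  fill <- function(M) { null <- !is.finite(M); M[null] <- 1; list(M, null) }
  f_ctw <- fill(ctw); f_ctb <- fill(ctb)
  f_cdw <- fill(cdw); f_cdb <- fill(cdb)

  # row-major over drugs then targets: transpose before flattening
  flat <- function(M) as.vector(t(M))
  out <- data.frame(
    drug_id = rep(net$drug_ids, each = Tn),
    target_id = rep(net$target_ids, times = D),
    is_known = flat(known),
    motif = flat(motif),
    ctw = flat(f_ctw[[1]]), ctb = flat(f_ctb[[1]]),
    cdw = flat(f_cdw[[1]]), cdb = flat(f_cdb[[1]]),
    null_ctw = flat(f_ctw[[2]]), null_ctb = flat(f_ctb[[2]]),
    null_cdw = flat(f_cdw[[2]]), null_cdb = flat(f_cdb[[2]]),
    stringsAsFactors = FALSE)
  class(out) <- c("pair_features", "data.frame")
  out
}

#' Feature of a single drug-target pair
#'
#' Convenience accessor computing one pair's [feature_matrix()] row. The
#' pair is excluded from the interacting sets when it is a known
#' interaction, so its null pattern reflects its motif.
#'
#' @inheritParams feature_matrix
#' @param drug_index,target_index indices of the pair.
#' @return One-row `pair_features` data.frame.
#' @export
pair_feature <- function(net, Sd, St, combiner, drug_index, target_index) {
  feats <- feature_matrix(net, Sd, St, combiner)
  feats[(drug_index - 1L) * ncol(net$A) + target_index, , drop = FALSE]
}

#' Per-motif histograms of one feature score
#'
#' Bins one of the four scores into 38 fixed-width bins of 0.02 starting
#' at 0.35 (values below 0.35 fall in the first bin, values at or above
#' 1.09 in the last), separately for each known-pair motif and for the
#' unapproved pairs, and normalizes each non-empty group to unit mass.
#'
#' @param features a `pair_features` data.frame from [feature_matrix()].
#' @param score one of `"ctw"`, `"ctb"`, `"cdw"`, `"cdb"` (or index 1-4).
#' @return data.frame with columns `group`, `bin_left`, `bin_right`,
#'   `height`; attribute `empty_groups` lists groups with no members.
#' @export
score_histograms <- function(features, score) {
  if (is.numeric(score)) score <- SCORE_NAMES[score]
  score <- match.arg(score, SCORE_NAMES)
  n_bins <- 38L
  left <- 0.35 + 0.02 * (seq_len(n_bins) - 1L)
  groups <- c(MOTIF_LEVELS, "unapproved")
  grp <- ifelse(features$is_known, features$motif, "unapproved")
  out <- list(); empty <- character(0)
  for (g in groups) {
    v <- features[[score]][grp == g]
    h <- numeric(n_bins)
    if (length(v)) {
      idx <- pmin(pmax(floor((v - 0.35) / 0.02), 0), n_bins - 1L) + 1L
      tab <- tabulate(idx, nbins = n_bins)
      h <- tab / sum(tab)
    } else empty <- c(empty, g)
    out[[g]] <- data.frame(group = g, bin_left = left,
                           bin_right = left + 0.02, height = h,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "empty_groups") <- empty
  res
}
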