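# Independent brute-force oracles and small random fixtures. These
# deliberately re-derive every quantity from first principles (explicit
# set enumeration, pair counting) so they share no code with the package
# implementations they check.

rand_net <- function(D, T_, p = 0.4) {
  A <- matrix(as.integer(stats::runif(D * T_) < p), D, T_)
  interaction_network(A, sprintf("d%d", seq_len(D)),
                      sprintf("t%d", seq_len(T_)))
}

rand_sim <- function(n, ids) {
  S <- matrix(stats::runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  similarity_matrix(S, ids)
}

# matching index by explicit neighbor-set counting
oracle_mi_drugs <- function(net, i, j) {
  Ti <- which(net$A[i, ] == 1L)
  Tj <- which(net$A[j, ] == 1L)
  T_ <- ncol(net$A)
  (T_ - length(Ti) - length(Tj) + 2 * length(intersect(Ti, Tj))) / T_
}

oracle_mi_targets <- function(net, p, q) {
  Dp <- which(net$A[, p] == 1L)
  Dq <- which(net$A[, q] == 1L)
  D_ <- nrow(net$A)
  (D_ - length(Dp) - length(Dq) + 2 * length(intersect(Dp, Dq))) / D_
}

# within/between scores by explicit set enumeration (NA = null)
oracle_target_view <- function(net, St, x, i, exclude_pair) {
  inter <- which(net$A[i, ] == 1L)
  if (exclude_pair) inter <- setdiff(inter, x)
  # the queried target is excluded from the complement even when known
  comp <- setdiff(seq_len(ncol(net$A)), c(which(net$A[i, ] == 1L), x))
  c(if (length(inter)) max(St$S[x, inter]) else NA_real_,
    if (length(comp)) max(St$S[x, comp]) else NA_real_)
}

oracle_drug_view <- function(net, Sd, y, j, exclude_pair) {
  inter <- which(net$A[, j] == 1L)
  if (exclude_pair) inter <- setdiff(inter, y)
  comp <- setdiff(seq_len(nrow(net$A)), c(which(net$A[, j] == 1L), y))
  c(if (length(inter)) max(Sd$S[y, inter]) else NA_real_,
    if (length(comp)) max(Sd$S[y, comp]) else NA_real_)
}

# AUC by exhaustive pair counting
oracle_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# AUPR by walking the sorted unique thresholds and accumulating
# precision at every recall increment (tie blocks atomic)
oracle_aupr <- function(pos, neg) {
  np <- length(pos)
  area <- 0
  prev_tp <- 0
  for (thr in sort(unique(c(pos, neg)), decreasing = TRUE)) {
    tp <- sum(pos >= thr)
    fp <- sum(neg >= thr)
    if (tp > prev_tp) {
      area <- area + ((tp - prev_tp) / np) * (tp / (tp + fp))
      prev_tp <- tp
    }
  }
  area
}

write_tsv_lines <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}
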