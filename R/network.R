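#' Construct a drug-target interaction network
#'
#' A bipartite network of `D` drugs and `T` targets stored as a binary
#' adjacency matrix `A` (drugs as rows). `A[i, j] == 1` means drug `i` is
#' known to interact with target `j`; `0` means the pair is unapproved.
#'
#' @param A numeric matrix with entries in \{0, 1\}; drugs as rows.
#' @param drug_ids character vector of unique drug identifiers, one per row.
#' @param target_ids character vector of unique target identifiers, one per
#'   column.
#' @return An object of class `interaction_network` with elements `A`
#'   (integer matrix with dimnames), `drug_ids`, `target_ids`.
#' @examples
#' net <- interaction_network(matrix(c(1, 0, 1, 1), 2, 2),
#'                            c("d1", "d2"), c("t1", "t2"))
#' drug_degrees(net)
#' @export
interaction_network <- function(A, drug_ids, target_ids) {
  A <- as.matrix(A)
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)
  if (nrow(A) < 1L || ncol(A) < 1L)
    stop("interaction matrix must have at least one drug and one target")
  if (length(drug_ids) != nrow(A))
    stop("length of drug_ids (", length(drug_ids),
         ") does not match number of rows (", nrow(A), ")")
  if (length(target_ids) != ncol(A))
    stop("length of target_ids (", length(target_ids),
         ") does not match number of columns (", ncol(A), ")")
  if (anyDuplicated(drug_ids))
    stop("duplicate drug identifiers: ",
         paste(unique(drug_ids[duplicated(drug_ids)]), collapse = ", "))
  if (anyDuplicated(target_ids))
    stop("duplicate target identifiers: ",
         paste(unique(target_ids[duplicated(target_ids)]), collapse = ", "))
  if (!all(A %in% c(0, 1)))
    stop("interaction matrix entries must all be 0 or 1")
  storage.mode(A) <- "integer"
  dimnames(A) <- list(drug_ids, target_ids)
  structure(list(A = A, drug_ids = drug_ids, target_ids = target_ids),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d drugs x %d targets, %d known interactions\n",
              nrow(x$A), ncol(x$A), sum(x$A)))
  invisible(x)
}

#' Node degrees of an interaction network
#'
#' Drug degree is the number of targets a drug interacts with (row sum);
#' target degree is the number of drugs interacting with a target
#' (column sum).
#'
#' @param net an `interaction_network`.
#' @return Integer vector of degrees named by identifier.
#' @export
drug_degrees <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  d <- rowSums(net$A)
  stats::setNames(as.integer(d), net$drug_ids)
}

#' @rdname drug_degrees
#' @export
target_degrees <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  d <- colSums(net$A)
  stats::setNames(as.integer(d), net$target_ids)
}

#' Construct a similarity matrix over one node set
#'
#' Square symmetric matrix of pairwise similarities in `[0, 1]` with unit
#' diagonal, e.g. chemical-structure similarity between drugs or normalized
#' sequence similarity between targets.
#'
#' Symmetry and diagonal are checked to 1e-9; mild asymmetry (at most 1e-6,
#' e.g. from file rounding) is repaired by averaging `S` and `t(S)`.
#'
#' @param S square numeric matrix.
#' @param ids character vector of unique node identifiers.
#' @return An object of class `similarity_matrix` with elements `S`
#'   (matrix with dimnames) and `ids`.
#' @export
similarity_matrix <- function(S, ids) {
  S <- as.matrix(S)
  ids <- as.character(ids)
  if (nrow(S) != ncol(S))
    stop("similarity matrix must be square, got ", nrow(S), " x ", ncol(S))
  if (length(ids) != nrow(S))
    stop("length of ids does not match matrix dimension")
  if (anyDuplicated(ids))
    stop("duplicate identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!is.finite(S)))
    stop("similarity matrix contains non-finite entries")
  if (any(S < -1e-9 | S > 1 + 1e-9))
    stop("similarity entries must lie in [0, 1]; offending range [",
         min(S), ", ", max(S), "]")
  asym <- max(abs(S - t(S)))
  if (asym > 1e-6)
    stop("similarity matrix is asymmetric (max |S - t(S)| = ",
         format(asym), " > 1e-6)")
  if (asym > 0) S <- (S + t(S)) / 2
  if (max(abs(diag(S) - 1)) > 1e-9)
    stop("similarity matrix diagonal must equal 1")
  diag(S) <- 1
  S[S < 0] <- 0
  S[S > 1] <- 1
  dimnames(S) <- list(ids, ids)
  structure(list(S = S, ids = ids), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$S[upper.tri(x$S)]
  if (length(off)) {
    cat(sprintf("similarity_matrix: %d x %d, off-diagonal range [%.3f, %.3f]\n",
                nrow(x$S), ncol(x$S), min(off), max(off)))
  } else {
    cat(sprintf("similarity_matrix: %d x %d\n", nrow(x$S), ncol(x$S)))
  }
  invisible(x)
}
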