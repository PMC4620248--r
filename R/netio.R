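# TSV I/O for interaction networks, similarity matrices and predictions.
# All files are tab-separated UTF-8 with '.' decimal separator, no quoting;
# matrix files carry a header row of identifiers and a first column of
# identifiers (header cell [1,1] is ignored on read, written as "id").

read_tsv_cells <- function(path) {
  if (!file.exists(path)) stop("cannot open file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("file is empty: ", path)
  strsplit(lines, "\t", fixed = TRUE)
}

check_rectangular <- function(cells, path) {
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in ", path, ": line widths ",
         paste(unique(widths), collapse = ", "))
}

#' Read a binary interaction matrix from TSV
#'
#' The file has a header row of identifiers and a first column of
#' identifiers; every other cell must be 0 or 1. Benchmark DTI files often
#' store targets as rows; set `orientation = "targets_as_rows"` and the
#' matrix is transposed so the returned network always has drugs as rows.
#'
#' @param path path to a TSV adjacency file.
#' @param orientation `"drugs_as_rows"` (default) or `"targets_as_rows"`.
#' @return An [interaction_network()].
#' @export
read_interaction_matrix <- function(path,
                                    orientation = c("drugs_as_rows",
                                                    "targets_as_rows")) {
  orientation <- match.arg(orientation)
  cells <- read_tsv_cells(path)
  check_rectangular(cells, path)
  if (length(cells) < 2L || length(cells[[1L]]) < 2L)
    stop("interaction matrix file needs a header row and an id column: ", path)
  col_ids <- cells[[1L]][-1L]
  row_ids <- vapply(cells[-1L], `[[`, character(1), 1L)
  vals <- lapply(cells[-1L], function(r) r[-1L])
  M <- matrix(NA_integer_, length(row_ids), length(col_ids))
  for (i in seq_along(vals)) {
    for (j in seq_along(col_ids)) {
      v <- vals[[i]][j]
      if (!v %in% c("0", "1"))
        stop("non-binary cell \"", v, "\" at row ", row_ids[i],
             ", column ", col_ids[j], " in ", path)
      M[i, j] <- as.integer(v)
    }
  }
  if (orientation == "targets_as_rows") {
    interaction_network(t(M), drug_ids = col_ids, target_ids = row_ids)
  } else {
    interaction_network(M, drug_ids = row_ids, target_ids = col_ids)
  }
}

#' Read an interaction pair list from TSV
#'
#' Two-column file (`drug_id`, `target_id`), one known interaction per
#' line; duplicated lines collapse to a single interaction. Unless
#' universes are supplied, the drug/target identifier sets default to the
#' distinct identifiers in the file, sorted lexicographically for
#' deterministic downstream ordering.
#'
#' @param path path to a two-column TSV file (no header).
#' @param drug_universe optional character vector of all drug ids.
#' @param target_universe optional character vector of all target ids.
#' @return An [interaction_network()].
#' @export
read_pair_list <- function(path, drug_universe = NULL,
                           target_universe = NULL) {
  cells <- read_tsv_cells(path)
  bad <- which(lengths(cells) != 2L)
  if (length(bad))
    stop("pair list lines must have exactly two columns; line ", bad[1L],
         " of ", path, " has ", lengths(cells)[bad[1L]])
  drugs <- vapply(cells, `[[`, character(1), 1L)
  targets <- vapply(cells, `[[`, character(1), 2L)
  if (is.null(drug_universe)) {
    drug_universe <- sort(unique(drugs))
  } else if (!all(drugs %in% drug_universe)) {
    stop("pair list references drugs outside the supplied universe: ",
         paste(unique(setdiff(drugs, drug_universe)), collapse = ", "))
  }
  if (is.null(target_universe)) {
    target_universe <- sort(unique(targets))
  } else if (!all(targets %in% target_universe)) {
    stop("pair list references targets outside the supplied universe: ",
         paste(unique(setdiff(targets, target_universe)), collapse = ", "))
  }
  A <- matrix(0L, length(drug_universe), length(target_universe))
  A[cbind(match(drugs, drug_universe), match(targets, target_universe))] <- 1L
  interaction_network(A, drug_universe, target_universe)
}

#' Read a similarity matrix from TSV
#'
#' Square file whose header row and first column carry identical
#' identifiers. Entries must lie in `[0, 1]` with unit diagonal; asymmetry
#' up to 1e-6 is repaired by averaging, larger asymmetry is an error.
#'
#' @param path path to a square TSV similarity file.
#' @return A [similarity_matrix()].
#' @export
read_similarity <- function(path) {
  cells <- read_tsv_cells(path)
  check_rectangular(cells, path)
  if (length(cells) < 2L)
    stop("similarity file needs a header row and at least one data row: ",
         path)
  col_ids <- cells[[1L]][-1L]
  row_ids <- vapply(cells[-1L], `[[`, character(1), 1L)
  if (length(row_ids) != length(col_ids) || !all(row_ids == col_ids))
    stop("similarity file must be square with identical row and column ",
         "identifiers: ", path)
  n <- length(row_ids)
  S <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(cells[[i + 1L]][-1L]))
    if (anyNA(v))
      stop("non-numeric similarity cell in row ", row_ids[i], " of ", path)
    S[i, ] <- v
  }
  similarity_matrix(S, row_ids)
}

#' Write a network or similarity matrix to TSV
#'
#' @param x an `interaction_network` or `similarity_matrix`.
#' @param path output file path.
#' @param digits significant digits for similarity values.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, digits = 10) {
  if (inherits(x, "interaction_network")) {
    M <- x$A
    fmt <- function(v) as.character(v)
  } else if (inherits(x, "similarity_matrix")) {
    M <- x$S
    fmt <- function(v) formatC(v, digits = digits, format = "g")
  } else stop("unsupported object of class ", paste(class(x), collapse = "/"))
  lines <- c(paste(c("id", colnames(M)), collapse = "\t"),
             vapply(seq_len(nrow(M)), function(i)
               paste(c(rownames(M)[i], fmt(M[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Align similarity matrices to a network's identifier order
#'
#' Reorders the drug similarity matrix to `net$drug_ids` and the target
#' similarity matrix to `net$target_ids`. Every network identifier must be
#' present in the corresponding similarity matrix; similarity identifiers
#' absent from the network are dropped with a warning.
#'
#' @param net an `interaction_network`.
#' @param Sd drug-drug `similarity_matrix`.
#' @param St target-target `similarity_matrix`.
#' @return List with elements `net`, `Sd`, `St`, aligned.
#' @export
align_inputs <- function(net, Sd, St) {
  stopifnot(inherits(net, "interaction_network"),
            inherits(Sd, "similarity_matrix"),
            inherits(St, "similarity_matrix"))
  align_one <- function(sim, ids, what) {
    missing <- setdiff(ids, sim$ids)
    if (length(missing))
      stop("network ", what, " identifiers missing from similarity matrix: ",
           paste(missing, collapse = ", "))
    extra <- setdiff(sim$ids, ids)
    if (length(extra))
      warning(length(extra), " ", what,
              " similarity identifiers absent from the network were ",
              "dropped: ", paste(extra, collapse = ", "))
    idx <- match(ids, sim$ids)
    similarity_matrix(sim$S[idx, idx, drop = FALSE], ids)
  }
  list(net = net,
       Sd = align_one(Sd, net$drug_ids, "drug"),
       St = align_one(St, net$target_ids, "target"))
}

#' Write ranked interaction predictions to TSV
#'
#' @param ranked data.frame with columns `rank`, `drug_id`, `target_id`,
#'   `score` (as produced by [rank_candidates()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(ranked, path) {
  req <- c("rank", "drug_id", "target_id", "score")
  if (!all(req %in% names(ranked)))
    stop("ranked predictions need columns: ", paste(req, collapse = ", "))
  if (nrow(ranked) && any(!is.finite(ranked$score)))
    stop("prediction scores must be finite")
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  lines <- c("rank\tdrug_id\ttarget_id\tscore",
             if (nrow(ranked))
               sprintf("%d\t%s\t%s\t%.6f", as.integer(ranked$rank),
                       ranked$drug_id, ranked$target_id, ranked$score))
  writeLines(lines, path)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path path to a prediction TSV.
#' @return data.frame with columns `rank`, `drug_id`, `target_id`, `score`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("integer", "character",
                                         "character", "numeric"))
  names(df) <- c("rank", "drug_id", "target_id", "score")
  df
}
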