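#' Pairwise normalized edit-distance matrix
#'
#' Builds the symmetric n x n matrix `M` with
#' `M[i, j] = normalized_edit_distance(records[i], records[j])`. Only the
#' upper triangle is computed and mirrored, so the result is exactly
#' symmetric with a zero diagonal; under default weights all entries lie
#' in \[0, 1\]. The computation is a serial upper-triangle sweep and is
#' bit-identical across runs.
#'
#' @param records a [seq_records()] set (or a named character vector of
#'   ACGT strings) with at least two records and unique ids.
#' @param weights an [edit_weights()] quadruple.
#' @param normalize divide each distance by the longer length (default
#'   `TRUE`); `FALSE` yields raw weighted edit distances.
#' @return a symmetric numeric matrix of class `"ned_distmat"` with record
#'   ids as dimnames and the weights stored in the `"weights"` attribute.
#' @examples
#' recs <- seq_records(c(a = "ATCAGTA", b = "TCGACTA"))
#' distance_matrix(recs)
#' @export
distance_matrix <- function(records, weights = edit_weights(),
                            normalize = TRUE) {
  if (!inherits(records, "seq_records"))
    records <- seq_records(as.character(records),
                           ids = names(records) %||% as.character(seq_along(records)))
  if (length(records) < 2L)
    stop_nedmap("need at least two records to build a distance matrix")
  weights <- check_weights(weights)
  M <- ed_distmat_cpp(unclass(records),
                      weights[["w_ins"]], weights[["w_del"]],
                      weights[["w_sub"]], weights[["w_mat"]],
                      normalize = check_flag(normalize, "normalize"),
                      restrict_match = restrict_match_policy(records))
  dimnames(M) <- list(names(records), names(records))
  structure(M, weights = weights, normalized = normalize,
            class = c("ned_distmat", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ned_distmat <- function(x, ...) {
  cat(sprintf("ned_distmat: %d x %d %s edit distances\n", nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) "normalized" else "raw"))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], ...)
  if (nrow(x) > 6L) cat(sprintf("  ... %d rows/columns omitted\n", nrow(x) - 6L))
  invisible(x)
}

# shared validation for functions consuming a distance matrix
check_distmat <- function(M, name = "M") {
  M <- as.matrix(M)
  if (!is.numeric(M) || nrow(M) != ncol(M))
    stop_nedmap(sprintf("`%s` must be a square numeric matrix", name))
  if (anyNA(M)) stop_nedmap(sprintf("`%s` contains NA", name))
  if (max(abs(M - t(M))) > 1e-9)
    stop_nedmap(sprintf("`%s` must be symmetric", name))
  if (any(diag(M) != 0))
    stop_nedmap(sprintf("`%s` must have a zero diagonal", name))
  M
}

#' Write a distance matrix as TSV
#'
#' Tab-separated square matrix: the first row holds ids, each following
#' row starts with its id; values are written with full float precision so
#' that write/read/write round-trips are byte-identical. With
#' `labeled_square = TRUE` a PHYLIP-like square format is written instead
#' (count line, then id-prefixed rows without a header row).
#'
#' @param M a `ned_distmat` (or any labelled symmetric matrix).
#' @param path output file path.
#' @param labeled_square write PHYLIP-like square layout for interop.
#' @return `path`, invisibly.
#' @export
write_distmat <- function(M, path, labeled_square = FALSE) {
  M <- as.matrix(M)
  ids <- rownames(M) %||% as.character(seq_len(nrow(M)))
  body <- apply(M, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  lines <- if (check_flag(labeled_square, "labeled_square")) {
    c(sprintf("%d", nrow(M)), paste(ids, body, sep = "\t"))
  } else {
    c(paste(c("id", ids), collapse = "\t"), paste(ids, body, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a distance matrix written by [write_distmat()]
#'
#' @param path TSV file with an `id` header row and id-prefixed rows.
#' @return a `"ned_distmat"` matrix with ids as dimnames.
#' @export
read_distmat <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, row.names = 1L,
                           check.names = FALSE, colClasses = "character")
  M <- apply(as.matrix(tab), c(1L, 2L), as.numeric)
  if (!identical(rownames(M), colnames(M)))
    stop_nedmap("row and column ids disagree in ", path)
  M <- check_distmat(M, "matrix read from file")
  structure(M, normalized = all(M >= 0 & M <= 1),
            class = c("ned_distmat", "matrix", "array"))
}
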