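# Embedding container shared by the Isomap and Laplacian Eigenmaps routes.

new_embedding <- function(coords, ids, method, eigenvalues, params,
                          dropped_ids = character(0)) {
  dimnames(coords) <- list(ids, paste0("dim", seq_len(ncol(coords))))
  structure(list(coords = coords, method = method,
                 eigenvalues = eigenvalues, params = params,
                 dropped_ids = dropped_ids),
            class = "ned_embedding")
}

#' @export
print.ned_embedding <- function(x, ...) {
  cat(sprintf("ned_embedding: %d points in %d dimensions (method: %s)\n",
              nrow(x$coords), ncol(x$coords), x$method))
  cat("retained eigenvalues:",
      paste(signif(x$eigenvalues, 6), collapse = ", "), "\n")
  if (length(x$dropped_ids))
    cat(sprintf("dropped %d disconnected ids\n", length(x$dropped_ids)))
  print(utils::head(x$coords), ...)
  if (nrow(x$coords) > 6L) cat(sprintf("  ... %d rows omitted\n", nrow(x$coords) - 6L))
  invisible(x)
}

#' @export
as.matrix.ned_embedding <- function(x, ...) x$coords

# Deterministic eigenvector orientation: flip so the largest-magnitude
# entry is positive (first such entry on ties). Makes embeddings
# bit-identical across LAPACK backends.
fix_signs <- function(V) {
  for (p in seq_len(ncol(V))) {
    i <- which.max(abs(V[, p]))
    if (V[i, p] < 0) V[, p] <- -V[, p]
  }
  V
}

#' Write an embedding as CSV with a JSON metadata sidecar
#'
#' The CSV has columns `id, dim1..dimk` at full float precision. A sidecar
#' `<path>.meta.json` records the method, its parameters, the retained
#' eigenvalues and any ids dropped as disconnected.
#'
#' @param emb a `ned_embedding`.
#' @param path output CSV path.
#' @param meta_path sidecar path (default `<path>.meta.json`).
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path, meta_path = paste0(path, ".meta.json")) {
  stopifnot(inherits(emb, "ned_embedding"))
  Y <- emb$coords
  header <- paste(c("id", colnames(Y)), collapse = ",")
  rows <- vapply(seq_len(nrow(Y)), function(i)
    paste(c(rownames(Y)[i], fmt_num(Y[i, ])), collapse = ","), character(1))
  writeLines(c(header, rows), path)
  meta <- list(method = emb$method, params = emb$params,
               eigenvalues = emb$eigenvalues, dropped_ids = emb$dropped_ids,
               n = nrow(Y), k = ncol(Y))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an embedding CSV written by [write_embedding()]
#' @param path CSV path with `id, dim1..dimk` columns.
#' @return a numeric matrix with ids as rownames.
#' @export
read_embedding <- function(path) {
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character")
  Y <- apply(as.matrix(tab[, -1L, drop = FALSE]), c(1L, 2L), as.numeric)
  rownames(Y) <- tab[[1L]]
  Y
}

#' Scatter plot of a 2-D/3-D embedding colored by label
#'
#' Diagnostic plot mirroring the usual visualization of sequence-family
#' embeddings; for k >= 3 the first two dimensions are shown. Requires
#' ggplot2.
#'
#' @param emb a `ned_embedding`.
#' @param labels optional named label vector (names = ids).
#' @return a ggplot object.
#' @export
plot_embedding <- function(emb, labels = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_nedmap("plot_embedding() requires the ggplot2 package")
  Y <- as.matrix(emb)
  df <- data.frame(id = rownames(Y), x = Y[, 1L],
                   y = if (ncol(Y) >= 2L) Y[, 2L] else 0)
  df$label <- if (is.null(labels)) "sequence" else as.character(labels[df$id])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "dim1", y = "dim2",
                  title = sprintf("%s embedding", emb$method)) +
    ggplot2::theme_minimal()
}
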