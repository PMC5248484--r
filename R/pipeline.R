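#' Run the full visualization pipeline and write its artifacts
#'
#' FASTA (+ optional labels) -> normalized edit-distance matrix ->
#' embedding -> (if labels) K-means validation report. Every artifact is
#' written deterministically, so identical inputs, config and seed yield
#' byte-identical files. Artifacts in `out_dir`:
#' \itemize{
#'   \item `distmat.tsv` — the normalized edit-distance matrix;
#'   \item `embedding.csv` + `embedding.csv.meta.json` — coordinates and
#'     method metadata;
#'   \item `report.json`, `report.txt` — clustering accuracy (labels only);
#'   \item `run_meta.json` — effective config, seeds and input digests.
#' }
#'
#' @param fasta input FASTA path.
#' @param out_dir output directory (created if missing).
#' @param labels_path optional id/label TSV for validation.
#' @param method `"isomap"` or `"le"`.
#' @param k embedding dimension.
#' @param K_frac Isomap neighbour fraction (default 0.30).
#' @param sigma Laplacian Eigenmaps bandwidth (default 0.3).
#' @param weights [edit_weights()].
#' @param variant Isomap centering variant.
#' @param component_policy Isomap disconnection policy.
#' @param iupac_policy input symbol policy, see [seq_records()].
#' @param seed RNG seed (K-means initialization).
#' @param restarts K-means restarts.
#' @param from_matrix optional precomputed `distmat.tsv` to reuse instead
#'   of recomputing distances.
#' @return invisibly, a list with the in-memory objects (`records`, `M`,
#'   `embedding`, and when labels are given `kmeans` and `report`).
#' @export
run_pipeline <- function(fasta, out_dir, labels_path = NULL,
                         method = c("isomap", "le"), k = 2,
                         K_frac = 0.30, sigma = 0.3,
                         weights = edit_weights(),
                         variant = c("classical", "product"),
                         component_policy = c("connect", "error", "largest"),
                         iupac_policy = c("reject", "strip", "as-mismatch"),
                         seed = 1L, restarts = 10L, from_matrix = NULL) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  component_policy <- match.arg(component_policy)
  iupac_policy <- match.arg(iupac_policy)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  records <- read_fasta(fasta, iupac_policy)
  M <- if (is.null(from_matrix)) distance_matrix(records, weights)
       else read_distmat(from_matrix)
  if (!identical(rownames(M), names(records)))
    stop_nedmap("distance-matrix ids do not match the FASTA records")
  write_distmat(M, file.path(out_dir, "distmat.tsv"))

  n <- nrow(M)
  emb <- if (method == "isomap") {
    K <- min(max(1L, as.integer(round(K_frac * n))), n - 1L)
    isomap_embed(M, K = K, k = k, variant = variant,
                 component_policy = component_policy)
  } else {
    le_embed(M, sigma = sigma, k = k)
  }
  write_embedding(emb, file.path(out_dir, "embedding.csv"))

  out <- list(records = records, M = M, embedding = emb)
  if (!is.null(labels_path)) {
    labels <- read_labels(labels_path)
    kept <- rownames(as.matrix(emb))
    miss <- setdiff(kept, names(labels))
    if (length(miss))
      stop_nedmap("labels missing for ids: ",
                  paste(utils::head(miss, 5), collapse = ", "))
    fit <- kmeans_fit(emb, K = length(unique(labels[kept])), seed = seed,
                      restarts = restarts)
    rep <- accuracy(fit, labels[kept])
    report <- list(accuracy = rep$accuracy,
                   majority_accuracy = rep$majority_accuracy,
                   correct = as.list(rep$correct), n = rep$n,
                   matching = rep$matching, seed = seed,
                   restarts = restarts, n_iter = fit$n_iter,
                   method = method, k = k)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    txt <- c(sprintf("method: %s (k = %d)", method, k),
             sprintf("clustering accuracy: %.4f (%d/%d correct)",
                     rep$accuracy, sum(rep$correct), rep$n),
             sprintf("majority-vote accuracy: %.4f", rep$majority_accuracy),
             "matching (cluster -> class):",
             sprintf("  %s -> %s", rep$matching$cluster, rep$matching$class))
    writeLines(txt, file.path(out_dir, "report.txt"))
    out$kmeans <- fit
    out$report <- rep
  }

  meta <- list(
    package = "nedmap",
    version = as.character(utils::packageVersion("nedmap")),
    config = list(method = method, k = k, K_frac = K_frac, sigma = sigma,
                  weights = as.list(unclass(weights)), variant = variant,
                  component_policy = component_policy,
                  iupac_policy = iupac_policy, seed = seed,
                  restarts = restarts),
    inputs = list(
      fasta = fasta, fasta_md5 = unname(tools::md5sum(fasta)),
      labels = labels_path,
      labels_md5 = if (!is.null(labels_path)) unname(tools::md5sum(labels_path))))
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
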