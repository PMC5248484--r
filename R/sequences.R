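#' Build a validated set of DNA sequence records
#'
#' A sequence record set is a named character vector of DNA strings over
#' the alphabet \{A, T, C, G\}, with unique non-empty ids. Sequences are
#' uppercased on input; symbols outside the alphabet (IUPAC ambiguity
#' codes, gaps, U) are handled according to `iupac_policy`:
#' \describe{
#'   \item{`"reject"`}{(default) any non-ACGT symbol is an error naming the
#'     offending record and position;}
#'   \item{`"strip"`}{non-ACGT symbols are removed from the sequence;}
#'   \item{`"as-mismatch"`}{non-ACGT symbols are kept but never count as a
#'     match in the edit-distance recursion, not even against themselves.}
#' }
#'
#' @param seqs character vector of sequences.
#' @param ids character vector of unique record ids; defaults to
#'   `names(seqs)`.
#' @param iupac_policy one of `"reject"`, `"strip"`, `"as-mismatch"`.
#' @return a named character vector of class `"seq_records"`; the applied
#'   policy is recorded in the `"iupac_policy"` attribute.
#' @examples
#' recs <- seq_records(c(a = "ATCAGTA", b = "TCGACTA"))
#' seq_lengths(recs)
#' @export
seq_records <- function(seqs, ids = names(seqs),
                        iupac_policy = c("reject", "strip", "as-mismatch")) {
  iupac_policy <- match.arg(iupac_policy)
  if (!is.character(seqs) || length(seqs) < 1L)
    stop_nedmap("`seqs` must be a non-empty character vector")
  if (is.null(ids) || !is.character(ids) || length(ids) != length(seqs))
    stop_nedmap("`ids` must be a character vector matching `seqs` in length")
  if (anyNA(seqs) || anyNA(ids)) stop_nedmap("sequences and ids must not be NA")
  if (any(!nzchar(ids))) stop_nedmap("record ids must be non-empty strings")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_nedmap("duplicate record ids: ", paste(dup, collapse = ", "))

  seqs <- toupper(seqs)
  bad <- gregexpr("[^ATCG]", seqs)
  has_bad <- vapply(bad, function(m) m[1L] != -1L, logical(1))
  if (any(has_bad)) {
    if (iupac_policy == "reject") {
      i <- which(has_bad)[1L]
      stop_nedmap(sprintf(
        "record '%s' has non-ACGT symbol '%s' at position %d (iupac_policy = \"reject\")",
        ids[i], substr(seqs[i], bad[[i]][1L], bad[[i]][1L]), bad[[i]][1L]))
    }
    if (iupac_policy == "strip") seqs <- gsub("[^ATCG]", "", seqs)
  }
  if (any(!nzchar(seqs))) {
    i <- which(!nzchar(seqs))[1L]
    stop_nedmap(sprintf("record '%s' is empty after input normalization", ids[i]))
  }
  structure(stats::setNames(seqs, ids),
            iupac_policy = iupac_policy,
            class = "seq_records")
}

#' Sequence lengths of a record set
#' @param records a `seq_records` object (or plain character vector).
#' @return integer vector of per-record lengths, named by id.
#' @export
seq_lengths <- function(records) {
  stats::setNames(nchar(unclass(records)), names(records))
}

#' @export
print.seq_records <- function(x, ...) {
  n <- length(x)
  len <- nchar(unclass(x))
  cat(sprintf("seq_records: %d DNA sequences, lengths %d-%d (policy: %s)\n",
              n, min(len), max(len), attr(x, "iupac_policy")))
  show <- utils::head(seq_len(n), 6L)
  for (i in show) {
    s <- unclass(x)[i]
    cat(sprintf("  %s  %s%s (%d nt)\n", names(x)[i],
                substr(s, 1L, 40L), if (nchar(s) > 40L) "..." else "",
                nchar(s)))
  }
  if (n > 6L) cat(sprintf("  ... and %d more\n", n - 6L))
  invisible(x)
}

#' @export
`[.seq_records` <- function(x, i, ...) {
  structure(NextMethod(), iupac_policy = attr(x, "iupac_policy"),
            class = "seq_records")
}

# TRUE when ambiguous symbols must never match in the DP
restrict_match_policy <- function(records) {
  identical(attr(records, "iupac_policy"), "as-mismatch")
}

as_seq_chr <- function(x) {
  if (inherits(x, "seq_records")) unclass(x) else as.character(x)
}
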