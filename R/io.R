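#' Read DNA sequences from a FASTA file
#'
#' Multi-record FASTA (wrapped or unwrapped lines) read via Biostrings.
#' The record id is the first whitespace-delimited token of each header.
#' Sequences are validated and normalized per `iupac_policy` (see
#' [seq_records()]); duplicate ids are an error listing the duplicates.
#'
#' @param path FASTA file path.
#' @param iupac_policy `"reject"`, `"strip"` or `"as-mismatch"`.
#' @return a [seq_records()] set, order-preserving.
#' @export
read_fasta <- function(path, iupac_policy = c("reject", "strip", "as-mismatch")) {
  iupac_policy <- match.arg(iupac_policy)
  if (!file.exists(path)) stop_nedmap("FASTA file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop_nedmap("malformed FASTA in ", path,
                                                ": ", conditionMessage(e)))
  if (!length(x)) stop_nedmap("no records in ", path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  seq_records(as.character(x), ids = ids, iupac_policy = iupac_policy)
}

#' Write sequences as FASTA
#'
#' 60-column wrapped FASTA; deterministic bytes for a given record set.
#'
#' @param records a [seq_records()] set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- as_seq_chr(records)
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    body <- gsub("(.{60})", "\\1\n", seqs[[i]])
    if (!endsWith(body, "\n")) body <- paste0(body, "\n")
    writeLines(c(paste0(">", names(seqs)[i])), con, sep = "\n")
    cat(body, file = con, sep = "")
  }
  invisible(path)
}

#' Read a two-column labels TSV (id, label)
#'
#' @param path TSV path; a `id<TAB>label` header row is accepted and
#'   skipped.
#' @return named character vector of labels (names = ids).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_nedmap("labels file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("id", "label"))
  if (nrow(tab) && identical(tolower(tab$id[1L]), "id"))
    tab <- tab[-1L, , drop = FALSE]
  if (!nrow(tab)) stop_nedmap("no label rows in ", path)
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup)) stop_nedmap("duplicate ids in labels file: ",
                               paste(dup, collapse = ", "))
  stats::setNames(tab$label, tab$id)
}

#' Write a two-column labels TSV
#' @param labels named character vector (names = ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  writeLines(c("id\tlabel", paste(names(labels), labels, sep = "\t")), path)
  invisible(path)
}
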