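#' Edit-operation weights
#'
#' Weight quadruple for the edit-distance dynamic program: insertion,
#' deletion, substitution and match. All weights must be non-negative and
#' the match weight must not exceed the substitution weight, otherwise the
#' match branch of the recursion would never be preferred and the
#' length-normalization bound would break. The default (1, 1, 1, 0) is the
#' classical Levenshtein distance.
#'
#' @param w_ins,w_del,w_sub,w_mat non-negative reals.
#' @return a named numeric vector of class `"edit_weights"`.
#' @examples
#' edit_weights()                 # Levenshtein
#' edit_weights(w_sub = 2)        # substitutions twice as costly
#' @export
edit_weights <- function(w_ins = 1, w_del = 1, w_sub = 1, w_mat = 0) {
  w <- c(w_ins = w_ins, w_del = w_del, w_sub = w_sub, w_mat = w_mat)
  if (!is.numeric(w) || anyNA(w) || any(w < 0))
    stop_nedmap("edit weights must be non-negative numbers")
  if (w[["w_mat"]] > w[["w_sub"]])
    stop_nedmap("w_mat must not exceed w_sub")
  structure(w, class = "edit_weights")
}

check_weights <- function(w) {
  if (!inherits(w, "edit_weights"))
    w <- do.call(edit_weights, as.list(w))
  w
}

check_one_seq <- function(x, name) {
  if (inherits(x, "seq_records")) {
    if (length(x) != 1L) stop_nedmap(sprintf("`%s` must be a single sequence", name))
    return(unclass(x)[[1L]])
  }
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop_nedmap(sprintf("`%s` must be a single character string", name))
  x <- toupper(x)
  if (grepl("[^ATCG]", x) && nzchar(x)) {
    pos <- regexpr("[^ATCG]", x)
    stop_nedmap(sprintf("`%s` has non-ACGT symbol '%s' at position %d",
                        name, substr(x, pos, pos), pos))
  }
  x
}

#' Weighted edit distance between two DNA sequences
#'
#' Minimum total weight of insertions, deletions and substitutions
#' transforming `x` into `y`, computed by dynamic programming over prefix
#' pairs. With the default unit weights this is the Levenshtein distance;
#' the result is then an integer bounded by `max(nchar(x), nchar(y))` and
#' bounded below by the length difference.
#'
#' @param x,y single sequences (character strings over A/T/C/G, or
#'   length-one `seq_records`). The empty string is allowed and acts as the
#'   empty prefix.
#' @param weights an [edit_weights()] quadruple.
#' @param restrict_match if `TRUE`, symbols outside A/C/G/T never match
#'   (the `"as-mismatch"` input policy); such symbols are otherwise
#'   rejected by [seq_records()] before reaching this function.
#' @return a single non-negative number.
#' @examples
#' edit_distance("ATCAGTA", "TCGACTA")  # 3
#' @seealso [dp_table()] for the full prefix table,
#'   [normalized_edit_distance()] for the length-normalized value.
#' @export
edit_distance <- function(x, y, weights = edit_weights(),
                          restrict_match = FALSE) {
  weights <- check_weights(weights)
  x <- check_one_seq(x, "x"); y <- check_one_seq(y, "y")
  ed_distance_cpp(x, y, weights[["w_ins"]], weights[["w_del"]],
                  weights[["w_sub"]], weights[["w_mat"]],
                  check_flag(restrict_match, "restrict_match"))
}

#' Edit-distance dynamic-programming table
#'
#' The full `(nchar(x)+1) x (nchar(y)+1)` prefix table `T`, where
#' `T[p+1, q+1]` is the weighted edit distance between the first `p`
#' symbols of `x` and the first `q` symbols of `y` (row/column 1 hold the
#' empty-prefix boundary `p * w_del` / `q * w_ins`). The last cell equals
#' [edit_distance()].
#'
#' @inheritParams edit_distance
#' @return a numeric matrix with prefix strings as dimnames.
#' @examples
#' T <- dp_table("ATCAGTA", "TCGACTA")
#' T[8, 8]  # 3
#' @export
dp_table <- function(x, y, weights = edit_weights(), restrict_match = FALSE) {
  weights <- check_weights(weights)
  x <- check_one_seq(x, "x"); y <- check_one_seq(y, "y")
  T <- ed_table_cpp(x, y, weights[["w_ins"]], weights[["w_del"]],
                    weights[["w_sub"]], weights[["w_mat"]],
                    check_flag(restrict_match, "restrict_match"))
  dimnames(T) <- list(
    c("", substring(x, 1L, seq_len(nchar(x)))),
    c("", substring(y, 1L, seq_len(nchar(y)))))
  T
}

#' Normalized edit distance
#'
#' The weighted edit distance divided by the length of the longer
#' sequence, `n_d(x, y) = d(x, y) / max(|x|, |y|)`. Under the default unit
#' weights this maps any pair of sequences into \[0, 1\], making sequences
#' of very different lengths comparable: it is 0 iff the sequences are
#' identical and 1 when every position of the longer sequence must be
#' edited.
#'
#' @inheritParams edit_distance
#' @return a number in \[0, 1\] under default weights.
#' @examples
#' normalized_edit_distance("ATCAGTA", "TCGACTA")  # 3/7
#' @export
normalized_edit_distance <- function(x, y, weights = edit_weights(),
                                     restrict_match = FALSE) {
  xs <- check_one_seq(x, "x"); ys <- check_one_seq(y, "y")
  denom <- max(nchar(xs), nchar(ys))
  if (denom == 0L)
    stop_nedmap("both sequences are empty: normalized edit distance is undefined")
  edit_distance(xs, ys, weights, restrict_match) / denom
}
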