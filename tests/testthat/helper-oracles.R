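# Independent oracles and fixture builders shared across the suite.

# Memo-free exhaustive edit-script recursion: explores every interleaving
# of deletions, insertions and (mis)matches. Exponential on purpose —
# only usable for short strings — and deliberately independent of the DP.
edit_oracle <- function(x, y, w_ins = 1, w_del = 1, w_sub = 1, w_mat = 0) {
  xs <- strsplit(x, "")[[1L]]
  ys <- strsplit(y, "")[[1L]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- Inf
    if (i > 0L) best <- min(best, rec(i - 1L, j) + w_del)
    if (j > 0L) best <- min(best, rec(i, j - 1L) + w_ins)
    if (i > 0L && j > 0L)
      best <- min(best,
                  rec(i - 1L, j - 1L) + if (xs[i] == ys[j]) w_mat else w_sub)
    best
  }
  rec(length(xs), length(ys))
}

# all strings over `alphabet` of length 0..max_len
all_strings <- function(alphabet, max_len) {
  out <- ""
  for (len in seq_len(max_len)) {
    grids <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, apply(as.matrix(grids), 1L, paste, collapse = ""))
  }
  out
}

rand_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

# Euclidean distance matrix of planted coordinates
planted_distmat <- function(X) {
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("p", seq_len(nrow(X))),
                      paste0("p", seq_len(nrow(X))))
  D
}

# random symmetric matrix usable as a (not necessarily metric) distance
rand_symmetric_dist <- function(n, max = 1) {
  M <- matrix(runif(n * n, 0.05, max), n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

# random connected undirected weighted graph as an Inf-padded matrix
rand_connected_graph <- function(n, extra_edges = n) {
  g <- matrix(Inf, n, n)
  diag(g) <- 0
  perm <- sample.int(n)           # random spanning tree guarantees connectivity
  for (i in 2:n) {
    a <- perm[i]
    b <- perm[sample.int(i - 1L, 1L)]
    w <- runif(1, 0.1, 2)
    g[a, b] <- w; g[b, a] <- w
  }
  for (e in seq_len(extra_edges)) {
    ij <- sample.int(n, 2L)
    w <- runif(1, 0.1, 2)
    g[ij[1L], ij[2L]] <- min(g[ij[1L], ij[2L]], w)
    g[ij[2L], ij[1L]] <- g[ij[1L], ij[2L]]
  }
  g
}

# exhaustive one-to-one matching oracle for clustering accuracy:
# enumerate every injective map from the smaller side of the contingency
# table into the larger and take the best total.
accuracy_oracle <- function(assign, truth) {
  tab <- unclass(table(factor(assign), factor(truth)))
  swap <- nrow(tab) > ncol(tab)
  if (swap) tab <- t(tab)
  m <- nrow(tab); M <- ncol(tab)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- 0
  for (p in perms(seq_len(M))) {
    cols <- p[seq_len(m)]
    best <- max(best, sum(tab[cbind(seq_len(m), cols)]))
  }
  best / length(assign)
}

small_families <- function(n_per = 15L, seed = 11L) {
  synth_families(list(family_spec("fa", n_per, 80),
                      family_spec("fb", n_per, 120),
                      family_spec("fc", n_per, 160)), seed = seed)
}
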