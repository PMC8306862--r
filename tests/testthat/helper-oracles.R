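# Independent brute-force oracles used to validate the implementation.
# They deliberately avoid the package's code paths: patterns are keyed by
# strings, parsing uses substring search, distances use Floyd-Warshall.

# Ordinal distribution by direct enumeration; patterns keyed by the stable
# sorting permutation pasted to a string.
oracle_pattern_table <- function(x, m, tau = 1, weighted = FALSE) {
  nwin <- length(x) - (m - 1) * tau
  stopifnot(nwin >= 1)
  keys <- character(nwin)
  w <- numeric(nwin)
  for (k in seq_len(nwin)) {
    v <- x[k + (0:(m - 1)) * tau]
    keys[k] <- paste(order(v), collapse = "-")
    w[k] <- if (weighted) mean((v - mean(v))^2) else 1
  }
  tapply(w, keys, sum) / sum(w)
}

# Normalized PE from the oracle table (natural log).
oracle_pe <- function(x, m, tau = 1, weighted = FALSE) {
  p <- oracle_pattern_table(x, m, tau, weighted)
  p <- p[p > 0]
  -sum(p * log(p)) / log(factorial(m))
}

# Jensen-Shannon complexity from an explicit probability vector padded with
# zeros to M bins; written term by term, independent of the package helper.
oracle_jsc <- function(p, M) {
  p <- c(p, rep(0, M - length(p)))
  u <- rep(1 / M, M)
  ent <- function(q) {
    s <- 0
    for (qi in q) if (qi > 0) s <- s - qi * log(qi)
    s
  }
  jsd <- ent((p + u) / 2) - ent(p) / 2 - ent(u) / 2
  q0 <- -2 / (((M + 1) / M) * log(M + 1) - 2 * log(2 * M) + log(M))
  q0 * jsd * (ent(p) / log(M))
}

# LZ76 exhaustive-history phrase count by definition: grow each phrase while
# it occurs as a substring of everything before its last character.
oracle_lz76 <- function(sym) {
  txt <- paste(letters[sym + 1L], collapse = "")
  n <- nchar(txt)
  cnt <- 0L
  start <- 1L
  while (start <= n) {
    end <- start
    while (end <= n &&
           grepl(substr(txt, start, end), substr(txt, 1, end - 1L),
                 fixed = TRUE)) {
      end <- end + 1L
    }
    cnt <- cnt + 1L
    start <- end + 1L
  }
  cnt
}

# All-pairs shortest paths by Floyd-Warshall on a 0/1 adjacency matrix.
oracle_geodesics <- function(adj) {
  N <- nrow(adj)
  d <- matrix(Inf, N, N)
  diag(d) <- 0
  d[adj != 0] <- 1
  for (k in seq_len(N)) {
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Node geodesic entropies and their mean from the Floyd-Warshall distances,
# renormalised over reachable nodes; isolated nodes contribute 0.
oracle_age <- function(adj) {
  d <- oracle_geodesics(adj)
  ge <- vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0) return(0)
    p <- as.numeric(table(di)) / length(di)
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  list(node_ge = ge, age = mean(ge))
}

# Adjacency matrix of labelled graph index `code` on N nodes: bits of `code`
# fill the upper triangle.
graph_from_code <- function(code, N) {
  npair <- N * (N - 1) / 2
  bits <- as.integer(intToBits(code))[seq_len(npair)]
  adj <- matrix(0L, N, N)
  adj[upper.tri(adj)] <- bits
  adj + t(adj)
}
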