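# Independent brute-force oracles for graph measurements. Deliberately
# naive (adjacency powers, exhaustive path enumeration, exhaustive
# partitions) and independent of the package implementation.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  Ak <- diag(n)
  for (k in seq_len(n)) {
    Ak <- Ak %*% A
    newly <- Ak > 0 & is.infinite(D)
    D[newly] <- k
  }
  D
}

# All shortest paths between a pair by exhaustive simple-path enumeration
# (n <= 8 only); returns the list of node sequences.
oracle_shortest_paths <- function(A, s, t) {
  n <- nrow(A)
  target_len <- oracle_distances(A)[s, t]
  if (is.infinite(target_len)) return(list())
  paths <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur == t) {
      if (length(path) - 1 == target_len) paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    if (length(path) - 1 >= target_len) return(invisible())
    for (nb in which(A[cur, ] == 1)) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  walk(s)
  paths
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- oracle_shortest_paths(A, s, t)
      if (length(paths) == 0) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(paths)
      }
    }
  }
  btw
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
}

# Best modularity over all partitions of n nodes (n <= 6: Bell(6) = 203).
oracle_best_modularity <- function(A) {
  n <- nrow(A)
  m <- sum(A) / 2
  deg <- rowSums(A)
  partitions <- list(rep(1L, 1L))
  assignments <- function(k) {
    if (k == 0) return(list(integer(0)))
    sub <- assignments(k - 1)
    out <- list()
    for (a in sub) {
      top <- if (length(a)) max(a) else 0L
      for (c in seq_len(top + 1L)) out[[length(out) + 1L]] <- c(a, c)
    }
    out
  }
  best <- -Inf
  for (memb in assignments(n)) {
    q <- 0
    for (c in unique(memb)) {
      idx <- memb == c
      e_cc <- sum(A[idx, idx]) / (2 * m)
      a_c <- sum(deg[idx]) / (2 * m)
      q <- q + e_cc - a_c^2
    }
    best <- max(best, q)
  }
  best
}

# Erdos-Renyi adjacency with guaranteed >= 1 edge
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.integer(stats::runif(length(up)) < p)
    A <- A + t(A)
    if (sum(A) > 0) return(A)
  }
}

# Small named graphs used across tests
star_graph <- function(leaves = 3) {
  n <- leaves + 1
  A <- matrix(0L, n, n)
  A[1, 2:n] <- 1L
  A[2:n, 1] <- 1L
  A
}

path_graph <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}

complete_graph <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  A
}

two_triangles <- function() {
  A <- matrix(0L, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  }
  A
}
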