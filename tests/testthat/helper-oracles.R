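# Independent brute-force oracles and small fixture builders shared across
# the suite. Everything here is deliberately naive: exhaustive enumeration
# only, never the algorithms under test.

# All simple paths between two nodes by depth-first search over an edge list.
# Returns a list of integer vectors (node sequences).
all_simple_paths_brute <- function(adj, s, t) {
  n <- nrow(adj)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (u in seq_len(n)) {
      if (adj[v, u] > 0 && !(u %in% path)) walk(c(path, u))
    }
  }
  walk(s)
  out
}

# Exact closeness/betweenness by enumerating every simple path of every pair.
# `lengths` is the edge-length matrix (0 = no edge). Closeness uses
# reachable-count / summed distances; betweenness counts shortest paths
# through interior vertices with multiplicity fractions.
centrality_oracle <- function(lengths) {
  n <- nrow(lengths)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  btw <- rep(0, n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_simple_paths_brute(lengths, s, t)
      if (length(paths) == 0) next
      plen <- vapply(paths, function(p) {
        sum(lengths[cbind(p[-length(p)], p[-1])])
      }, numeric(1))
      dmin <- min(plen)
      dist[s, t] <- dist[t, s] <- dmin
      shortest <- paths[plen <= dmin + 1e-12]
      sigma <- length(shortest)
      interior <- unlist(lapply(shortest, function(p) p[-c(1, length(p))]))
      if (length(interior) > 0) {
        tab <- table(interior)
        idx <- as.integer(names(tab))
        btw[idx] <- btw[idx] + as.numeric(tab) / sigma
      }
    }
  }
  closeness <- vapply(1:n, function(i) {
    d <- dist[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
  list(closeness = closeness, betweenness = btw, dist = dist)
}

# Random pairwise_network on n nodes; weighted draws signed weights.
random_network <- function(n, p_edge = 0.5, weighted = FALSE,
                           connected = FALSE) {
  repeat {
    edges <- NULL
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p_edge) {
          w <- if (weighted) stats::runif(1, 0.2, 2) *
              sample(c(-1, 1), 1) else 1
          edges <- rbind(edges, data.frame(from = paste0("N", i),
                                           to = paste0("N", j), weight = w))
        }
      }
    }
    net <- pairwise_network(paste0("N", 1:n), edges)
    if (!connected) return(net)
    if (nrow(net$edges) >= n - 1 &&
        igraph::is_connected(as_igraph(net))) return(net)
  }
}

adjacency_lengths <- function(net, weighted = TRUE) {
  n <- length(net$nodes)
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(net$edges))) {
    i <- match(net$edges$from[k], net$nodes)
    j <- match(net$edges$to[k], net$nodes)
    L[i, j] <- L[j, i] <- if (weighted) 1 / abs(net$edges$weight[k]) else 1
  }
  L
}

# All set partitions of 1..n (restricted-growth strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(assign, maxid) {
    k <- length(assign)
    if (k == n) {
      out[[length(out) + 1L]] <<- assign
      return()
    }
    for (id in seq_len(maxid + 1)) grow(c(assign, id), max(maxid, id))
  }
  grow(1L, 1L)
  out
}

# Chain Ising parameters: W[i, i+1] = w, h = 0.
chain_params <- function(p = 8, w = 1.2) {
  W <- matrix(0, p, p)
  for (i in 1:(p - 1)) {
    W[i, i + 1] <- w
    W[i + 1, i] <- w
  }
  codes <- paste0("D", seq_len(p))
  dimnames(W) <- list(codes, codes)
  structure(list(W = W, h = stats::setNames(rep(0, p), codes)),
            class = "ising_parameters")
}

small_catalog <- function(p) {
  disease_catalog(paste0("D", seq_len(p)), paste0("disease ", seq_len(p)))
}

# Minimal valid cohort from a disease matrix with fixed demographics.
matrix_cohort <- function(X, catalog = small_catalog(ncol(X)),
                          gender = NULL) {
  n <- nrow(X)
  colnames(X) <- catalog$code
  df <- tibble::tibble(
    person_id = sprintf("P%03d", seq_len(n)),
    gender = gender %||% rep(c("M", "F"), length.out = n),
    age_group = rep("50-64", n),
    income_q = rep("Q1", n),
    education = rep("Primary", n)
  )
  validate_cohort(dplyr::bind_cols(df, tibble::as_tibble(X)), catalog)
}

# The two-triangle graph: cliques {a,b,c} and {d,e,f} joined by c-d.
two_triangles <- function() {
  pairwise_network(
    letters[1:6],
    data.frame(from = c("a", "a", "b", "d", "d", "e", "c"),
               to   = c("b", "c", "c", "e", "f", "f", "d"),
               weight = 1)
  )
}

# 12-person, 8-disease hand fixture with a fixed three-community partition.
pattern_fixture <- function() {
  catalog <- small_catalog(8)
  # communities: C1 = D1,D2,D3; C2 = D4,D5,D6; C3 = D7,D8
  membership <- stats::setNames(c(1, 1, 1, 2, 2, 2, 3, 3), catalog$code)
  X <- rbind(
    c(1, 1, 0, 0, 0, 0, 0, 0),  # P001: 2 in C1            -> {1}
    c(1, 1, 1, 0, 0, 0, 0, 0),  # P002: 3 in C1            -> {1}
    c(1, 0, 0, 1, 0, 0, 0, 0),  # P003: 1+1                -> {}
    c(1, 1, 0, 1, 1, 0, 0, 0),  # P004: 2 in C1, 2 in C2   -> {1,2} complex
    c(0, 0, 0, 1, 1, 1, 1, 1),  # P005: 3 in C2, 2 in C3   -> {2,3} complex
    c(0, 0, 0, 0, 0, 0, 1, 1),  # P006: 2 in C3            -> {3}
    c(0, 0, 0, 0, 0, 0, 0, 0),  # P007: nothing            -> {}
    c(1, 0, 1, 0, 1, 0, 1, 0),  # P008: 2 in C1            -> {1}
    c(1, 1, 1, 1, 1, 1, 1, 1),  # P009: all                -> {1,2,3} complex
    c(0, 1, 1, 0, 0, 1, 0, 1),  # P010: 2 in C1            -> {1}
    c(0, 0, 0, 1, 1, 0, 0, 0),  # P011: 2 in C2            -> {2}
    c(0, 0, 0, 0, 1, 1, 1, 0)   # P012: 2 in C2            -> {2}
  )
  gender <- c("M", "M", "M", "M", "M", "M", "F", "F", "F", "F", "F", "F")
  list(cohort = matrix_cohort(X, catalog, gender = gender),
       membership = membership)
}

# Structural bipartiteness by BFS 2-coloring (igraph's bipartite_mapping
# errors on named non-bipartite graphs in some versions).
is_bipartite_net <- function(net) {
  n <- length(net$nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(net$edges))) {
    i <- match(net$edges$from[k], net$nodes)
    j <- match(net$edges$to[k], net$nodes)
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  colr <- rep(NA_integer_, n)
  for (start in seq_len(n)) {
    if (!is.na(colr[start])) next
    colr[start] <- 0L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.na(colr[u])) {
          colr[u] <- 1L - colr[v]
          queue <- c(queue, u)
        } else if (colr[u] == colr[v]) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}
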