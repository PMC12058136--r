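#' Detect multimorbidity patterns by fast-greedy modularity maximisation
#'
#' Agglomerative (CNM) community detection on the disease network, using
#' absolute edge weights: starting from singletons, the pair of communities
#' with the largest modularity gain is merged until no merge improves
#' modularity. Isolated nodes end up as singleton communities; an edgeless
#' network yields all singletons with Q = 0 (and a warning, since modularity
#' is undefined at zero total weight).
#'
#' @param net A [pairwise_network()].
#' @return An object of class `community_partition`: a list with `membership`
#'   (tibble `disease`, `community`), `Q` (modularity of the returned
#'   partition), and `merges` (the merge matrix of the agglomeration).
#' @export
detect_communities <- function(net) {
  stopifnot(inherits(net, "pairwise_network"), length(net$nodes) >= 1)
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) {
    warning("network has no edges: all-singleton partition, Q defined as 0")
    memb <- tibble::tibble(disease = net$nodes,
                           community = seq_along(net$nodes))
    return(structure(list(membership = memb, Q = 0, merges = NULL),
                     class = "community_partition"))
  }
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$absweight)
  # cut the dendrogram at the modularity-optimal step ourselves; ties go to
  # the coarser partition (deterministic)
  n_nodes <- length(net$nodes)
  ks <- seq(n_nodes - nrow(cl$merges), n_nodes)
  cuts <- lapply(ks, function(k) igraph::cut_at(cl, no = k))
  qs <- vapply(cuts, function(mb)
    modularity_q(net, stats::setNames(mb, net$nodes)), numeric(1))
  best <- which(qs >= max(qs) - 1e-12)[1]
  memb <- tibble::tibble(disease = net$nodes,
                         community = as.integer(cuts[[best]]))
  q <- qs[best]
  structure(list(membership = memb, Q = q, merges = cl$merges),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  k <- length(unique(x$membership$community))
  cat(sprintf("<community_partition: %d communities, Q = %.4f>\n", k, x$Q))
  invisible(x)
}

#' @export
#' @method tidy community_partition
tidy.community_partition <- function(x, ...) x$membership

#' Weighted modularity of a partition
#'
#' Direct evaluation of `Q = sum_c (e_c / m - (d_c / 2m)^2)` on absolute edge
#' weights, where `e_c` is the total weight inside community `c`, `d_c` the
#' total weighted degree of its nodes and `m` the total edge weight. Q is
#' invariant to rescaling all weights. A weightless network yields 0 with a
#' warning.
#'
#' @param net A [pairwise_network()].
#' @param membership Named integer vector (or `community_partition`) mapping
#'   every node to a community id.
#' @return The modularity, a real number in [-0.5, 1].
#' @export
modularity_q <- function(net, membership) {
  stopifnot(inherits(net, "pairwise_network"))
  if (inherits(membership, "community_partition")) {
    membership <- stats::setNames(membership$membership$community,
                                  membership$membership$disease)
  }
  if (!all(net$nodes %in% names(membership))) {
    stop("membership must cover every network node", call. = FALSE)
  }
  w <- abs(net$edges$weight)
  m <- sum(w)
  if (m == 0) {
    warning("total edge weight is 0: modularity defined as 0")
    return(0)
  }
  cfrom <- membership[net$edges$from]
  cto <- membership[net$edges$to]
  e_in <- tapply(w[cfrom == cto], cfrom[cfrom == cto], sum)
  deg <- tapply(c(w, w), c(cfrom, cto), sum)  # weighted degree per community
  q <- sum(deg^2) / (4 * m^2)
  sum(e_in) / m - q
}

#' Six disease-centrality metrics
#'
#' Computes, per disease: degree (count of incident edges); closeness
#' (number of other reachable nodes divided by the summed shortest-path
#' distances to them, 0 for isolates); betweenness (Brandes' algorithm);
#' PageRank (damping 0.85, sums to 1); eigenvector centrality (principal
#' eigenvector of the weighted adjacency, scaled to max 1); and the HITS hub
#' score (equal to the authority score on undirected graphs, scaled to max
#' 1). In weighted mode (default) shortest-path metrics use edge lengths
#' `1 / |weight|` (strong association = short distance) while spectral
#' metrics use `|weight|`; in unweighted mode all edges count 1. Edge signs
#' never enter: association magnitude carries the strength.
#'
#' @param net A [pairwise_network()].
#' @param weighted Use edge weights (default `TRUE`) or treat every edge as
#'   unit strength.
#' @param damping PageRank damping factor (default 0.85).
#' @return A tibble with columns `disease`, `degree`, `closeness`,
#'   `betweenness`, `pagerank`, `eigenvector`, `hub_score`, in catalog order.
#' @export
compute_centralities <- function(net, weighted = TRUE, damping = 0.85) {
  stopifnot(inherits(net, "pairwise_network"))
  g <- as_igraph(net)
  nv <- igraph::vcount(g)
  has_edges <- igraph::ecount(g) > 0
  aw <- if (has_edges && weighted) igraph::E(g)$absweight else
    rep(1, igraph::ecount(g))
  len <- if (length(aw)) 1 / aw else numeric()
  deg <- igraph::degree(g)
  if (has_edges) {
    D <- igraph::distances(g, weights = len)
    closeness <- vapply(seq_len(nv), function(i) {
      d <- D[i, -i]
      d <- d[is.finite(d)]
      if (length(d) == 0) 0 else length(d) / sum(d)
    }, numeric(1))
    btw <- igraph::betweenness(g, weights = len)
    pr <- igraph::page_rank(g, damping = damping, weights = aw)$vector
    ev <- igraph::eigen_centrality(g, weights = aw)$vector
    hub <- igraph::hits_scores(g, weights = aw, scale = TRUE)$hub
  } else {
    closeness <- btw <- rep(0, nv)
    pr <- rep(1 / nv, nv)
    ev <- hub <- rep(0, nv)
  }
  tibble::tibble(
    disease = net$nodes,
    degree = as.integer(deg),
    closeness = as.numeric(closeness),
    betweenness = as.numeric(btw),
    pagerank = as.numeric(pr),
    eigenvector = as.numeric(ev),
    hub_score = as.numeric(hub)
  )
}

#' Rank candidate bridging diseases
#'
#' Orders diseases by a chosen centrality metric (betweenness by default, the
#' canonical bridge signal: it counts how often a disease sits on shortest
#' paths between other conditions). Ties are broken by degree, then by
#' catalog order, so the ranking is fully deterministic. All six metrics are
#' kept in the output for side-by-side reading.
#'
#' @param table A centrality tibble from [compute_centralities()].
#' @param metric Ranking metric; one of the six centrality column names.
#' @param top_k Optionally keep only the first `top_k` rows.
#' @return The reordered centrality tibble with a leading `rank` column.
#' @export
rank_bridges <- function(table, metric = "betweenness", top_k = NULL) {
  stopifnot(nrow(table) > 0)
  metrics <- c("degree", "closeness", "betweenness", "pagerank",
               "eigenvector", "hub_score")
  if (!metric %in% metrics) {
    stop("metric must be one of: ", paste(metrics, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(-table[[metric]], -table$degree, seq_len(nrow(table)))
  out <- table[ord, ]
  out <- dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

#' Write a community partition as JSON
#'
#' On-disk format: an object mapping community id to the list of member
#' disease codes.
#'
#' @param partition A `community_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  memb <- partition$membership
  x <- split(memb$disease, memb$community)
  jsonlite::write_json(x, path, pretty = TRUE)
  invisible(path)
}
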