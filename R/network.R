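# Per-pen aggression networks and node centrality traits.
#
# Fight and bullying records are combined into one undirected, unweighted
# graph per pen (an edge between two pen mates means at least one aggressive
# interaction in either direction); all centralities are computed on that
# graph, with isolated animals kept as degree-0 nodes.

#' Build the undirected aggression network of one pen
#'
#' @param records data frame of interaction records with columns
#'   `initiator_id` and `receiver_id` (and optionally `kind`, `duration`,
#'   which are deliberately ignored: the network is unweighted and
#'   undirected).
#' @param pen_members vector of animal ids housed in the pen, including
#'   animals with no recorded interaction.
#' @param pen_id optional pen label carried through to outputs.
#' @return an object of class `pen_network`: the member ids, a symmetric
#'   logical adjacency matrix with zero diagonal, and the pen id.
#' @export
build_pen_network <- function(records, pen_members, pen_id = NULL) {
  pen_members <- as.character(pen_members)
  n <- length(pen_members)
  adj <- matrix(FALSE, n, n, dimnames = list(pen_members, pen_members))
  if (nrow(records)) {
    ini <- as.character(records$initiator_id)
    rec <- as.character(records$receiver_id)
    bad <- setdiff(c(ini, rec), pen_members)
    if (length(bad))
      stop("interaction records reference animals outside the pen: ",
           paste(bad, collapse = ", "))
    if (any(ini == rec)) stop("self-interaction records are not allowed")
    adj[cbind(ini, rec)] <- TRUE
    adj <- adj | t(adj)
  }
  structure(list(pen_id = pen_id, members = pen_members, adjacency = adj),
            class = "pen_network")
}

#' @export
print.pen_network <- function(x, ...) {
  cat("<pen_network>", if (!is.null(x$pen_id)) paste0("pen ", x$pen_id), ":",
      length(x$members), "animals,", sum(x$adjacency) / 2, "edges\n")
  invisible(x)
}

.as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency * 1, mode = "undirected",
                                      diag = FALSE)
}

#' Degree centrality
#'
#' Number of pen mates an animal interacted with, normalised by `n - 1`.
#'
#' @param net a [build_pen_network()] object.
#' @return named numeric vector of normalised degree (`k_i / (n-1)`); the raw
#'   degree counts are attached as attribute `"raw"`.
#' @export
degree_centrality <- function(net) {
  n <- length(net$members)
  if (n < 2) stop("degree centrality needs at least 2 nodes")
  raw <- rowSums(net$adjacency)
  out <- stats::setNames(raw / (n - 1), net$members)
  attr(out, "raw") <- stats::setNames(as.integer(raw), net$members)
  out
}

#' Betweenness centrality
#'
#' Fraction of shortest paths between other pairs of pen mates passing
#' through each animal, normalised by `(n-1)(n-2)/2`.
#'
#' @inheritParams degree_centrality
#' @return named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(net) {
  if (length(net$members) < 3) stop("betweenness needs at least 3 nodes")
  g <- .as_igraph(net)
  stats::setNames(igraph::betweenness(g, directed = FALSE, normalized = TRUE),
                  net$members)
}

#' Closeness centrality
#'
#' Inverse average geodesic distance, with the reachable-set rescaling for
#' disconnected graphs: for node `v` with `r` reachable other nodes at total
#' distance `D`, closeness is `(r / D) * (r / (n - 1))`; isolated nodes get 0.
#'
#' @inheritParams degree_centrality
#' @return named numeric vector in `[0, 1]`.
#' @export
closeness_centrality <- function(net) {
  n <- length(net$members)
  if (n < 2) stop("closeness centrality needs at least 2 nodes")
  g <- .as_igraph(net)
  d <- igraph::distances(g)
  out <- vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (!length(dv)) return(0)
    (length(dv) / sum(dv)) * (length(dv) / (n - 1))
  }, numeric(1))
  stats::setNames(out, net$members)
}

#' Eigenvector centrality
#'
#' Leading eigenvector of the adjacency matrix restricted to the largest
#' connected component; animals outside that component get 0. Entries are
#' non-negative and rescaled so the maximum is 1 (`scale = "max"`) or so the
#' vector has unit Euclidean norm (`scale = "l2"`).
#'
#' @inheritParams degree_centrality
#' @param scale rescaling convention, `"max"` (default) or `"l2"`.
#' @return named numeric vector; all zero (with a warning) for an edgeless
#'   pen.
#' @export
eigenvector_centrality <- function(net, scale = c("max", "l2")) {
  scale <- match.arg(scale)
  n <- length(net$members)
  out <- stats::setNames(numeric(n), net$members)
  if (sum(net$adjacency) == 0) {
    warning("edgeless network: eigenvector centrality undefined, returning 0")
    return(out)
  }
  g <- .as_igraph(net)
  comp <- igraph::components(g)
  main <- which.max(comp$csize)  # ties: first component
  keep <- which(comp$membership == main)
  sub <- igraph::induced_subgraph(g, keep)
  v <- igraph::eigen_centrality(sub)$vector  # scaled so max entry is 1
  v <- abs(v)  # sign is arbitrary; Perron vector is non-negative
  if (scale == "l2") v <- v / sqrt(sum(v^2))
  out[keep] <- v
  out
}

#' Local clustering coefficient
#'
#' Proportion of an animal's interaction partners that also interacted with
#' each other: `2 T_i / (k_i (k_i - 1))` with `T_i` the number of triangles
#' through node `i`. Animals with fewer than two partners get 0 so that every
#' animal stays phenotyped.
#'
#' @inheritParams degree_centrality
#' @return named numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  g <- .as_igraph(net)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0  # degree-1 nodes
  stats::setNames(cc, net$members)
}

#' Maximum-clique membership
#'
#' Flags animals belonging to at least one largest fully connected subgroup
#' of the pen. For an edgeless pen the largest cliques are the single
#' animals, so everyone is a member (flagged degenerate via the attribute).
#'
#' @inheritParams degree_centrality
#' @return named integer vector of 0/1 with attribute `"max_clique_size"`.
#' @export
clique_membership <- function(net) {
  g <- .as_igraph(net)
  cl <- igraph::largest_cliques(g)
  size <- if (length(cl)) length(cl[[1]]) else 1L
  member <- stats::setNames(integer(length(net$members)), net$members)
  for (cc in cl) member[as.integer(cc)] <- 1L
  attr(member, "max_clique_size") <- as.integer(size)
  member
}

#' Dichotomise betweenness into high/low categories
#'
#' Animals at or above the 75th percentile of the population-wide
#' betweenness distribution are `high`; the rest are `low`. Ties at the cut
#' are all high; a constant vector therefore makes everyone high (degenerate,
#' warned).
#'
#' @param values numeric vector of betweenness values for the whole
#'   population (not per pen).
#' @param prob quantile defining the top group; default 0.75 (top quartile).
#' @return factor with levels `low`, `high` and attribute `"cutoff"`.
#' @export
categorize_betweenness <- function(values, prob = 0.75) {
  if (length(values) < 4) stop("need at least 4 values to form quartiles")
  cut <- stats::quantile(values, prob, names = FALSE)
  high <- values >= cut
  if (all(high)) warning("all betweenness values tied: everyone is 'high'")
  structure(factor(ifelse(high, "high", "low"), levels = c("low", "high")),
            cutoff = cut)
}

#' Per-animal network traits for every pen
#'
#' Builds each pen's combined fight + bullying network and computes the full
#' set of node traits: raw and normalised degree, betweenness, closeness,
#' eigenvector centrality, local clustering coefficient, maximum-clique
#' membership and the population-wide high/low betweenness category.
#'
#' @param interactions data frame of interaction records with columns
#'   `pen_id`, `initiator_id`, `receiver_id` (plus ignored `kind`,
#'   `duration`).
#' @param assignment pen assignment data frame with columns `animal_id`,
#'   `pen_id`.
#' @param eigen_scale passed to [eigenvector_centrality()].
#' @return data frame with one row per penned animal.
#' @export
pen_sna_traits <- function(interactions, assignment, eigen_scale = "max") {
  stopifnot(all(c("animal_id", "pen_id") %in% names(assignment)))
  res <- lapply(split(assignment, assignment$pen_id), function(pen) {
    recs <- interactions[interactions$pen_id == pen$pen_id[1], , drop = FALSE]
    net <- build_pen_network(recs, pen$animal_id, pen_id = pen$pen_id[1])
    deg <- degree_centrality(net)
    cli <- clique_membership(net)
    data.frame(animal_id = pen$animal_id,
               pen_id = pen$pen_id[1],
               degree_raw = as.integer(attr(deg, "raw")[as.character(pen$animal_id)]),
               degree = as.numeric(deg[as.character(pen$animal_id)]),
               betweenness = as.numeric(betweenness_centrality(net)[as.character(pen$animal_id)]),
               closeness = as.numeric(closeness_centrality(net)[as.character(pen$animal_id)]),
               eigenvector = as.numeric(
                 suppressWarnings(eigenvector_centrality(net, eigen_scale))[as.character(pen$animal_id)]),
               clustering = as.numeric(clustering_coefficient(net)[as.character(pen$animal_id)]),
               clique_member = as.integer(cli[as.character(pen$animal_id)]),
               max_clique_size = attr(cli, "max_clique_size"))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$betweenness_cat <- categorize_betweenness(out$betweenness)
  out
}
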