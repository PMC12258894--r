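#' Group atoms into residue nodes
#'
#' Builds the node bookkeeping used by the network stage: one node per
#' residue (keyed chain:resid), with its Ca atom index and the indices of
#' its heavy atoms.
#'
#' @param atoms an \code{\link{atom_table}}.
#' @param idx optional subset of atom rows to consider (default all).
#' @return data.frame-like list of class \code{"residue_nodes"}: node
#'   \code{labels}, \code{ca_idx}, and \code{heavy} (list of heavy-atom
#'   indices per node), \code{residue_id}, \code{chain_id}.
#' @export
residue_nodes <- function(atoms, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(atoms))
  key <- paste(atoms$chain_id[idx], atoms$residue_id[idx], sep = ":")
  uk <- unique(key)
  ca <- integer(length(uk)); heavy <- vector("list", length(uk))
  for (i in seq_along(uk)) {
    rows <- idx[key == uk[i]]
    cai <- rows[atoms$atom_name[rows] == "CA"]
    if (!length(cai)) stop("node ", uk[i], " has no CA atom")
    ca[i] <- cai[1]
    heavy[[i]] <- rows[toupper(atoms$element[rows]) != "H"]
  }
  structure(list(labels = uk, ca_idx = ca, heavy = heavy,
                 residue_id = atoms$residue_id[ca],
                 chain_id = atoms$chain_id[ca]),
            class = "residue_nodes")
}

#' Normalized covariance (correlation) of node fluctuations
#'
#' \deqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#'   \sqrt{\langle \Delta r_i^2 \rangle \langle \Delta r_j^2 \rangle}}
#' with \eqn{\Delta r} the 3-D displacement of a node (Ca) from its
#' trajectory-mean position; dot products are over the full 3-D
#' displacement vectors.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param node_idx atom indices of the node positions (one per node).
#' @return symmetric matrix with unit diagonal, class
#'   \code{"correlation_matrix"}.
#' @export
correlation_matrix <- function(traj, node_idx) {
  if (n_frames(traj) < 2) stop("need at least 2 frames")
  raw <- matrix(0, length(node_idx), length(node_idx))
  for (ax in 1:3) {
    x <- matrix(traj$coords[, node_idx, ax], nrow = n_frames(traj))
    x <- sweep(x, 2, colMeans(x))
    raw <- raw + crossprod(x)
  }
  v <- diag(raw)
  if (any(v <= 1e-300)) {
    bad <- which(v <= 1e-300)
    stop("zero-variance node(s): ", paste(bad, collapse = ","))
  }
  C <- raw / sqrt(outer(v, v))
  diag(C) <- 1
  structure(C, class = c("correlation_matrix", "matrix", "array"))
}

#' Residue contact map from a trajectory
#'
#' Two residues are in contact when their minimum heavy-atom distance is
#' within the cutoff in at least an occupancy fraction of frames.
#' Sequence neighbors up to \code{neighbor_exclusion} apart (same chain)
#' are excluded to avoid trivial backbone edges; set it to 0 to keep
#' them.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param nodes a \code{\link{residue_nodes}} object.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 5).
#' @param occupancy minimum fraction of frames (default 0.75).
#' @param neighbor_exclusion residue-offset exclusion (default 1).
#' @return logical symmetric matrix of class \code{"contact_map"}, with
#'   attribute \code{occupancy_matrix} (fraction of frames in contact).
#' @export
contact_map <- function(traj, nodes, cutoff = 5, occupancy = 0.75,
                        neighbor_exclusion = 1) {
  n <- length(nodes$labels)
  nf <- n_frames(traj)
  occ <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    hi <- nodes$heavy[[i]]; hj <- nodes$heavy[[j]]
    hits <- 0L
    for (f in seq_len(nf)) {
      xyz <- frame_coords(traj, f)
      d2 <- outer(rowSums(xyz[hi, , drop = FALSE]^2),
                  rowSums(xyz[hj, , drop = FALSE]^2), "+") -
        2 * xyz[hi, , drop = FALSE] %*% t(xyz[hj, , drop = FALSE])
      if (min(d2) <= cutoff^2) hits <- hits + 1L
    }
    occ[i, j] <- occ[j, i] <- hits / nf
  }
  cm <- occ >= occupancy
  if (neighbor_exclusion > 0) {
    same_chain <- outer(nodes$chain_id, nodes$chain_id, "==")
    close_seq <- abs(outer(nodes$residue_id, nodes$residue_id, "-")) <=
      neighbor_exclusion
    cm[same_chain & close_seq] <- FALSE
  }
  diag(cm) <- FALSE
  attr(cm, "occupancy_matrix") <- occ
  class(cm) <- c("contact_map", "matrix", "array")
  cm
}

#' Build a correlation-weighted residue network
#'
#' Contact edges are weighted as \eqn{w_{ij} = -\ln |C_{ij}|}; taking the
#' magnitude follows the established dynamic-network convention so
#' anti-correlated pairs still carry a finite weight, and natural log
#' only rescales path lengths without changing their ranking. Edges with
#' C exactly 0 are dropped with a warning (infinite weight).
#'
#' @param contacts a \code{\link{contact_map}} (or logical matrix).
#' @param C a \code{\link{correlation_matrix}} (or numeric matrix).
#' @param labels optional node labels.
#' @return list of class \code{"weighted_network"}: \code{n},
#'   \code{edges} (data.frame i, j, w, cij), adjacency weight matrix
#'   \code{w} (Inf where no edge), \code{strength} (|C| on edges), and
#'   \code{labels}.
#' @export
build_network <- function(contacts, C, labels = NULL) {
  contacts <- unclass(contacts); C <- unclass(C)
  if (!all(dim(contacts) == dim(C)))
    stop("contact map and correlation matrix dimensions differ")
  n <- nrow(C)
  if (any(contacts) && max(abs(C[contacts])) > 1 + 1e-8)
    stop("|C| > 1 beyond tolerance on a contact edge")
  ut <- which(contacts & upper.tri(contacts), arr.ind = TRUE)
  cij <- C[ut]
  zero <- abs(cij) < 1e-300
  if (any(zero)) {
    warning(sum(zero), " contact edge(s) dropped: C_ij = 0")
    ut <- ut[!zero, , drop = FALSE]; cij <- cij[!zero]
  }
  w <- -log(pmin(abs(cij), 1))
  wm <- matrix(Inf, n, n)
  wm[ut] <- w; wm[ut[, c(2, 1), drop = FALSE]] <- w
  diag(wm) <- 0
  sm <- matrix(0, n, n)
  sm[ut] <- abs(cij); sm[ut[, c(2, 1), drop = FALSE]] <- abs(cij)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  structure(list(n = n,
                 edges = data.frame(i = ut[, 1], j = ut[, 2], w = w,
                                    cij = cij),
                 w = wm, strength = sm, labels = labels),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %d nodes, %d edges\n", x$n,
              nrow(x$edges)))
  invisible(x)
}

# all-pairs shortest path lengths, Floyd-Warshall on the weight matrix
.floyd_warshall <- function(wm) {
  n <- nrow(wm)
  D <- wm
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# lexicographically smallest shortest path from s to t given distances to t
.reconstruct_path <- function(wm, D, s, t) {
  path <- s; cur <- s
  tol <- 1e-10 * max(1, D[s, t])
  while (cur != t) {
    nbr <- which(is.finite(wm[cur, ]) & seq_len(ncol(wm)) != cur)
    ok <- nbr[abs(wm[cur, nbr] + D[nbr, t] - D[cur, t]) <= tol]
    ok <- setdiff(ok, path)              # keep the path simple
    if (!length(ok)) stop("path reconstruction failed")
    cur <- min(ok)                       # deterministic lexicographic pick
    path <- c(path, cur)
  }
  path
}

#' Optimal (shortest) coupling path between two nodes
#'
#' All-pairs shortest path lengths by Floyd-Warshall on the
#' \eqn{-\ln|C|} edge weights; the returned node sequence is the
#' lexicographically smallest among equally short paths.
#'
#' @param net a \code{\link{weighted_network}}.
#' @param source,sink node indices (or labels).
#' @return list of class \code{"path_set"} with the \code{optimal} path
#'   (\code{nodes}, \code{length}), all-pairs distance matrix \code{D},
#'   and empty \code{suboptimal} slot.
#' @export
optimal_path <- function(net, source, sink) {
  s <- .node_index(net, source); t <- .node_index(net, sink)
  if (s == t) stop("source and sink must differ")
  D <- .floyd_warshall(net$w)
  if (!is.finite(D[s, t])) stop("sink unreachable from source")
  nodes <- .reconstruct_path(net$w, D, s, t)
  structure(list(source = s, sink = t,
                 optimal = list(nodes = nodes, length = D[s, t]),
                 suboptimal = NULL, tolerance = NULL, D = D,
                 labels = net$labels),
            class = "path_set")
}

.node_index <- function(net, x) {
  if (is.character(x)) {
    i <- match(x, net$labels)
    if (is.na(i)) stop("unknown node label: ", x)
    i
  } else as.integer(x)
}

#' Suboptimal coupling paths within a length tolerance
#'
#' Enumerates all simple paths whose length is strictly below
#' (1 + tolerance) times the optimal length, by depth-first search with
#' branch-and-bound pruning against the Floyd-Warshall distance-to-sink
#' lower bound. Paths at exactly the boundary are excluded (strict
#' inequality). Results are sorted by length, ties broken
#' lexicographically.
#'
#' @param net a \code{\link{weighted_network}}.
#' @param source,sink node indices or labels.
#' @param tolerance fractional tolerance (default 0.5).
#' @param cap maximum number of paths to return (default 1000); hitting
#'   the cap sets \code{truncated = TRUE}.
#' @return a \code{"path_set"} with \code{suboptimal} filled in (a list
#'   of \code{nodes}/\code{length} entries, optimal path first).
#' @export
suboptimal_paths <- function(net, source, sink, tolerance = 0.5,
                             cap = 1000) {
  ps <- optimal_path(net, source, sink)
  s <- ps$source; t <- ps$sink; D <- ps$D
  bound <- (1 + tolerance) * ps$optimal$length
  eps <- 1e-9 * max(1, bound)
  found <- list(); nfound <- 0L; truncated <- FALSE
  visit <- function(path, len) {
    if (truncated) return()
    cur <- path[length(path)]
    if (cur == t) {
      if (nfound >= cap) { truncated <<- TRUE; return() }
      nfound <<- nfound + 1L
      found[[nfound]] <<- list(nodes = path, length = len)
      return()
    }
    nbr <- which(is.finite(net$w[cur, ]) & seq_len(net$n) != cur)
    nbr <- setdiff(nbr, path)
    for (v in sort(nbr)) {
      nl <- len + net$w[cur, v]
      if (nl + D[v, t] < bound - eps) visit(c(path, v), nl)
    }
  }
  visit(s, 0)
  ord <- order(vapply(found, `[[`, numeric(1), "length"),
               vapply(found, function(p)
                 paste(sprintf("%06d", p$nodes), collapse = ","),
                 character(1)))
  ps$suboptimal <- found[ord]
  ps$tolerance <- tolerance
  ps$truncated <- truncated
  ps
}

#' @export
print.path_set <- function(x, ...) {
  fmt <- function(p) paste(x$labels[p$nodes], collapse = " - ")
  cat(sprintf("<path_set> %s -> %s\n optimal (length %.4f): %s\n",
              x$labels[x$source], x$labels[x$sink],
              x$optimal$length, fmt(x$optimal)))
  if (!is.null(x$suboptimal))
    cat(sprintf(" %d path(s) within %.0f%% tolerance%s\n",
                length(x$suboptimal), 100 * x$tolerance,
                if (isTRUE(x$truncated)) " (truncated)" else ""))
  invisible(x)
}

#' Dynamic communities by divisive edge-betweenness clustering
#'
#' Girvan-Newman procedure on the weighted network: edge betweenness is
#' computed with the \eqn{-\ln|C|} weights as distances, the
#' highest-betweenness edge is removed (ties broken by smallest (i, j)),
#' and the partition sequence is scored by modularity computed with
#' \eqn{|C|} edge strengths; the maximum-modularity partition is
#' returned. A connected graph scores 0 as a single community, so a
#' clique is never split.
#'
#' @param net a \code{\link{weighted_network}}.
#' @return list of class \code{"community_partition"}: \code{membership}
#'   (integer vector), \code{modularity}, \code{n_communities}.
#' @export
communities <- function(net) {
  if (nrow(net$edges) == 0) stop("empty network")
  g_full <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$i, to = net$edges$j),
    directed = FALSE, vertices = data.frame(name = seq_len(net$n)))
  strength <- exp(-net$edges$w)          # |C| on each edge
  g <- g_full
  igraph::E(g)$dist <- net$edges$w
  igraph::E(g)$id <- seq_len(nrow(net$edges))
  best <- NULL; best_q <- -Inf
  repeat {
    memb <- igraph::components(g)$membership
    q <- igraph::modularity(g_full, memb, weights = strength)
    if (q > best_q + 1e-12) { best_q <- q; best <- memb }
    if (igraph::ecount(g) == 0) break
    eb <- igraph::edge_betweenness(g, weights = igraph::E(g)$dist)
    cand <- which(abs(eb - max(eb)) < 1e-9)
    drop <- cand[which.min(igraph::E(g)$id[cand])]
    g <- igraph::delete_edges(g, drop)
  }
  structure(list(membership = as.integer(best), modularity = best_q,
                 n_communities = length(unique(best)),
                 labels = net$labels),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, modularity %.4f\n",
              x$n_communities, x$modularity))
  invisible(x)
}
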