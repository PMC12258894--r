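#' Fluctuation magnitude series of a node
#'
#' Per frame, the scalar distance of a node from its equilibrium
#' (trajectory-mean) position, x_t = |r_t - <r>|. This is the sample the
#' fluctuation-density entropies are estimated from.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param node_idx a single atom index.
#' @return numeric vector of distances (Angstrom), length n_frames.
#' @export
fluctuation_series <- function(traj, node_idx) {
  if (n_frames(traj) < 2) stop("need at least 2 frames")
  xyz <- matrix(traj$coords[, node_idx, ], ncol = 3)
  mu <- colMeans(xyz)
  sqrt(rowSums(sweep(xyz, 2, mu)^2))
}

#' Differential entropy by Gaussian-mixture density estimation
#'
#' Fits Gaussian mixture models with 1 to \code{max_components}
#' components (BIC selection, via \pkg{mclust}) to the samples and
#' returns the plug-in entropy
#' \deqn{H = -\frac{1}{N} \sum_n \ln \hat\rho(x_n)} in nats.
#' Works for 1-D samples (vectors) and multi-D samples (matrices, one
#' row per observation) alike; the 2-D case is used for joint entropies.
#'
#' @param samples numeric vector or matrix of samples (>= 50).
#' @param max_components maximum mixture size (default 5).
#' @param seed seed fixed before fitting for reproducibility.
#' @return list of class \code{"entropy_estimate"}: \code{H} (nats),
#'   \code{n_components}, \code{n}, and the fitted \code{model}.
#' @export
gmm_entropy <- function(samples, max_components = 5, seed = 42) {
  x <- if (is.matrix(samples)) samples else as.numeric(samples)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n < 50) stop("need at least 50 samples")
  rng <- if (is.matrix(x)) max(apply(x, 2, function(c) diff(range(c))))
    else diff(range(x))
  if (rng < 1e-12)
    stop("degenerate samples (all equal): differential entropy is -Inf")
  set.seed(seed)
  fit <- mclust::densityMclust(x, G = seq_len(max_components),
                               plot = FALSE, verbose = FALSE)
  dens <- pmax(stats::predict(fit, x), 1e-300)
  structure(list(H = -mean(log(dens)), n_components = fit$G, n = n,
                 model = fit),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("<entropy_estimate> H = %.4f nats (%d components, n = %d)\n",
              x$H, x$n_components, x$n))
  invisible(x)
}

#' Mutual information between two fluctuation series
#'
#' \eqn{M_{ij} = H_i + H_j - H_{ij}} with all three entropies estimated
#' by GMM density fits (the joint by a 2-D mixture on paired samples).
#' Small negative estimates (a finite-sample artifact) are clamped to 0
#' and flagged; exactly dependent series would have divergent continuous
#' MI and return the configured saturation value with a degeneracy flag.
#'
#' @param series_i,series_j numeric vectors of equal length.
#' @param max_components maximum mixture size.
#' @param saturation value reported for degenerate (deterministically
#'   related) pairs (default 10 nats).
#' @param seed fitting seed.
#' @return list of class \code{"mi_estimate"}: \code{M} (nats), flags
#'   \code{clamped} and \code{degenerate}, and the component entropies.
#' @export
mutual_information <- function(series_i, series_j, max_components = 5,
                               saturation = 10, seed = 42) {
  if (length(series_i) != length(series_j))
    stop("series lengths differ: ", length(series_i), " vs ",
         length(series_j))
  r <- suppressWarnings(stats::cor(series_i, series_j))
  if (is.finite(r) && abs(r) > 1 - 1e-10)
    return(structure(list(M = saturation, clamped = FALSE,
                          degenerate = TRUE, Hi = NA, Hj = NA, Hij = NA),
                     class = "mi_estimate"))
  Hi <- gmm_entropy(series_i, max_components, seed = seed)$H
  Hj <- gmm_entropy(series_j, max_components, seed = seed)$H
  Hij <- gmm_entropy(cbind(series_i, series_j), max_components,
                     seed = seed)$H
  M <- Hi + Hj - Hij
  clamped <- M < 0
  structure(list(M = max(M, 0), clamped = clamped, degenerate = FALSE,
                 Hi = Hi, Hj = Hj, Hij = Hij),
            class = "mi_estimate")
}

#' Pairwise mutual-information matrix over contact pairs
#'
#' Computes \eqn{M_{ij}} for every pair in contact (skipping pairs that
#' cannot carry a network edge keeps the cost linear in the edge count).
#'
#' @param traj a \code{\link{trajectory}}.
#' @param node_idx atom indices of the nodes.
#' @param contacts logical contact matrix (\code{NULL} computes all
#'   pairs).
#' @param ... passed to \code{\link{mutual_information}}.
#' @return symmetric numeric matrix (nats) with zero diagonal and
#'   attribute \code{n_clamped}.
#' @export
mi_matrix <- function(traj, node_idx, contacts = NULL, ...) {
  n <- length(node_idx)
  series <- lapply(node_idx, function(k) fluctuation_series(traj, k))
  M <- matrix(0, n, n)
  nclamp <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.null(contacts) && !contacts[i, j]) next
    mi <- mutual_information(series[[i]], series[[j]], ...)
    M[i, j] <- M[j, i] <- mi$M
    nclamp <- nclamp + mi$clamped
  }
  attr(M, "n_clamped") <- nclamp
  M
}

#' Build an information-flow network
#'
#' Masks the mutual-information matrix by the boolean contact map,
#' \eqn{A_{ij} = C_{ij} M_{ij}}, and forms the degree matrix and graph
#' Laplacian \eqn{L = D - A} (row sums of L are zero by construction).
#'
#' @param contacts logical contact matrix.
#' @param M symmetric mutual-information matrix (nats).
#' @return list of class \code{"flow_network"}: \code{A}, \code{D},
#'   \code{L}, \code{n}.
#' @export
flow_network <- function(contacts, M) {
  contacts <- unclass(contacts)
  if (!all(dim(contacts) == dim(M)))
    stop("contact map and MI matrix dimensions differ")
  A <- unclass(M) * (contacts * 1)
  diag(A) <- 0
  D <- diag(rowSums(A))
  structure(list(A = A, D = D, L = D - A, n = nrow(A)),
            class = "flow_network")
}

#' Information flow through each node for a source/sink pair
#'
#' Solves the current-flow problem on the MI-weighted contact network:
#' the reduced Laplacian (sink rows/columns removed) against a supply of
#' one unit entering at the source, sinks held at potential zero, then
#' \deqn{f_i = \tfrac{1}{2} \sum_j |P_i - P_j| A_{ij}.}
#' By conservation the flow through a sole source (and sole sink) is
#' exactly 0.5: half of the unit current is attributed to each endpoint
#' node. Kirchhoff balance (unit net current out of the source) is
#' checked to 1e-10 and reported.
#'
#' @param fn a \code{\link{flow_network}}.
#' @param source a single source node index.
#' @param sinks one or more sink node indices.
#' @return list of class \code{"flow_result"}: potentials \code{P}, flow
#'   \code{f}, \code{source}, \code{sinks}, and the Kirchhoff residual
#'   \code{balance_error}.
#' @export
information_flow <- function(fn, source, sinks) {
  stopifnot(inherits(fn, "flow_network"))
  source <- as.integer(source); sinks <- as.integer(sinks)
  if (source %in% sinks) stop("source must not be a sink")
  adj <- unname((fn$A > 0) * 1)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    adj, mode = "undirected"))$membership
  if (any(comp[sinks] != comp[source]))
    stop("source and sink(s) are not in one connected component")
  keep <- setdiff(seq_len(fn$n), sinks)
  Lr <- fn$L[keep, keep, drop = FALSE]
  b <- numeric(length(keep))
  b[match(source, keep)] <- 1
  P <- numeric(fn$n)
  sol <- tryCatch(solve(Lr, b),
                  error = function(e) stop("singular reduced Laplacian: ",
                                           conditionMessage(e)))
  P[keep] <- sol
  pd <- outer(P, P, "-")
  f <- 0.5 * rowSums(abs(pd) * fn$A)
  out_source <- sum(pd[source, ] * fn$A[source, ])
  structure(list(P = P, f = f, source = source, sinks = sinks,
                 balance_error = abs(out_source - 1)),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf(
    "<flow_result> source %d -> sink(s) %s; f range [%.4f, %.4f]\n",
    x$source, paste(x$sinks, collapse = ","), min(x$f), max(x$f)))
  invisible(x)
}
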