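# Shared fixtures and independent oracles for the test suite.

# trajectory holding the same frame n times
static_traj <- function(coords, n_frames = 3, box = NULL) {
  arr <- array(NA_real_, dim = c(n_frames, nrow(coords), 3))
  for (i in seq_len(n_frames)) arr[i, , ] <- coords
  trajectory(arr, box = box)
}

# random connected weighted network: correlations in (0.2, 0.95) on a
# random sparse contact graph, returned as a built weighted_network
random_network <- function(n, mean_degree = 3, seed = 1) {
  set.seed(seed)
  repeat {
    p <- min(0.9, mean_degree / (n - 1))
    ct <- matrix(FALSE, n, n)
    ct[upper.tri(ct)] <- stats::runif(n * (n - 1) / 2) < p
    ct <- ct | t(ct)
    g <- igraph::graph_from_adjacency_matrix(ct * 1, mode = "undirected")
    if (igraph::is_connected(g)) break
  }
  C <- matrix(0, n, n)
  C[upper.tri(C)] <- stats::runif(n * (n - 1) / 2, 0.2, 0.95)
  C <- C + t(C); diag(C) <- 1
  build_network(ct, C)
}

# exhaustive enumeration of all simple paths s -> t with lengths
enumerate_paths <- function(wm, s, t) {
  n <- nrow(wm)
  out <- list()
  walk <- function(path, len) {
    cur <- path[length(path)]
    if (cur == t) {
      out[[length(out) + 1L]] <<- list(nodes = path, length = len)
      return()
    }
    for (v in seq_len(n)) {
      if (v %in% path || !is.finite(wm[cur, v]) || v == cur) next
      walk(c(path, v), len + wm[cur, v])
    }
  }
  walk(s, 0)
  out
}

# independent permeation oracle: explicit two-state boundary automaton,
# written as a direct transcription of the definition
permeation_oracle <- function(zt, lo, hi) {
  side <- function(z) if (z < lo) "below" else if (z >= hi) "above" else "in"
  up <- 0L; down <- 0L
  entered_from <- NULL
  prev <- side(zt[1])
  for (z in zt[-1]) {
    cur <- side(z)
    if (cur == prev) next
    if (prev != "in" && cur == "in") entered_from <- prev
    if (cur != "in" && prev == "in") {
      if (!is.null(entered_from) && cur != entered_from) {
        if (cur == "above") up <- up + 1L else down <- down + 1L
      }
      entered_from <- NULL
    }
    if (prev == "below" && cur == "above") { up <- up + 1L
      entered_from <- NULL }
    if (prev == "above" && cur == "below") { down <- down + 1L
      entered_from <- NULL }
    prev <- cur
  }
  c(up = up, down = down)
}

# brute-force optimal-superposition RMSD by scanning Euler angles with
# local refinement (independent of the Kabsch route)
bruteforce_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  rmsd_of <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3,
                  byrow = TRUE)
    d <- bc %*% t(Rz1 %*% Ry %*% Rz2) - ac
    sqrt(mean(rowSums(d^2)))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, by = pi / 18),
                      b = seq(0, pi, by = pi / 18),
                      g = seq(0, 2 * pi, by = pi / 18))
  vals <- apply(grid, 1, rmsd_of)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, rmsd_of, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  opt$value
}
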