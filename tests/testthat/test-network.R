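test_that("correlation matrix has unit diagonal and catches sign", {
  set.seed(1)
  n <- 200
  x <- rnorm(n)
  arr <- array(0, dim = c(n, 2, 3))
  arr[, 1, 1] <- x; arr[, 2, 1] <- -x  # exactly opposite motion
  C <- correlation_matrix(trajectory(arr), 1:2)
  expect_equal(diag(C), c(1, 1))
  expect_equal(C[1, 2], -1)
  static <- array(1, dim = c(5, 2, 3))
  expect_error(correlation_matrix(trajectory(static), 1:2),
               "zero-variance")
})

test_that("contact occupancy thresholds are honored exactly", {
  at <- atom_table(1:2, "CA", 1:2, "GLY", element = "C")
  nodes <- residue_nodes(at)
  # 10 frames: pair within 5 A in exactly 7 of them
  arr <- array(0, dim = c(10, 2, 3))
  arr[, 2, 1] <- c(rep(4.2, 7), rep(6.5, 3))
  tr <- trajectory(arr)
  cm70 <- contact_map(tr, nodes, occupancy = 0.75,
                      neighbor_exclusion = 0)
  expect_false(cm70[1, 2])
  cm65 <- contact_map(tr, nodes, occupancy = 0.65,
                      neighbor_exclusion = 0)
  expect_true(cm65[1, 2])
  expect_equal(attr(cm65, "occupancy_matrix")[1, 2], 0.7)
  # neighbor exclusion removes sequence-adjacent pairs
  cmx <- contact_map(tr, nodes, occupancy = 0.65, neighbor_exclusion = 1)
  expect_false(cmx[1, 2])
})

test_that("contact map equals a brute-force per-frame recount", {
  set.seed(3)
  nres <- 4; nat <- 3
  at <- atom_table(seq_len(nres * nat),
                   rep(c("CA", "CB", "CG"), nres),
                   rep(seq_len(nres), each = nat), "GLY", element = "C")
  nodes <- residue_nodes(at)
  arr <- array(rnorm(8 * nres * nat * 3, sd = 4), dim = c(8, nres * nat, 3))
  tr <- trajectory(arr)
  cm <- contact_map(tr, nodes, cutoff = 5, occupancy = 0.5,
                    neighbor_exclusion = 0)
  for (i in 1:(nres - 1)) for (j in (i + 1):nres) {
    hits <- 0
    for (f in 1:8) {
      dmin <- Inf
      for (a in nodes$heavy[[i]]) for (b in nodes$heavy[[j]])
        dmin <- min(dmin, sqrt(sum((arr[f, a, ] - arr[f, b, ])^2)))
      if (dmin <= 5) hits <- hits + 1
    }
    expect_identical(unclass(cm)[i, j], hits / 8 >= 0.5)
  }
})

test_that("edge weights are -log |C| on contact edges only", {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 1
  C[2, 3] <- C[3, 2] <- 0.5
  C[1, 3] <- C[3, 1] <- 0.9
  ct <- matrix(c(FALSE, TRUE, FALSE,
                 TRUE, FALSE, TRUE,
                 FALSE, TRUE, FALSE), 3)
  net <- build_network(ct, C)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$w[1, 2], 0)
  expect_equal(net$w[2, 3], 0.6931, tolerance = 1e-4)
  expect_false(is.finite(net$w[1, 3]))  # no contact, no edge
  # anti-correlation gets a finite weight through |C|
  C[2, 3] <- C[3, 2] <- -0.5
  net2 <- build_network(ct, C)
  expect_equal(net2$w[2, 3], net$w[2, 3])
})

test_that("triangle optimal path goes through the cheap relay", {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- exp(-1)
  C[2, 3] <- C[3, 2] <- exp(-1)
  C[1, 3] <- C[3, 1] <- exp(-3)
  ct <- matrix(TRUE, 3, 3); diag(ct) <- FALSE
  net <- build_network(ct, C)
  ps <- optimal_path(net, 1, 3)
  expect_equal(ps$optimal$nodes, c(1, 2, 3))
  expect_equal(ps$optimal$length, 2.0)
  expect_equal(optimal_path(net, 3, 1)$optimal$length, 2.0)
  # the direct edge sits exactly at 1.5 x optimal: strictly excluded
  sp <- suboptimal_paths(net, 1, 3, tolerance = 0.5)
  expect_length(sp$suboptimal, 1)
  expect_equal(sp$suboptimal[[1]]$nodes, c(1, 2, 3))
  # wider tolerance admits it; the suboptimal set is monotone
  sp2 <- suboptimal_paths(net, 1, 3, tolerance = 0.51)
  expect_length(sp2$suboptimal, 2)
})

test_that("path lengths and suboptimal sets match exhaustive search", {
  for (seed in 1:25) {
    n <- sample(4:10, 1)
    net <- random_network(n, mean_degree = 3, seed = seed)
    st <- sample(n, 2)
    s <- st[1]; t <- st[2]
    all_paths <- enumerate_paths(net$w, s, t)
    lens <- vapply(all_paths, `[[`, numeric(1), "length")
    ps <- suboptimal_paths(net, s, t, tolerance = 0.5)
    expect_equal(ps$optimal$length, min(lens), tolerance = 1e-12)
    bound <- 1.5 * min(lens)
    keep <- which(lens < bound - 1e-9 * max(1, bound))
    got_lens <- vapply(ps$suboptimal, `[[`, numeric(1), "length")
    expect_equal(sort(got_lens), sort(lens[keep]), tolerance = 1e-12)
    got_keys <- sort(vapply(ps$suboptimal, function(p)
      paste(p$nodes, collapse = "-"), character(1)))
    exp_keys <- sort(vapply(all_paths[keep], function(p)
      paste(p$nodes, collapse = "-"), character(1)))
    expect_identical(got_keys, exp_keys)
    # symmetry of the optimal length
    expect_equal(optimal_path(net, t, s)$optimal$length,
                 ps$optimal$length, tolerance = 1e-12)
  }
})

test_that("node relabeling permutes paths consistently", {
  net <- random_network(7, mean_degree = 3, seed = 99)
  perm <- sample(7)
  wm <- matrix(Inf, 7, 7); diag(wm) <- 0
  C <- diag(7); ct <- matrix(FALSE, 7, 7)
  for (e in seq_len(nrow(net$edges))) {
    i <- perm[net$edges$i[e]]; j <- perm[net$edges$j[e]]
    ct[i, j] <- ct[j, i] <- TRUE
    C[i, j] <- C[j, i] <- net$edges$cij[e]
  }
  pnet <- build_network(ct, C)
  p1 <- optimal_path(net, 1, 7)
  p2 <- optimal_path(pnet, perm[1], perm[7])
  expect_equal(p2$optimal$length, p1$optimal$length, tolerance = 1e-12)
})

test_that("planted two-block ensembles are split at the bridge", {
  # two 8-node blocks of correlated motion, contact topology = two
  # cliques joined by one bridge edge; correlations are estimated from
  # the sampled ensemble, not taken from the planted matrix
  n <- 16
  C <- matrix(0.1, n, n)
  C[1:8, 1:8] <- 0.6; C[9:16, 9:16] <- 0.6
  diag(C) <- 1
  tr <- sample_harmonic_ensemble(matrix(0, n, 3), C, n_frames = 1e4,
                                 seed = 21)
  Chat <- correlation_matrix(tr, 1:n)
  ct <- matrix(FALSE, n, n)
  ct[1:8, 1:8] <- TRUE; ct[9:16, 9:16] <- TRUE
  ct[8, 9] <- ct[9, 8] <- TRUE
  diag(ct) <- FALSE
  part <- communities(build_network(ct, Chat))
  expect_equal(part$n_communities, 2)
  expect_length(unique(part$membership[1:8]), 1)
  expect_length(unique(part$membership[9:16]), 1)
  expect_false(part$membership[1] == part$membership[9])
  # a single clique stays one community
  full <- matrix(TRUE, n, n); diag(full) <- FALSE
  one <- communities(build_network(full,
                                   matrix(0.8, n, n) + 0.2 * diag(n)))
  expect_equal(one$n_communities, 1)
  expect_error(communities(build_network(matrix(FALSE, 2, 2), diag(2))),
               "empty network")
})
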