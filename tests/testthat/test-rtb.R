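chain_nodes <- function(n_per_chain, chains = "A") {
  xyz <- NULL; info <- NULL
  off <- 0
  for (ch in chains) {
    st <- make_zigzag_chain(n_per_chain)
    nd <- select_nodes(st)
    nd$info$chain <- ch
    xyz <- rbind(xyz, nd$xyz + off)
    info <- rbind(info, nd$info)
    off <- off + 50
  }
  new_node_set(xyz, info)
}

test_that("block partition follows size and chain-boundary rules", {
  nd <- chain_nodes(10)
  expect_equal(make_blocks(nd, 1), 1:10)
  b3 <- make_blocks(nd, 3)
  expect_equal(as.integer(table(b3)), c(3, 3, 3, 1))
  two <- chain_nodes(5, chains = c("A", "B"))
  b4 <- make_blocks(two, 4)
  expect_equal(length(unique(b4)), 4)            # blocks never span chains
  expect_equal(as.integer(table(b4)), c(4, 1, 4, 1))
})

test_that("hetero groups and lipid nodes get their own blocks", {
  prot <- chain_nodes(4)
  lip <- build_bilayer_slab(10, 10, 5, 8)
  both <- combine_nodes(prot, lip)
  b <- make_blocks(both, 2)
  expect_equal(length(unique(b[both$info$component == "lipid"])),
               n_nodes(lip))
  expect_equal(length(unique(b)), 2 + n_nodes(lip))
})

test_that("a single whole-molecule block leaves only the six rigid modes", {
  nd <- cloud_nodes(random_cloud(10, seed = 5, sd = 3))
  H <- hessian(build_network(nd, cutoff = 10))
  pr <- rtb_project(H, rep(1L, 10), nd)
  expect_equal(dim(pr$matrix), c(6, 6))
  expect_lt(max(abs(pr$matrix)), 1e-8)
})

test_that("one node per block reproduces the full spectrum exactly", {
  nd <- cloud_nodes(random_cloud(16, seed = 6, sd = 3))
  H <- hessian(build_network(nd, cutoff = 10))
  full <- solve_modes(H, nd)
  rtb <- solve_modes(H, nd, partition = seq_len(16))
  expect_equal(rtb$values, full$values, tolerance = 1e-8)
  expect_equal(rtb$n_zero, full$n_zero)
})

test_that("coarser blocks obey Rayleigh-Ritz interlacing", {
  nd <- chain_nodes(30)
  net <- suppressWarnings(build_network(nd, cutoff = 10))
  H <- hessian(net)
  full <- suppressWarnings(solve_modes(H, nd))
  for (bs in c(3, 5)) {
    rtb <- suppressWarnings(solve_modes(H, nd,
                                        partition = make_blocks(nd, bs)))
    nk <- length(rtb$values)
    expect_true(all(rtb$values - full$values[seq_len(nk)] > -1e-8))
  }
})

test_that("projection operator columns are orthonormal, including degenerate blocks", {
  # a 1-node block (3 dof) and a 2-node block (5 dof) alongside full blocks
  nd <- cloud_nodes(random_cloud(9, seed = 12, sd = 4))
  part <- c(1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L)
  H <- suppressWarnings(hessian(build_network(nd, cutoff = 12)))
  pr <- rtb_project(H, part, nd)
  PtP <- as.matrix(Matrix::t(pr$P) %*% pr$P)
  expect_equal(PtP, diag(ncol(PtP)), tolerance = 1e-10)
  expect_equal(ncol(pr$P), 3 + 5 + 6 + 6)
})

test_that("dumbbell closed form: five zeros and lambda = 2k", {
  m <- suppressWarnings(
    solve_modes(hessian(build_network(dumbbell_nodes(3), cutoff = 10)),
                dumbbell_nodes(3)))
  expect_equal(m$n_zero, 5)
  expect_equal(m$values[6], 2, tolerance = 1e-12)
  expect_equal(m$first_internal, 6)
})

test_that("internal eigenpairs satisfy the Hessian residual and orthonormality checks", {
  nd <- cloud_nodes(random_cloud(14, seed = 8, sd = 3))
  H <- as.matrix(hessian(build_network(nd, cutoff = 10)))
  m <- solve_modes(H, nd)
  U <- m$vectors
  expect_equal(crossprod(U), diag(ncol(U)), tolerance = 1e-8,
               ignore_attr = TRUE)
  lmax <- max(m$values)
  for (j in internal_modes(m)) {
    res <- sqrt(sum((H %*% U[, j] - m$values[j] * U[, j])^2))
    expect_lt(res / lmax, 1e-6)
  }
})

test_that("zigzag slow spectrum matches an independent dense eigensolve", {
  st <- make_zigzag_chain(30)
  nd <- select_nodes(st)
  net <- build_network(nd, cutoff = 8)
  H <- as.matrix(hessian(net))
  m <- suppressWarnings(solve_modes(H, nd))
  # oracle: base eigen on an independently assembled dense matrix
  oracle <- matrix(0, 90, 90)
  for (r in seq_len(nrow(net$springs))) {
    i <- net$springs$i[r]; j <- net$springs$j[r]
    dr <- nd$xyz[i, ] - nd$xyz[j, ]
    blk <- (net$k / sum(dr^2)) * outer(dr, dr)
    ri <- 3 * (i - 1) + 1:3; rj <- 3 * (j - 1) + 1:3
    oracle[ri, ri] <- oracle[ri, ri] + blk
    oracle[rj, rj] <- oracle[rj, rj] + blk
    oracle[ri, rj] <- oracle[ri, rj] - blk
    oracle[rj, ri] <- oracle[rj, ri] - blk
  }
  lam_o <- sort(eigen(oracle, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(max(abs(m$values - lam_o)), 1e-10)
})

test_that("relative frequencies are anchored at the first internal mode", {
  nd <- cloud_nodes(random_cloud(12, seed = 2, sd = 3))
  m <- solve_modes(hessian(build_network(nd, cutoff = 10)), nd)
  expect_equal(m$rel_freq[m$first_internal], 1)
  expect_true(all(diff(m$rel_freq[internal_modes(m)]) >= -1e-12))
  expect_equal(m$freq_cm1[m$first_internal], 2.5)
  tab <- mode_summary(m)
  expect_equal(tab$rel_freq, m$rel_freq)
})

test_that("mode matching recovers identity, permutations, and survives noise", {
  nd <- cloud_nodes(random_cloud(15, seed = 14, sd = 3))
  m <- solve_modes(hessian(build_network(nd, cutoff = 10)), nd)
  idx <- internal_modes(m, 5)
  self <- match_modes(m, m, nd, nd, modes_a = idx, modes_b = idx)
  expect_equal(self$mode_a, self$mode_b)
  expect_true(all(self$overlap > 1 - 1e-8))
  # permuted copy
  m2 <- m
  perm <- rev(idx)
  m2$vectors[, idx] <- m$vectors[, perm]
  mp <- match_modes(m, m2, nd, nd, modes_a = idx, modes_b = idx)
  expect_equal(mp$mode_b[match(idx, mp$mode_a)], perm)
  # perturbed coordinates
  xyz2 <- nd$xyz + withr::with_seed(31, matrix(rnorm(45, 0, 0.1), 15, 3))
  nd2 <- cloud_nodes(xyz2)
  mn <- solve_modes(hessian(build_network(nd2, cutoff = 10)), nd2)
  got <- match_modes(m, mn, nd, nd2, modes_a = m$first_internal,
                     modes_b = internal_modes(mn, 3))
  expect_equal(got$mode_a, m$first_internal)
  expect_gt(got$overlap, 0.9)
})

test_that("mode files serialize eigenvalues and vectors", {
  nd <- dumbbell_nodes(3)
  m <- suppressWarnings(solve_modes(hessian(build_network(nd, cutoff = 10)),
                                    nd))
  tf <- withr::local_tempfile(fileext = ".txt")
  write_modes(m, tf, modes = 6)
  lines <- readLines(tf)
  expect_match(lines[1], "^MODE 6 2")
  expect_equal(length(lines), 3)   # header + 2 node rows
})
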