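#' Partition nodes into rotation-translation blocks
#'
#' Blocks are runs of consecutive residues within a chain; hetero groups
#' get one block per residue (heme, ligand) and lipid surrogate nodes one
#' block each. With one residue per block the RTB projection spans the full
#' space for C-alpha networks and the projected spectrum is exact.
#'
#' @param nodes a `node_set`.
#' @param residues_per_block integer >= 1.
#' @return integer vector of block indices, one per node.
#' @export
make_blocks <- function(nodes, residues_per_block = 1L) {
  if (residues_per_block < 1) stop("residues_per_block must be >= 1")
  info <- nodes$info
  n <- n_nodes(nodes)
  block <- integer(n)
  nb <- 0L
  is_poly <- !info$is_hetero & info$component == "protein"
  # polymer residues: consecutive runs within each chain
  for (ch in unique(info$chain[is_poly])) {
    ix <- which(is_poly & info$chain == ch)
    rk <- paste(info$resno[ix], info$insert[ix])
    res_of_node <- match(rk, unique(rk))           # residue ordinal in chain
    block[ix] <- nb + (res_of_node - 1L) %/% residues_per_block + 1L
    nb <- max(block[ix])
  }
  # hetero groups: one block per residue
  het <- which(!is_poly & info$component == "protein")
  if (length(het)) {
    rk <- paste(info$chain[het], info$resno[het], info$insert[het])
    block[het] <- nb + match(rk, unique(rk))
    nb <- max(block[het])
  }
  # lipid surrogate nodes: one block each
  lip <- which(info$component == "lipid")
  if (length(lip)) {
    block[lip] <- nb + seq_along(lip)
    nb <- max(block[lip])
  }
  if (any(block == 0L)) block[block == 0L] <- nb + seq_len(sum(block == 0L))
  block
}

# Orthonormal rigid-body basis (translations + rotations about the
# centroid) for one group of nodes; drops rank-deficient columns so a
# single node contributes 3 and a collinear pair 5 degrees of freedom.
rigid_basis <- function(xyz) {
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  rel <- sweep(xyz, 2, ctr)
  B <- matrix(0, 3 * n, 6)
  for (a in 1:3) B[seq(a, 3 * n, by = 3), a] <- 1       # translations
  axes <- diag(3)
  for (a in 1:3) {                                      # rotations
    cr <- t(apply(rel, 1, function(r) crossprod_vec(axes[a, ], r)))
    B[, 3 + a] <- as.numeric(t(cr))
  }
  qr_ <- qr(B)
  rank <- sum(abs(diag(qr_$qr)[seq_len(min(dim(B)))]) > 1e-8 * max(abs(B), 1))
  qr.Q(qr_)[, seq_len(rank), drop = FALSE]
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation-translation-block projection
#'
#' Builds the block projection operator P (up to six orthonormalized
#' rigid-body columns per block: three translations and three rotations
#' about the block centroid) and the projected Hessian P^T H P. By the
#' Rayleigh-Ritz principle the projected eigenvalues bound the full ones
#' from above; with one node or residue per block the projection is exact
#' for C-alpha networks.
#'
#' @param hess 3N x 3N Hessian (dense or sparse).
#' @param partition integer block index per node, from [make_blocks()].
#' @param nodes the `node_set` the Hessian was built from.
#' @return list with `matrix` (projected symmetric matrix) and `P`
#'   (3N x m sparse projection operator, orthonormal columns).
#' @export
rtb_project <- function(hess, partition, nodes) {
  n <- n_nodes(nodes)
  if (nrow(hess) != 3 * n || length(partition) != n)
    stop("dimension mismatch between hessian, partition and nodes")
  blocks <- split(seq_len(n), partition)
  cols <- vector("list", length(blocks))
  trip_i <- trip_j <- trip_x <- vector("list", length(blocks))
  col0 <- 0L
  for (bi in seq_along(blocks)) {
    ix <- blocks[[bi]]
    Q <- rigid_basis(nodes$xyz[ix, , drop = FALSE])
    rows <- as.numeric(t(outer(3 * (ix - 1L), 1:3, "+")))  # 3 rows per node
    nc <- ncol(Q)
    trip_i[[bi]] <- rep(rows, nc)
    trip_j[[bi]] <- rep(col0 + seq_len(nc), each = length(rows))
    trip_x[[bi]] <- as.numeric(Q)
    col0 <- col0 + nc
  }
  P <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(3L * n, col0))
  Hp <- Matrix::t(P) %*% hess %*% P
  Hp <- as.matrix((Hp + Matrix::t(Hp)) / 2)
  list(matrix = Hp, P = P)
}

#' Solve for normal modes
#'
#' Eigen-decomposition of the (optionally RTB-projected, optionally
#' mass-weighted) Hessian, keeping the smallest-eigenvalue end of the
#' spectrum. Eigenvalues are reported ascending; frequencies are
#' omega_j = sqrt(lambda_j). Mode numbering follows the usual convention:
#' rigid-body modes 1..n_zero, first internal mode n_zero + 1 (7 for a
#' connected free molecule). Relative frequencies are normalized to the
#' first internal mode; `freq_cm1` anchors that mode at 2.5 cm^-1.
#'
#' @param hess 3N x 3N Hessian.
#' @param nodes the `node_set` (needed when `partition` is given, and for
#'   masses).
#' @param n_modes number of modes to retain from the low end (default: all
#'   available).
#' @param partition optional block index vector; when given, the problem is
#'   solved in the RTB subspace and eigenvectors are back-projected to the
#'   3N atomic space (still orthonormal, since P has orthonormal columns).
#' @param masses optional per-node masses overriding `nodes$mass`; the
#'   generalized problem is solved by symmetric mass weighting
#'   M^(-1/2) H M^(-1/2).
#' @param zero_tol relative tolerance for counting zero modes
#'   (lambda < zero_tol * lambda_max).
#' @return A `mode_set`: list with `values` (ascending), `frequencies`,
#'   `vectors` (3N x n kept, orthonormal columns), `n_zero`,
#'   `first_internal`, `rel_freq`, `freq_cm1`, `n_nodes`, `masses`.
#' @export
solve_modes <- function(hess, nodes = NULL, n_modes = NULL, partition = NULL,
                        masses = NULL, zero_tol = 1e-8) {
  n3 <- nrow(hess)
  if (is.null(masses) && !is.null(nodes)) masses <- nodes$mass
  weighted <- !is.null(masses) && any(masses != 1)
  if (weighted) {
    sm <- rep(1 / sqrt(masses), each = 3)
    hess <- Matrix::t(Matrix::t(hess * sm) * sm)
  }
  P <- NULL
  if (!is.null(partition)) {
    if (is.null(nodes)) stop("partition requires nodes")
    if (weighted)
      warning("RTB projection uses geometric (unweighted) block bases")
    pr <- rtb_project(hess, partition, nodes)
    A <- pr$matrix
    P <- pr$P
  } else {
    A <- as.matrix(hess)
  }
  es <- eigen(A, symmetric = TRUE)
  if (any(!is.finite(es$values))) stop("eigensolver returned non-finite values")
  ord <- order(es$values)
  lam <- es$values[ord]
  V <- es$vectors[, ord, drop = FALSE]
  lmax <- max(lam, 1e-12)
  n_zero <- sum(lam < zero_tol * lmax)
  if (is.null(n_modes)) n_modes <- length(lam)
  n_keep <- min(n_modes, length(lam))
  lam <- lam[seq_len(n_keep)]
  V <- V[, seq_len(n_keep), drop = FALSE]
  if (!is.null(P)) V <- as.matrix(P %*% V)
  lam[lam < 0 & lam > -zero_tol * lmax] <- 0
  freq <- sqrt(pmax(lam, 0))
  first_internal <- n_zero + 1L
  if (n_zero != 6L)
    warning("n_zero = ", n_zero, " (6 expected for a connected free system); ",
            "mode numbering follows n_zero")
  w7 <- if (first_internal <= n_keep) freq[first_internal] else NA_real_
  rel <- if (is.na(w7) || w7 == 0) rep(NA_real_, n_keep) else freq / w7
  structure(list(values = lam, frequencies = freq, vectors = V,
                 n_zero = n_zero, first_internal = first_internal,
                 rel_freq = rel, freq_cm1 = 2.5 * rel,
                 n_nodes = n3 / 3L,
                 masses = if (weighted) masses else rep(1, n3 / 3L)),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("mode_set:", length(x$values), "modes over", x$n_nodes, "nodes;",
      x$n_zero, "zero modes\n")
  if (x$first_internal + 1 <= length(x$values))
    cat("  relative frequencies (modes ", x$first_internal, "-",
        min(x$first_internal + 3, length(x$values)), "): ",
        paste(sprintf("%.3f", x$rel_freq[x$first_internal:
                min(x$first_internal + 3, length(x$values))]), collapse = " "),
        "\n", sep = "")
  invisible(x)
}

#' Indices of internal (non-rigid) modes
#' @param modeset a `mode_set`.
#' @param n_v keep at most this many internal modes (default all).
#' @return integer mode indices.
#' @export
internal_modes <- function(modeset, n_v = Inf) {
  idx <- seq.int(modeset$first_internal, length(modeset$values))
  idx[seq_len(min(n_v, length(idx)))]
}

#' Per-mode summary table
#' @param modeset a `mode_set`.
#' @return data.frame with mode index, eigenvalue, frequency, relative
#'   frequency, and frequency on the 2.5 cm^-1 anchor scale.
#' @export
mode_summary <- function(modeset) {
  data.frame(mode = seq_along(modeset$values),
             lambda = modeset$values,
             omega = modeset$frequencies,
             rel_freq = modeset$rel_freq,
             freq_cm1 = modeset$freq_cm1)
}

#' Write a mode set as plain text
#'
#' One block per mode: a header line `MODE <j> <eigenvalue>` followed by
#' the 3N eigenvector components, one node (x y z) per line.
#'
#' @param modeset a `mode_set`.
#' @param path output path.
#' @param modes which modes (default all kept).
#' @return `path`, invisibly.
#' @export
write_modes <- function(modeset, path, modes = seq_along(modeset$values)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (j in modes) {
    cat(sprintf("MODE %d %.12g\n", j, modeset$values[j]), file = con)
    u <- matrix(modeset$vectors[, j], ncol = 3, byrow = TRUE)
    utils::write.table(format(u, digits = 10), con, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Match modes between two systems
#'
#' Pairs modes of two mode sets by absolute cosine overlap of their
#' eigenvectors restricted to a shared node set, after projecting out net
#' rigid-body motion over those nodes. Used, e.g., to locate a free
#' monomer's hinge and twist modes within a membrane-embedded system's
#' spectrum. Pairing is greedy on the overlap matrix.
#'
#' @param modeset_a,modeset_b `mode_set` objects.
#' @param nodes_a,nodes_b node sets the modes belong to.
#' @param shared_a,shared_b parallel integer vectors of shared node indices
#'   (defaults: all nodes of a, mapped 1:1).
#' @param modes_a,modes_b candidate mode indices (default: internal modes).
#' @return data.frame (mode_a, mode_b, overlap) sorted by decreasing
#'   overlap of the greedy pairing.
#' @export
match_modes <- function(modeset_a, modeset_b, nodes_a, nodes_b,
                        shared_a = seq_len(modeset_a$n_nodes),
                        shared_b = shared_a,
                        modes_a = internal_modes(modeset_a),
                        modes_b = internal_modes(modeset_b)) {
  if (!length(shared_a) || length(shared_a) != length(shared_b))
    stop("shared node mappings must be non-empty and parallel")
  rows_a <- as.numeric(t(outer(3 * (shared_a - 1L), 1:3, "+")))
  rows_b <- as.numeric(t(outer(3 * (shared_b - 1L), 1:3, "+")))
  R <- rigid_basis(nodes_a$xyz[shared_a, , drop = FALSE])
  strip <- function(v) {
    v <- v - R %*% crossprod(R, v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) v else v / nv
  }
  A <- matrix(apply(modeset_a$vectors[rows_a, modes_a, drop = FALSE], 2, strip),
              ncol = length(modes_a))
  B <- matrix(apply(modeset_b$vectors[rows_b, modes_b, drop = FALSE], 2, strip),
              ncol = length(modes_b))
  ov <- abs(crossprod(A, B))
  pairs <- data.frame(mode_a = integer(0), mode_b = integer(0),
                      overlap = numeric(0))
  while (nrow(ov) && ncol(ov) && max(ov) > 0) {
    hit <- which(ov == max(ov), arr.ind = TRUE)[1, ]
    pairs <- rbind(pairs, data.frame(mode_a = modes_a[hit[1]],
                                     mode_b = modes_b[hit[2]],
                                     overlap = max(ov)))
    modes_a <- modes_a[-hit[1]]; modes_b <- modes_b[-hit[2]]
    ov <- ov[-hit[1], -hit[2], drop = FALSE]
  }
  pairs
}
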