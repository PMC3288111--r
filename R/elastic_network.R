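#' Build a Tirion elastic network
#'
#' Connects every pair of nodes closer than the connectivity cutoff with a
#' Hookean spring of uniform force constant, the single-parameter potential
#' of the elastic-network model: the input conformation is taken as the
#' energy minimum and each spring's rest length is the observed pair
#' distance. The default cutoffs used downstream are 10 A for a monomer and
#' 8 A for oligomers.
#'
#' @param nodes a `node_set`.
#' @param cutoff connectivity cutoff R_c in Angstrom.
#' @param k spring force constant (reduced units, default 1).
#' @param extra_pairs optional two-column matrix of node index pairs to
#'   connect regardless of distance (rest length = observed distance);
#'   used, e.g., for the inter-leaflet struts of the bilayer surrogate.
#' @return An `elastic_network`: list with `nodes`, `springs` (data.frame
#'   i, j, d0 with i < j), `cutoff`, `k`, `n_components`.
#' @export
build_network <- function(nodes, cutoff = 10, k = 1, extra_pairs = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- n_nodes(nodes)
  if (n < 2) stop("need at least 2 nodes")
  sp <- neighbor_pairs(nodes$xyz, cutoff)
  if (!is.null(extra_pairs)) {
    i <- pmin(extra_pairs[, 1], extra_pairs[, 2])
    j <- pmax(extra_pairs[, 1], extra_pairs[, 2])
    d0 <- sqrt(rowSums((nodes$xyz[i, , drop = FALSE] -
                          nodes$xyz[j, , drop = FALSE])^2))
    sp <- rbind(sp, data.frame(i = i, j = j, d0 = d0))
    sp <- sp[!duplicated(sp[, c("i", "j")]), , drop = FALSE]
    sp <- sp[order(sp$i, sp$j), , drop = FALSE]
  }
  if (!nrow(sp)) stop("degenerate network: no springs at cutoff ", cutoff)
  if (any(sp$d0 < 1e-6)) stop("coincident nodes (zero rest length)")
  g <- igraph::graph_from_edgelist(cbind(sp$i, sp$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  ncomp <- igraph::components(g)$no
  if (ncomp > 1)
    warning("network has ", ncomp,
            " connected components; rigid-mode count will exceed 6")
  structure(list(nodes = nodes, springs = sp, cutoff = cutoff, k = k,
                 n_components = ncomp), class = "elastic_network")
}

# All pairs within cutoff, computed in column chunks to bound memory.
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  s2 <- rowSums(xyz^2)
  chunk <- max(1L, floor(2e7 / n))
  out <- vector("list", ceiling(n / chunk))
  ci <- 0L
  for (start in seq(1L, n, by = chunk)) {
    cols <- start:min(start + chunk - 1L, n)
    d2 <- outer(s2, s2[cols], "+") - 2 * xyz %*% t(xyz[cols, , drop = FALSE])
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    i <- hit[, 1]; j <- cols[hit[, 2]]
    keep <- i < j
    ci <- ci + 1L
    out[[ci]] <- data.frame(i = i[keep], j = j[keep],
                            d0 = sqrt(pmax(d2[hit][keep], 0)))
  }
  sp <- do.call(rbind, out)
  sp[order(sp$i, sp$j), , drop = FALSE]
}

#' @export
print.elastic_network <- function(x, ...) {
  cat("elastic_network:", n_nodes(x$nodes), "nodes,", nrow(x$springs),
      "springs, cutoff", x$cutoff, "A, k =", x$k, "\n")
  if (x$n_components > 1) cat("  (", x$n_components, "components )\n")
  invisible(x)
}

#' Hessian of the Tirion potential
#'
#' Assembles the 3N x 3N second-derivative matrix of the elastic-network
#' energy at the input conformation. For a spring (i, j) the off-diagonal
#' 3 x 3 super-element is -(k / d0^2) (r_i - r_j)(r_i - r_j)^T; the
#' diagonal super-elements are minus the row sums, so each 3-row block sums
#' to zero (translation invariance) and the matrix is positive
#' semidefinite with six rigid-body null vectors for a connected free
#' molecule.
#'
#' @param network an `elastic_network`.
#' @param sparse return a sparse `Matrix::dsCMatrix`; default for systems
#'   larger than 1000 nodes, dense base matrix otherwise.
#' @return symmetric 3N x 3N matrix (reduced energy units / A^2).
#' @export
hessian <- function(network, sparse = n_nodes(network$nodes) > 1000) {
  xyz <- network$nodes$xyz
  sp <- network$springs
  k <- network$k
  ns <- nrow(sp)
  dr <- xyz[sp$i, , drop = FALSE] - xyz[sp$j, , drop = FALSE]
  w <- k / sp$d0^2
  # 3x3 blocks, row-major over (a, b) Cartesian components
  blocks <- matrix(0, ns, 9)
  cidx <- 0L
  for (a in 1:3) for (b in 1:3) {
    cidx <- cidx + 1L
    blocks[, cidx] <- w * dr[, a] * dr[, b]
  }
  ab <- expand.grid(b = 1:3, a = 1:3)[, c("a", "b")]  # column-major pairing
  ab <- ab[order(ab$a, ab$b), ]
  ii <- jj <- xx <- vector("list", 9L)
  for (cidx in 1:9) {
    a <- ab$a[cidx]; b <- ab$b[cidx]
    v <- blocks[, cidx]
    ri <- 3 * (sp$i - 1L) + a; rj <- 3 * (sp$j - 1L) + a
    ci <- 3 * (sp$i - 1L) + b; cj <- 3 * (sp$j - 1L) + b
    ii[[cidx]] <- c(ri, rj, ri, rj)
    jj[[cidx]] <- c(ci, cj, cj, ci)
    xx[[cidx]] <- c(v, v, -v, -v)
  }
  n3 <- 3L * n_nodes(network$nodes)
  H <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n3, n3))
  H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  if (sparse) H else as.matrix(H)
}

#' Tirion potential energy
#'
#' Harmonic energy of a displaced configuration,
#' E = (k/2) sum over springs (d_ij - d0_ij)^2. Used by the
#' finite-difference validation of [hessian()].
#'
#' @param network an `elastic_network`.
#' @param xyz displaced N x 3 coordinates (default: rest coordinates).
#' @return scalar energy (reduced units).
#' @export
network_energy <- function(network, xyz = network$nodes$xyz) {
  sp <- network$springs
  d <- sqrt(rowSums((xyz[sp$i, , drop = FALSE] -
                       xyz[sp$j, , drop = FALSE])^2))
  0.5 * network$k * sum((d - sp$d0)^2)
}

#' Dump the spring list
#' @param network an `elastic_network`.
#' @param path output TSV path (columns i, j, rest_length).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$springs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("i", "j", "rest_length"))
  invisible(path)
}
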