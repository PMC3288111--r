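#' Structures with known elastic-network spectra
#'
#' Deterministic generators of small test structures whose network spectra
#' and symmetry properties are known analytically or checkable by a dense
#' eigensolve, so every pipeline stage can be validated without an external
#' structure. All generators emit legal PDB-style atom records and
#' round-trip through [write_structure()] / [read_structure()].
#'
#' @name synthetic
NULL

# Wrap bare coordinates as a one-chain C-alpha structure.
structure_from_xyz <- function(xyz, chain = "A", resid = "ALA", name = "CA",
                               hetero = FALSE, provenance = "synthetic") {
  n <- nrow(xyz)
  atoms <- data.frame(serial = seq_len(n), name = name, elem = "C",
                      resid = resid, chain = chain, resno = seq_len(n),
                      insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = 1, b = 0, is_hetero = hetero,
                      stringsAsFactors = FALSE)
  new_structure(atoms, provenance = provenance)
}

#' Zigzag chain
#'
#' A chain with exact consecutive spacing: node i+1 sits `spacing` away
#' from node i, with transverse offsets of size `zigzag_amplitude`
#' (alternating in y, three-step cycling in z, so the chain is neither
#' collinear nor planar; a collinear chain has only five rigid modes and a
#' planar network is degenerate under the pairwise potential). With a
#' cutoff just above `spacing`, connectivity is nearest-neighbour only and
#' the slow spectrum is checkable against a dense eigensolve; note that
#' sparsely connected chains have more than six zero modes (unresisted
#' bending/torsion), which is itself exercised in tests.
#'
#' @param n number of residues (>= 3).
#' @param spacing consecutive-node distance (Angstrom, default 3.8).
#' @param zigzag_amplitude transverse half-amplitude (Angstrom, default 1);
#'   0 gives a collinear chain (warning).
#' @return an `enm_structure`.
#' @export
make_zigzag_chain <- function(n, spacing = 3.8, zigzag_amplitude = 1) {
  if (n < 3) stop("n must be >= 3")
  if (zigzag_amplitude == 0)
    warning("zigzag_amplitude = 0: collinear chain, rigid-mode count is 5")
  if (1.25 * zigzag_amplitude^2 >= spacing^2)
    stop("zigzag_amplitude too large for the given spacing")
  dy <- zigzag_amplitude * rep_len(c(1, -1), n - 1)
  dz <- zigzag_amplitude * rep_len(c(1, 0, -1), n - 1) / 2
  dx <- sqrt(spacing^2 - dy^2 - dz^2)
  xyz <- cbind(c(0, cumsum(dx)), c(0, cumsum(dy)), c(0, cumsum(dz)))
  structure_from_xyz(xyz, provenance = "synthetic zigzag chain")
}

#' Ideal helix of C-alpha nodes
#'
#' @param n number of residues.
#' @param radius helix radius (Angstrom, default 2.3).
#' @param rise rise per residue (Angstrom, default 1.5).
#' @param twist twist per residue (degrees, default 100).
#' @return an `enm_structure`.
#' @export
make_helix <- function(n, radius = 2.3, rise = 1.5, twist = 100) {
  th <- (seq_len(n) - 1) * twist * pi / 180
  xyz <- cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1) * rise)
  structure_from_xyz(xyz, provenance = "synthetic helix")
}

#' Two-domain dumbbell
#'
#' Two compact clusters joined by a sparse linker - the minimal geometry
#' whose slowest internal mode is a hinge motion displacing the two
#' domains against each other, with the smallest amplitudes on the linker.
#' The linker winds helically about the inter-domain axis: a straight (or
#' planar) linker would carry spurious zero modes under the pairwise
#' potential, because transverse displacements of collinear nodes are
#' unresisted to first order.
#'
#' @param n_per_domain nodes per cluster (>= 4).
#' @param linker_length center-to-center gap bridged by linker nodes
#'   (Angstrom, default 24).
#' @param domain_radius cluster radius (Angstrom, default 7).
#' @param linker_spacing node spacing along the linker axis (default 3).
#' @return an `enm_structure`.
#' @export
make_two_domain_dumbbell <- function(n_per_domain, linker_length = 24,
                                     domain_radius = 7, linker_spacing = 3) {
  if (n_per_domain < 4) stop("n_per_domain must be >= 4")
  cluster <- fibonacci_cloud(n_per_domain, domain_radius)
  off <- domain_radius + linker_length / 2
  right <- sweep(cluster, 2, c(-off, 0, 0))        # cluster centred at +off
  left <- right
  left[, 1] <- -left[, 1]                          # mirror image at -off
  # winding depends on |x| only, so the whole dumbbell is exactly mirror
  # symmetric about the x = 0 plane
  lx <- seq(-linker_length / 2, linker_length / 2, by = linker_spacing)
  th <- 0.7 * abs(lx)
  linker <- cbind(lx, 1.5 * cos(th), 1.5 * sin(th))
  structure_from_xyz(rbind(left, linker, right),
                     provenance = "synthetic two-domain dumbbell")
}

# Deterministic quasi-uniform ball filling: spherical Fibonacci points at
# graded radii (no RNG, so the construction is exactly mirror-symmetric
# across builds).
fibonacci_cloud <- function(n, radius) {
  i <- seq_len(n)
  golden <- (1 + sqrt(5)) / 2
  z <- 1 - 2 * (i - 0.5) / n
  r2 <- sqrt(pmax(1 - z^2, 0))
  th <- 2 * pi * i / golden
  r <- radius * ((i - 0.5) / n)^(1 / 3)
  cbind(r * r2 * cos(th), r * r2 * sin(th), r * z)
}

#' Ring oligomer
#'
#' C_n-symmetric assembly: n copies of a monomer placed on a circle of the
#' given radius in the xy plane, each rotated by 2 pi / n about z. Per
#' construction the per-protomer flexibility profiles of a connected ring
#' are identical.
#'
#' @param monomer an `enm_structure` (centered before placement).
#' @param n_copies number of protomers (>= 2).
#' @param radius placement circle radius (Angstrom).
#' @param min_separation copies closer than this raise an overlap error
#'   (Angstrom, default 1).
#' @return a multi-chain `enm_structure`.
#' @export
make_ring_oligomer <- function(monomer, n_copies, radius,
                               min_separation = 1) {
  if (n_copies < 2) stop("n_copies must be >= 2")
  at0 <- monomer$atoms
  xyz0 <- as.matrix(at0[, c("x", "y", "z")])
  xyz0 <- sweep(xyz0, 2, colMeans(xyz0))
  pieces <- vector("list", n_copies)
  chain_pool <- c(LETTERS, letters)
  for (k in seq_len(n_copies)) {
    th <- 2 * pi * (k - 1) / n_copies
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    xyz <- t(R %*% t(xyz0)) +
      matrix(c(radius * cos(th), radius * sin(th), 0),
             nrow(xyz0), 3, byrow = TRUE)
    at <- at0
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    at$chain <- chain_pool[k]
    pieces[[k]] <- at
  }
  out <- do.call(rbind, pieces)
  out$serial <- seq_len(nrow(out))
  # overlap check between distinct copies
  xyz <- as.matrix(out[, c("x", "y", "z")])
  cop <- rep(seq_len(n_copies), each = nrow(at0))
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  d2[cop[row(d2)] == cop[col(d2)]] <- Inf
  mind <- sqrt(max(min(d2), 0))
  if (mind < min_separation)
    stop(sprintf("overlapping copies: minimum inter-copy distance %.3f A",
                 mind))
  new_structure(out, provenance = sprintf("synthetic ring oligomer x%d",
                                          n_copies))
}

#' Pseudo-experimental B-factors
#'
#' Affine transform of a computed MSF profile plus Gaussian noise,
#' B = scale * (8 pi^2 / 3) * msf + shift + N(0, noise_sd^2), emulating
#' X-ray B-factors whose rigid-body baseline and unit conversion are
#' unknown. Used to test that the affine rescaling recovers the planted
#' parameters.
#'
#' @param msf per-node MSF.
#' @param scale,shift planted affine parameters.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return numeric per-node pseudo-B vector.
#' @export
make_pseudo_bfactors <- function(msf, scale = 1, shift = 0, noise_sd = 0,
                                 seed = NULL) {
  b <- scale * bfactor(msf) + shift
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0")
    b <- b + withr::with_seed(seed, stats::rnorm(length(b), 0, noise_sd))
  }
  b
}
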