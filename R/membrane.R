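#' Build a coarse bilayer-slab surrogate
#'
#' Two parallel square lattices of elastic-network nodes standing in for
#' the head-group planes of a lipid bilayer. The surrogate reproduces the
#' qualitative effect of a membrane on protein normal modes - extra
#' connectivity that damps fluctuations at the contact surface - without
#' any lipid chemistry. The default lateral size is 80 x 80 Angstrom.
#'
#' @param dim_x,dim_y lateral dimensions (Angstrom, default 80).
#' @param spacing lattice spacing (Angstrom, default 5).
#' @param leaflet_z half-separation of the two leaflet planes (Angstrom,
#'   default 15; leaflets sit at z = +/- leaflet_z).
#' @param center xyz offset of the slab center (default origin).
#' @return a `node_set` with component label `"lipid"`, residue name MEM.
#' @export
build_bilayer_slab <- function(dim_x = 80, dim_y = 80, spacing = 5,
                               leaflet_z = 15, center = c(0, 0, 0)) {
  if (spacing <= 0) stop("spacing must be positive")
  if (dim_x < spacing || dim_y < spacing) stop("dims must be >= spacing")
  gx <- seq(0, dim_x, by = spacing) - dim_x / 2
  gy <- seq(0, dim_y, by = spacing) - dim_y / 2
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  xyz <- rbind(cbind(grid, z = leaflet_z), cbind(grid, z = -leaflet_z))
  xyz <- sweep(xyz, 2, -center)
  n <- nrow(xyz)
  info <- data.frame(chain = "M", resno = seq_len(n), insert = "",
                     resid = "MEM", name = "P", is_hetero = TRUE,
                     component = "lipid", stringsAsFactors = FALSE)
  out <- new_node_set(xyz, info, mass = 1)
  attr(out, "spacing") <- spacing
  out
}

#' Inter-leaflet strut springs for the slab surrogate
#'
#' Pairs each surviving upper-leaflet node with the lower-leaflet nodes
#' within one lattice step laterally (the vertical strut plus its four
#' diagonals). These struts emulate the tail-tail coupling of the two
#' leaflets: without them each flat leaflet lattice would carry
#' out-of-plane and leaflet-shear motions unresisted to first order by the
#' pairwise potential.
#'
#' @param nodes a `node_set` containing lipid-component nodes (e.g. the
#'   combined node set of an `embedded_system`).
#' @param lateral maximum lateral (xy) distance for a strut (default: the
#'   slab lattice spacing).
#' @return two-column matrix of node index pairs for
#'   [build_network()]'s `extra_pairs`.
#' @export
membrane_struts <- function(nodes, lateral = 5) {
  lip <- which(nodes$info$component == "lipid")
  if (!length(lip)) return(matrix(integer(0), 0, 2))
  z <- nodes$xyz[lip, 3]
  zmid <- mean(range(z))
  top <- lip[z > zmid]; bot <- lip[z <= zmid]
  if (!length(top) || !length(bot)) return(matrix(integer(0), 0, 2))
  TX <- nodes$xyz[top, 1:2, drop = FALSE]
  BX <- nodes$xyz[bot, 1:2, drop = FALSE]
  d2 <- outer(rowSums(TX^2), rowSums(BX^2), "+") - 2 * TX %*% t(BX)
  hit <- which(d2 <= (lateral * 1.001)^2, arr.ind = TRUE)
  cbind(top[hit[, 1]], bot[hit[, 2]])
}

#' Embed a protein node set into a bilayer slab
#'
#' Merges protein and lipid nodes after removing every lipid node within
#' the clash radius of any protein heavy atom. The caller is responsible
#' for orienting the protein with the membrane normal along z beforehand.
#'
#' @param nodes protein `node_set` (pre-oriented).
#' @param slab lipid `node_set` from [build_bilayer_slab()].
#' @param clash_radius removal distance in Angstrom (default 3).
#' @param heavy_xyz optional M x 3 matrix of protein heavy-atom coordinates
#'   to test clashes against (default: the node coordinates themselves, the
#'   right choice for all-heavy node sets; pass the full structure's heavy
#'   atoms when nodes are C-alpha only).
#' @return An `embedded_system`: list with `nodes` (protein first, then
#'   surviving lipid nodes), `n_removed`, `clash_radius`, `n_protein`.
#' @export
embed_protein <- function(nodes, slab, clash_radius = 3,
                          heavy_xyz = nodes$xyz) {
  P <- as.matrix(heavy_xyz)
  L <- slab$xyz
  d2 <- outer(rowSums(L^2), rowSums(P^2), "+") - 2 * L %*% t(P)
  clash <- apply(d2, 1, min) <= clash_radius^2
  if (!any(clash))
    warning("no lipid nodes removed; protein may lie outside the slab")
  keep <- which(!clash)
  combined <- combine_nodes(nodes, subset_nodes(slab, keep))
  structure(list(nodes = combined, n_removed = sum(clash),
                 clash_radius = clash_radius, n_protein = n_nodes(nodes)),
            class = "embedded_system")
}

#' @export
print.embedded_system <- function(x, ...) {
  cat("embedded_system:", x$n_protein, "protein nodes +",
      n_nodes(x$nodes) - x$n_protein, "lipid nodes (", x$n_removed,
      "lipid nodes removed at clash radius", x$clash_radius, "A )\n")
  invisible(x)
}

#' Protein nodes in contact with the membrane
#' @param embedded an `embedded_system`.
#' @param contact_radius distance threshold (Angstrom, default 5).
#' @return integer indices (into the protein node set) of contact nodes.
#' @export
membrane_contacts <- function(embedded, contact_radius = 5) {
  nod <- embedded$nodes
  prot <- seq_len(embedded$n_protein)
  lip <- setdiff(seq_len(n_nodes(nod)), prot)
  if (!length(lip)) return(integer(0))
  P <- nod$xyz[prot, , drop = FALSE]
  L <- nod$xyz[lip, , drop = FALSE]
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  which(apply(d2, 1, min) <= contact_radius^2)
}
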