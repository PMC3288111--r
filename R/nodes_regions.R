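#' Select network nodes from a structure
#'
#' Two coarse-graining schemes are supported. `calpha_plus_hetero` places
#' one node per amino-acid residue at its C-alpha and one node per hetero
#' heavy atom, so cofactors (heme) and bound ligands enter the network with
#' all of their heavy atoms. `all_heavy` places one node per heavy atom.
#'
#' @param structure an `enm_structure`.
#' @param scheme `"calpha_plus_hetero"` or `"all_heavy"`.
#' @param mass per-node mass; the default 1 follows the reduced-unit
#'   convention of the elastic-network model.
#' @return A `node_set`: list with `xyz` (N x 3 matrix, Angstrom), `mass`
#'   (length N), and `info` (data.frame with chain, resno, insert, resid,
#'   name, is_hetero, component).
#' @export
select_nodes <- function(structure,
                         scheme = c("calpha_plus_hetero", "all_heavy"),
                         mass = 1) {
  scheme <- match.arg(scheme)
  at <- structure$atoms
  if (!nrow(at)) stop("empty structure")
  if (scheme == "all_heavy") {
    sel <- seq_len(nrow(at))
  } else {
    rk <- residue_key(at)
    sel <- integer(0)
    for (key in unique(rk)) {
      ix <- which(rk == key)
      if (at$is_hetero[ix[1]]) {
        sel <- c(sel, ix)                       # hetero: every heavy atom
      } else {
        ca <- ix[at$name[ix] == "CA"]
        if (!length(ca)) {
          warning("residue ", key, " has no CA atom; skipped")
        } else sel <- c(sel, ca[1])
      }
    }
  }
  at <- at[sel, , drop = FALSE]
  info <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                     resid = at$resid, name = at$name,
                     is_hetero = at$is_hetero,
                     component = "protein", stringsAsFactors = FALSE)
  info$component[info$resid == "MEM"] <- "lipid"
  new_node_set(as.matrix(at[, c("x", "y", "z")]), info, mass = mass)
}

#' Construct a node set
#' @param xyz N x 3 coordinate matrix (Angstrom).
#' @param info data.frame of per-node metadata (chain, resno, insert, resid,
#'   name, is_hetero, component).
#' @param mass per-node masses (recycled), default 1 (reduced units).
#' @return object of class `node_set`.
#' @export
new_node_set <- function(xyz, info, mass = 1) {
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  n <- nrow(xyz)
  mass <- rep_len(mass, n)
  if (any(mass <= 0)) stop("masses must be positive")
  rownames(info) <- NULL
  structure(list(xyz = xyz, mass = mass, info = info), class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  cat("node_set:", nrow(x$xyz), "nodes (",
      paste(sprintf("%s: %d", names(table(x$info$component)),
                    as.integer(table(x$info$component))), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Number of nodes
#' @param nodes a `node_set`.
#' @return integer count.
#' @export
n_nodes <- function(nodes) nrow(nodes$xyz)

#' Merge two node sets
#' @param a,b `node_set` objects with identical info columns.
#' @return combined `node_set` (a's nodes first).
#' @export
combine_nodes <- function(a, b) {
  new_node_set(rbind(a$xyz, b$xyz), rbind(a$info, b$info),
               mass = c(a$mass, b$mass))
}

#' Region specification for flexibility reporting
#'
#' Holds named residue selectors (heme, substrate, catalytic cleft, access
#' channel, proximal cavity, E/P electrostatic sites) plus the radial-layer
#' thresholds used to split a molecule into an inner core, middle layer and
#' outer layer around the substrate centroid.
#'
#' @param regions named list; each element a list with any of `resid`
#'   (residue-name selector, e.g. `"HEM"`), `resno` (residue numbers),
#'   `chain` (restrict to chains).
#' @param layer_radii strictly increasing radii in Angstrom (default
#'   `c(15, 20)`).
#' @param cleft_distance fallback rule for an empty `catalytic_cleft`:
#'   residues with any heavy atom within this distance (Angstrom) of the
#'   substrate (default 4.5).
#' @return object of class `region_spec`.
#' @export
region_spec <- function(regions = list(), layer_radii = c(15, 20),
                        cleft_distance = 4.5) {
  if (is.unsorted(layer_radii, strictly = TRUE))
    stop("layer_radii must be strictly increasing")
  structure(list(regions = regions, layer_radii = layer_radii,
                 cleft_distance = cleft_distance), class = "region_spec")
}

#' Read a region specification from a YAML config
#'
#' Schema: top-level keys are region names (`heme`, `substrate`,
#' `catalytic_cleft`, `access_channel`, `proximal_cavity`, `e_site`,
#' `p_site`, ...), each mapping to `resid` / `resno` / `chain` selectors,
#' plus optional `layer_radii` and `cleft_distance`.
#'
#' @param path YAML file.
#' @return a [region_spec()].
#' @export
read_region_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  radii <- cfg$layer_radii %||% c(15, 20)
  cdist <- cfg$cleft_distance %||% 4.5
  cfg$layer_radii <- NULL
  cfg$cleft_distance <- NULL
  regions <- lapply(cfg, function(r) {
    list(resid = r$resid, resno = unlist(r$resno), chain = r$chain)
  })
  region_spec(regions, layer_radii = as.numeric(radii),
              cleft_distance = as.numeric(cdist))
}

# Resolve one selector to atom-row indices of a structure.
resolve_selector <- function(atoms, sel) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(sel$resid)) keep <- keep & atoms$resid %in% sel$resid
  if (!is.null(sel$resno)) keep <- keep & atoms$resno %in% sel$resno
  if (!is.null(sel$chain)) keep <- keep & atoms$chain %in% sel$chain
  if (is.null(sel$resid) && is.null(sel$resno) && is.null(sel$chain))
    keep <- rep(FALSE, nrow(atoms))
  which(keep)
}

#' Assign nodes to regions and radial layers
#'
#' Every node receives exactly one layer label from its distance to the
#' substrate-centroid reference point (layer 1: r <= radii[1]; layer 2:
#' radii[1] < r <= radii[2]; outermost: r > last radius, following the
#' boundary convention inner core r <= 15 A, middle 15 < r <= 20 A, outer
#' r > 20 A). Region labels may overlap layers and each other except where
#' noted. Residue-node layer membership uses the C-alpha position; hetero
#' nodes use their own atom position.
#'
#' @param structure the `enm_structure` the nodes came from.
#' @param nodes a `node_set` from [select_nodes()].
#' @param spec a [region_spec()].
#' @param layers compute radial layers (requires a resolvable `substrate`
#'   region; default `TRUE` when one is present).
#' @return A `region_assignment`: list with `regions` (logical N x R
#'   matrix), `layer` (integer per node, NA when layers not computed),
#'   `layer_names`, and `reference` (the substrate centroid).
#' @export
assign_regions <- function(structure, nodes, spec,
                           layers = !is.null(spec$regions$substrate)) {
  at <- structure$atoms
  nn <- n_nodes(nodes)
  region_names <- names(spec$regions)
  regions <- matrix(FALSE, nn, length(region_names),
                    dimnames = list(NULL, region_names))
  node_rk <- paste(nodes$info$chain, nodes$info$resno, nodes$info$insert,
                   sep = "|")

  sub_idx <- if (!is.null(spec$regions$substrate))
    resolve_selector(at, spec$regions$substrate) else integer(0)

  for (rn in region_names) {
    sel <- spec$regions[[rn]]
    idx <- resolve_selector(at, sel)
    if (rn == "catalytic_cleft" && !length(idx) && length(sub_idx)) {
      # fallback: residues with any heavy atom within cleft_distance of the
      # substrate heavy atoms
      S <- as.matrix(at[sub_idx, c("x", "y", "z")])
      P <- as.matrix(at[, c("x", "y", "z")])
      d2 <- outer(rowSums(P^2), rowSums(S^2), "+") - 2 * P %*% t(S)
      near <- apply(d2, 1, min) <= spec$cleft_distance^2
      near[sub_idx] <- FALSE
      idx <- which(near & !at$is_hetero)
    }
    if (length(idx))
      regions[node_rk %in% unique(residue_key(at[idx, , drop = FALSE])), rn] <- TRUE
  }

  layer <- rep(NA_integer_, nn)
  ref <- NULL
  if (layers) {
    if (!length(sub_idx))
      stop("layer assignment requested but the substrate selection is empty")
    ref <- colMeans(as.matrix(at[sub_idx, c("x", "y", "z")]))
    r <- sqrt(rowSums((nodes$xyz - matrix(ref, nn, 3, byrow = TRUE))^2))
    layer <- findInterval(r, spec$layer_radii, left.open = TRUE) + 1L
  }
  nlay <- length(spec$layer_radii) + 1L
  layer_names <- if (nlay == 3L) c("inner_core", "middle_layer", "outer_layer")
                 else paste0("layer_", seq_len(nlay))
  structure(list(regions = regions, layer = layer, layer_names = layer_names,
                 reference = ref), class = "region_assignment")
}

#' Count charged residues in a site
#'
#' Census of acidic (Asp, Glu) and basic (Lys, Arg, optionally His) side
#' chains within a named residue set, as used to characterize the
#' electronegative E site and electropositive P site flanking the
#' head-to-tail binding interface. The heme counts as one positive moiety
#' when its residue is inside the site.
#'
#' @param structure an `enm_structure`.
#' @param site selector list (`resid` / `resno` / `chain`), as in
#'   [region_spec()].
#' @param include_his count histidine as basic (default `FALSE`).
#' @return list with `n_acidic`, `n_basic`, `include_heme`.
#' @export
charge_census <- function(structure, site, include_his = FALSE) {
  at <- structure$atoms
  idx <- resolve_selector(at, site)
  if (!length(idx)) return(list(n_acidic = 0L, n_basic = 0L,
                                include_heme = FALSE))
  res <- at[idx, , drop = FALSE]
  res <- res[!duplicated(residue_key(res)), , drop = FALSE]
  basic <- c("LYS", "ARG", if (include_his) "HIS")
  list(n_acidic = sum(res$resid %in% c("ASP", "GLU")),
       n_basic = sum(res$resid %in% basic),
       include_heme = any(res$resid == "HEM"))
}
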