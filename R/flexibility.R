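#' Mean square fluctuation from normal modes
#'
#' Thermal MSF of node i from the slow internal modes,
#' MSF_i = (k_B T / m_i) * sum_j |U_ij|^2 / omega_j^2, where U_ij is the
#' 3-vector of mode j at node i and the sum runs over the n_v slowest
#' internal modes (rigid modes excluded). The conventional choice n_v = 100
#' gives a converged profile for protein-sized networks; when fewer
#' internal modes exist, all are used (with a message).
#'
#' @param modeset a `mode_set`.
#' @param n_v number of internal modes to include (default 100).
#' @param masses per-node masses (default: the mode set's, usually 1).
#' @param kBT thermal energy in reduced units (default 1).
#' @return numeric per-node MSF (reduced units).
#' @export
msf <- function(modeset, n_v = 100, masses = modeset$masses, kBT = 1) {
  idx <- internal_modes(modeset, n_v)
  if (is.finite(n_v) && length(idx) < n_v)
    message("only ", length(idx), " internal modes available; using all")
  lam <- modeset$values[idx]
  if (any(lam <= 0))
    stop("zero/negative eigenvalue among internal modes entering the MSF sum")
  U2 <- modeset$vectors[, idx, drop = FALSE]^2
  # sum the three Cartesian rows of each node, weight by 1/omega^2 = 1/lambda
  per_row <- U2 %*% (1 / lam)
  node_sum <- rowSums(matrix(per_row, ncol = 3, byrow = TRUE))
  kBT * node_sum / rep_len(masses, length(node_sum))
}

#' B-factor from MSF
#'
#' Isotropic crystallographic temperature factor, B = (8 pi^2 / 3) * MSF.
#' In reduced MSF units the output is proportional and must be rescaled
#' against experiment with [rescale_to_experiment()] before comparison.
#'
#' @param msf per-node MSF.
#' @return per-node B (same units times 8 pi^2 / 3).
#' @export
bfactor <- function(msf) {
  if (any(msf < 0)) stop("MSF must be non-negative")
  (8 * pi^2 / 3) * msf
}

#' Rescale computed B-factors to experiment
#'
#' Ordinary least squares of the experimental B-factors on the computed
#' ones: b_exp ~ s * b_calc + b0. The origin shift b0 absorbs the
#' rigid-body and lattice-disorder contribution present in X-ray B-factors
#' but absent from internal-mode fluctuations; the scale s converts reduced
#' units to Angstrom^2.
#'
#' @param b_calc computed per-node B (reduced units).
#' @param b_exp experimental per-node B (Angstrom^2).
#' @param exclude optional indices to leave out of the fit (e.g. terminal
#'   residues); excluded nodes still receive fitted values.
#' @return A `bfactor_fit`: list with `scale`, `shift`, `fitted`, `r`
#'   (Pearson correlation over the fitted subset), `se` (standard errors of
#'   scale and shift), `n_fit`.
#' @export
rescale_to_experiment <- function(b_calc, b_exp, exclude = NULL) {
  if (length(b_calc) != length(b_exp))
    stop("b_calc and b_exp must have the same length")
  use <- setdiff(seq_along(b_calc), exclude)
  if (length(use) < 3) stop("need at least 3 nodes to fit")
  if (stats::var(b_calc[use]) < .Machine$double.eps)
    stop("degenerate fit: computed B-factors have zero variance")
  fit <- stats::lm(b_exp[use] ~ b_calc[use])
  cf <- unname(stats::coef(fit))
  # a noiseless affine input gives an exact fit; the usual "essentially
  # perfect fit" caveat does not apply to the coefficients themselves
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  structure(list(scale = cf[2], shift = cf[1],
                 fitted = cf[1] + cf[2] * b_calc,
                 r = stats::cor(b_calc[use], b_exp[use]),
                 se = c(shift = unname(se[1]), scale = unname(se[2])),
                 n_fit = length(use)),
            class = "bfactor_fit")
}

#' @export
print.bfactor_fit <- function(x, ...) {
  cat(sprintf("bfactor_fit: B_exp ~ %.4g * B_calc + %.4g  (r = %.3f, n = %d)\n",
              x$scale, x$shift, x$r, x$n_fit))
  invisible(x)
}

#' Relative RMSF
#'
#' Square root of the MSF, normalized so that its mean over the reporting
#' node set is exactly 1; flexibility is thus expressed relative to the
#' molecule-wide average.
#'
#' @param msf per-node MSF.
#' @param reporting indices of the reporting set (default: all nodes).
#' @return per-node relative RMSF (dimensionless).
#' @export
relative_rmsf <- function(msf, reporting = seq_along(msf)) {
  if (!length(reporting)) stop("reporting set is empty")
  r <- sqrt(msf)
  m <- mean(r[reporting])
  if (m < .Machine$double.eps) stop("degenerate profile: all-zero MSF")
  r / m
}

# Residue-level values: the node value itself in C-alpha mode (one node per
# residue); the mean over a residue's nodes otherwise (backbone averaging
# is applied upstream by passing only backbone nodes).
residue_values <- function(values, nodes) {
  key <- paste(nodes$info$chain, nodes$info$resno, nodes$info$insert,
               sep = "|")
  agg <- tapply(values, key, mean)
  ord <- unique(key)
  data.frame(chain = nodes$info$chain[match(ord, key)],
             resno = nodes$info$resno[match(ord, key)],
             insert = nodes$info$insert[match(ord, key)],
             resid = nodes$info$resid[match(ord, key)],
             value = as.numeric(agg[ord]),
             stringsAsFactors = FALSE)
}

#' Region and layer flexibility report
#'
#' Unweighted arithmetic mean of residue-level relative RMSF over each
#' named region and radial layer. Residue-level values are the per-node
#' value in C-alpha mode and the mean over a residue's nodes for
#' multi-node residues (heme, ligand). Empty regions are omitted with a
#' warning; rows appear in a deterministic order (regions as specified,
#' then layers inner to outer).
#'
#' @param rmsf per-node relative RMSF.
#' @param assignment a `region_assignment` from [assign_regions()].
#' @param nodes the `node_set`.
#' @return data.frame (name, kind, mean_rmsf, n_nodes, n_residues).
#' @export
region_layer_report <- function(rmsf, assignment, nodes) {
  rows <- list()
  key <- paste(nodes$info$chain, nodes$info$resno, nodes$info$insert,
               sep = "|")
  region_mean <- function(sel) {
    if (!any(sel)) return(NULL)
    rv <- residue_values(rmsf[sel], subset_nodes(nodes, which(sel)))
    c(mean = mean(rv$value), n_nodes = sum(sel), n_res = nrow(rv))
  }
  for (rn in colnames(assignment$regions)) {
    s <- region_mean(assignment$regions[, rn])
    if (is.null(s)) { warning("region '", rn, "' is empty; omitted"); next }
    rows[[length(rows) + 1L]] <- data.frame(name = rn, kind = "region",
                                            mean_rmsf = s["mean"],
                                            n_nodes = s["n_nodes"],
                                            n_residues = s["n_res"])
  }
  if (!all(is.na(assignment$layer))) {
    for (li in seq_along(assignment$layer_names)) {
      s <- region_mean(!is.na(assignment$layer) & assignment$layer == li)
      if (is.null(s)) { warning("layer '", assignment$layer_names[li],
                                "' is empty; omitted"); next }
      rows[[length(rows) + 1L]] <- data.frame(name = assignment$layer_names[li],
                                              kind = "layer",
                                              mean_rmsf = s["mean"],
                                              n_nodes = s["n_nodes"],
                                              n_residues = s["n_res"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subset a node set
#' @param nodes a `node_set`.
#' @param idx node indices to keep.
#' @return the reduced `node_set`.
#' @export
subset_nodes <- function(nodes, idx) {
  new_node_set(nodes$xyz[idx, , drop = FALSE],
               nodes$info[idx, , drop = FALSE], mass = nodes$mass[idx])
}

#' Compare two flexibility profiles
#'
#' Per-node deltas (b minus a) over a shared node mapping, e.g. a structure
#' with and without its bound substrate, plus per-region deltas when an
#' assignment is supplied. Positive delta means profile b is more mobile.
#'
#' @param rmsf_a,rmsf_b per-node relative RMSF vectors.
#' @param shared_a,shared_b parallel index vectors mapping shared nodes
#'   (defaults: identity over a's nodes).
#' @param assignment optional `region_assignment` on system a (restricted
#'   to the shared nodes).
#' @param nodes_a optional `node_set` for residue-level region deltas.
#' @return list with `delta` (per shared node) and, when an assignment is
#'   given, `region_delta` (data.frame name, kind, delta).
#' @export
compare_profiles <- function(rmsf_a, rmsf_b,
                             shared_a = seq_along(rmsf_a),
                             shared_b = shared_a,
                             assignment = NULL, nodes_a = NULL) {
  if (!length(shared_a) || length(shared_a) != length(shared_b))
    stop("shared node mappings must be non-empty and parallel")
  delta <- rmsf_b[shared_b] - rmsf_a[shared_a]
  out <- list(delta = delta)
  if (!is.null(assignment) && !is.null(nodes_a)) {
    ra <- region_layer_report(rmsf_a, assignment, nodes_a)
    # evaluate b's values on a's nodes through the shared mapping
    rb <- rmsf_a
    rb[shared_a] <- rmsf_b[shared_b]
    keep <- rep(FALSE, length(rmsf_a)); keep[shared_a] <- TRUE
    assignment2 <- assignment
    assignment2$regions <- assignment$regions & keep
    assignment2$layer <- ifelse(keep, assignment$layer, NA_integer_)
    ra2 <- suppressWarnings(region_layer_report(rmsf_a, assignment2, nodes_a))
    rb2 <- suppressWarnings(region_layer_report(rb, assignment2, nodes_a))
    m <- merge(ra2, rb2, by = c("name", "kind"), suffixes = c("_a", "_b"))
    out$region_delta <- data.frame(name = m$name, kind = m$kind,
                                   delta = m$mean_rmsf_b - m$mean_rmsf_a)
  }
  out
}

#' Full flexibility profile
#'
#' Convenience wrapper chaining [msf()], [bfactor()] and [relative_rmsf()].
#'
#' @param modeset a `mode_set`.
#' @param n_v internal modes in the MSF sum (default 100).
#' @param kBT thermal energy, reduced units.
#' @return A `flex_profile`: list with `msf`, `rmsf_rel`, `b_calc`, `n_v`.
#' @export
flexibility_profile <- function(modeset, n_v = 100, kBT = 1) {
  m <- msf(modeset, n_v = n_v, kBT = kBT)
  structure(list(msf = m, rmsf_rel = relative_rmsf(m), b_calc = bfactor(m),
                 n_v = min(n_v, length(internal_modes(modeset)))),
            class = "flex_profile")
}
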