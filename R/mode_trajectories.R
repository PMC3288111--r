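#' Perturb a structure along one normal mode
#'
#' Generates conformers x(a) = x0 + a * U_j over an amplitude grid, the
#' standard way of visualizing a collective mode. The default grid, -100 to
#' 100 in steps of 20, yields 11 frames with the unperturbed structure in
#' the middle.
#'
#' @param nodes a `node_set` (the coordinates the mode set was solved on).
#' @param modeset a `mode_set`.
#' @param mode mode index (internal modes expected; a rigid mode triggers a
#'   warning but is allowed).
#' @param amplitudes numeric grid (default `seq(-100, 100, by = 20)`).
#' @return A `mode_trajectory`: list with `mode`, `amplitudes`, `frames`
#'   (list of N x 3 matrices), `nodes`.
#' @export
perturb_along_mode <- function(nodes, modeset, mode,
                               amplitudes = seq(-100, 100, by = 20)) {
  if (mode < 1 || mode > ncol(modeset$vectors)) stop("mode index out of range")
  if (mode < modeset$first_internal)
    warning("mode ", mode, " is a rigid-body mode")
  U <- matrix(modeset$vectors[, mode], ncol = 3, byrow = TRUE)
  frames <- lapply(amplitudes, function(a) nodes$xyz + a * U)
  structure(list(mode = mode, amplitudes = amplitudes, frames = frames,
                 nodes = nodes), class = "mode_trajectory")
}

#' Write a mode trajectory as multi-model PDB
#'
#' One MODEL/ENDMDL block per amplitude frame, re-readable through the
#' package's PDB reader (or any multi-model-aware reader).
#'
#' @param traj a `mode_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  info <- traj$nodes$info
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (f in seq_along(traj$frames)) {
    xyz <- traj$frames[[f]]
    bio3d::write.pdb(file = tmp, xyz = as.numeric(t(xyz)),
                     type = ifelse(info$is_hetero | info$component == "lipid",
                                   "HETATM", "ATOM"),
                     eleno = seq_len(nrow(xyz)), elety = info$name,
                     resid = info$resid, chain = info$chain,
                     resno = info$resno, insert = info$insert,
                     o = rep(1, nrow(xyz)), b = rep(0, nrow(xyz)))
    lines <- readLines(tmp, warn = FALSE)
    lines <- lines[!startsWith(lines, "END")]
    writeLines(c(sprintf("MODEL     %4d", f), lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Eigenvector arrow field
#'
#' Per-node base position and scaled displacement vector for rendering a
#' mode as arrows; the conventional display scale is 200.
#'
#' @param nodes a `node_set`.
#' @param modeset a `mode_set`.
#' @param mode mode index.
#' @param scale multiplier applied to the eigenvector (default 200).
#' @return data.frame (chain, resno, x, y, z, dx, dy, dz).
#' @export
eigenvector_arrows <- function(nodes, modeset, mode, scale = 200) {
  if (mode < 1 || mode > ncol(modeset$vectors)) stop("mode index out of range")
  U <- matrix(modeset$vectors[, mode], ncol = 3, byrow = TRUE)
  data.frame(chain = nodes$info$chain, resno = nodes$info$resno,
             x = nodes$xyz[, 1], y = nodes$xyz[, 2], z = nodes$xyz[, 3],
             dx = scale * U[, 1], dy = scale * U[, 2], dz = scale * U[, 3])
}

#' Write an arrow field as TSV
#' @param arrows data.frame from [eigenvector_arrows()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_arrows <- function(arrows, path) {
  utils::write.table(arrows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
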