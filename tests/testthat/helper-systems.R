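# Shared builders for small test systems.

# Bare node set from a coordinate matrix (one pseudo-residue per node).
cloud_nodes <- function(xyz, chain = "A") {
  n <- nrow(xyz)
  new_node_set(xyz, data.frame(chain = chain, resno = seq_len(n),
                               insert = "", resid = "ALA", name = "CA",
                               is_hetero = FALSE, component = "protein",
                               stringsAsFactors = FALSE))
}

# Deterministic compact random cloud, connected at the given cutoff.
random_cloud <- function(n, seed, sd = 3) {
  withr::with_seed(seed, matrix(stats::rnorm(3 * n, sd = sd), n, 3))
}

# Two-node dumbbell separated by d along x.
dumbbell_nodes <- function(d = 3) {
  cloud_nodes(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE))
}

# Independent brute-force pair enumeration (the oracle for build_network).
brute_pairs <- function(xyz, cutoff) {
  out <- NULL
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= cutoff) out <- rbind(out, c(i, j))
  }
  out
}

# Hand-written fixed-column PDB fixture writer.
write_pdb_lines <- function(path, records) {
  lines <- vapply(records, function(r) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            r$type, r$serial, paste0(" ", r$name), r$alt, r$resid, r$chain,
            r$resno, " ", r$x, r$y, r$z, r$occ, r$b, r$elem)
  }, character(1))
  writeLines(c(lines, "END"), path)
}

atom_rec <- function(serial, name, resid, chain, resno, x, y, z,
                     occ = 1, b = 10, elem = "C", alt = " ",
                     type = "ATOM") {
  list(type = type, serial = serial, name = name, alt = alt, resid = resid,
       chain = chain, resno = resno, x = x, y = y, z = z, occ = occ, b = b,
       elem = elem)
}
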