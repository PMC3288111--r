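#' Run configuration
#'
#' Collects the tunable parameters of a flexibility run with the
#' conventional defaults: connectivity cutoff 10 A for a monomer and 8 A
#' for oligomers, 100 internal modes in the MSF sum, radial layers at 15
#' and 20 A, perturbation grid -100..100 step 20, arrow scale 200.
#'
#' @param input path to a PDB file, or an `enm_structure`.
#' @param scheme node scheme (see [select_nodes()]).
#' @param cutoff connectivity cutoff (Angstrom).
#' @param residues_per_block RTB block size (1 = exact for C-alpha runs).
#' @param n_v internal modes in the MSF sum.
#' @param region_spec a [region_spec()], path to a YAML config, or `NULL`.
#' @param exclude_termini residues trimmed from each chain end in the
#'   B-factor fit (default 3).
#' @param seed integer seed recorded in the provenance and used for any
#'   stochastic step.
#' @param outdir output directory, or `NULL` to skip writing files.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(input, scheme = "calpha_plus_hetero", cutoff = 10,
                       residues_per_block = 1, n_v = 100, region_spec = NULL,
                       exclude_termini = 3, seed = 1, outdir = NULL) {
  bad <- character(0)
  if (is.character(input) && !file.exists(input)) bad <- c(bad, "input")
  if (!scheme %in% c("calpha_plus_hetero", "all_heavy")) bad <- c(bad, "scheme")
  if (!is.numeric(cutoff) || cutoff <= 0) bad <- c(bad, "cutoff")
  if (residues_per_block < 1) bad <- c(bad, "residues_per_block")
  if (n_v < 1) bad <- c(bad, "n_v")
  if (is.character(region_spec) && !file.exists(region_spec))
    bad <- c(bad, "region_spec")
  if (length(bad))
    stop("invalid configuration keys: ", paste(bad, collapse = ", "))
  structure(list(input = input, scheme = scheme, cutoff = cutoff,
                 residues_per_block = residues_per_block, n_v = n_v,
                 region_spec = region_spec,
                 exclude_termini = exclude_termini, seed = seed,
                 outdir = outdir), class = "run_config")
}

resolve_input <- function(input) {
  if (inherits(input, "enm_structure")) input else read_structure(input)
}

resolve_region_spec <- function(rs) {
  if (is.null(rs) || inherits(rs, "region_spec")) rs else read_region_spec(rs)
}

# Terminal residue-node indices (first/last n residues of each chain).
terminal_nodes <- function(nodes, n_trim) {
  if (n_trim < 1) return(integer(0))
  info <- nodes$info
  out <- integer(0)
  for (ch in unique(info$chain)) {
    ix <- which(info$chain == ch & !info$is_hetero)
    if (!length(ix)) next
    res <- unique(info$resno[ix])
    trim <- c(utils::head(res, n_trim), utils::tail(res, n_trim))
    out <- c(out, ix[info$resno[ix] %in% trim])
  }
  out
}

provenance_record <- function(config, extra = list()) {
  cfg <- unclass(config)
  cfg$input <- if (is.character(cfg$input)) cfg$input else
    paste0("<structure: ", cfg$input$provenance, ">")
  cfg$region_spec <- if (is.character(cfg$region_spec)) cfg$region_spec
    else if (is.null(cfg$region_spec)) NULL else "<region_spec object>"
  hashed <- cfg
  hashed$outdir <- NULL   # analysis identity must not depend on output paths
  json <- jsonlite::toJSON(hashed, auto_unbox = TRUE, digits = NA,
                           null = "null")
  tf <- tempfile(); writeLines(json, tf); on.exit(unlink(tf))
  c(list(config = cfg, config_hash = unname(tools::md5sum(tf)),
         package_version = as.character(utils::packageVersion("enmaflex")),
         seed = config$seed), extra)
}

write_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prof <- result$profile_table
  utils::write.table(prof, file.path(outdir, "profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(result$region_report))
    utils::write.table(result$region_report,
                       file.path(outdir, "regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(result$mode_table, file.path(outdir, "modes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$provenance, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(outdir)
}

#' Flexibility pipeline for a single system
#'
#' Reads or accepts a structure, builds the elastic network at the
#' configured cutoff, solves the RTB normal modes, and reports the MSF /
#' relative-RMSF / B-factor profile plus region and layer means when a
#' region specification is provided. All outputs are deterministic given
#' the configuration.
#'
#' @param config a [run_config()].
#' @return list with `nodes`, `network`, `modes`, `profile`
#'   (a `flex_profile`), `profile_table` (per-residue TSV-ready table),
#'   `region_report`, `bfit` (fit against experimental B-factors when the
#'   input carries them), `mode_table`, `provenance`.
#' @export
run_flexibility <- function(config) {
  stopifnot(inherits(config, "run_config"))
  struct <- resolve_input(config$input)
  nodes <- select_nodes(struct, scheme = config$scheme)
  net <- build_network(nodes, cutoff = config$cutoff)
  part <- make_blocks(nodes, config$residues_per_block)
  modes <- solve_modes(hessian(net), nodes, partition = part)
  prof <- flexibility_profile(modes, n_v = config$n_v)

  rs <- resolve_region_spec(config$region_spec)
  assignment <- NULL
  report <- NULL
  if (!is.null(rs)) {
    assignment <- assign_regions(struct, nodes, rs)
    report <- region_layer_report(prof$rmsf_rel, assignment, nodes)
  }

  # fit to experimental B-factors when the structure carries any
  bfit <- NULL
  b_exp <- node_experimental_b(struct, nodes)
  if (any(b_exp > 0)) {
    excl <- terminal_nodes(nodes, config$exclude_termini)
    bfit <- rescale_to_experiment(prof$b_calc, b_exp, exclude = excl)
  }

  tab <- data.frame(chain = nodes$info$chain, resno = nodes$info$resno,
                    resid = nodes$info$resid, name = nodes$info$name,
                    msf = prof$msf, rmsf_rel = prof$rmsf_rel,
                    b_calc = prof$b_calc,
                    b_fit = if (is.null(bfit)) NA_real_ else bfit$fitted,
                    b_exp = b_exp)
  result <- list(structure = struct, nodes = nodes, network = net,
                 modes = modes, profile = prof, profile_table = tab,
                 assignment = assignment, region_report = report,
                 bfit = bfit, mode_table = mode_summary(modes),
                 provenance = provenance_record(config, list(
                   n_nodes = n_nodes(nodes), n_springs = nrow(net$springs),
                   n_zero = modes$n_zero)))
  if (!is.null(config$outdir)) write_outputs(result, config$outdir)
  invisible(result)
}

# Experimental B of each node (atom B in all-heavy mode, CA B per residue
# in C-alpha mode, mean over atoms for hetero groups).
node_experimental_b <- function(struct, nodes) {
  at <- struct$atoms
  key_at <- paste(residue_key(at), at$name)
  key_nd <- paste(nodes$info$chain, nodes$info$resno, nodes$info$insert,
                  sep = "|")
  key_nd <- paste(key_nd, nodes$info$name)
  b <- at$b[match(key_nd, key_at)]
  b[is.na(b)] <- 0
  b
}

#' Flexibility pipeline for a crystallographic oligomer
#'
#' Expands a structure by symmetry operators, then runs the standard
#' pipeline at the oligomer cutoff (default 8 A). When `central_chains` is
#' given, the B-factor fit is restricted to those chains, mirroring the
#' validation of a crystal-packed central monomer against X-ray data.
#'
#' @param config a [run_config()] (its `cutoff` defaults to the monomer
#'   value; pass `cutoff = 8` for oligomers).
#' @param operators,copies,lattice forwarded to [apply_symmetry()]; the
#'   identity-only selection degenerates to a plain monomer run.
#' @param central_chains chains (after relabeling) for the restricted fit.
#' @return as [run_flexibility()], plus `oligomer` (the expanded
#'   structure) and `central_fit`.
#' @export
run_oligomer <- function(config, operators = NULL, copies = NULL,
                         lattice = NULL, central_chains = NULL) {
  stopifnot(inherits(config, "run_config"))
  struct <- resolve_input(config$input)
  olig <- apply_symmetry(struct, operators = operators, copies = copies,
                         lattice = lattice)
  cfg2 <- config
  cfg2$input <- olig
  result <- run_flexibility(cfg2)
  result$oligomer <- olig
  if (!is.null(central_chains)) {
    sel <- which(result$nodes$info$chain %in% central_chains)
    b_exp <- node_experimental_b(olig, result$nodes)
    if (any(b_exp[sel] > 0)) {
      excl <- setdiff(seq_len(n_nodes(result$nodes)), sel)
      excl <- union(excl, terminal_nodes(result$nodes,
                                         config$exclude_termini))
      result$central_fit <- rescale_to_experiment(result$profile$b_calc,
                                                  b_exp, exclude = excl)
    }
  }
  result
}

#' Flexibility pipeline for a membrane-embedded system
#'
#' Builds the bilayer-slab surrogate, embeds the (pre-oriented) protein,
#' and runs the normal-mode pipeline on the combined system; lipid nodes
#' are ordinary network nodes with one RTB block each. When a free-monomer
#' mode set is supplied, a mode-match table against it is included.
#'
#' @param config a [run_config()].
#' @param slab a `node_set` from [build_bilayer_slab()] (default: the 80 x
#'   80 A slab).
#' @param clash_radius lipid removal radius (Angstrom, default 3).
#' @param free_result optional result of [run_flexibility()] on the free
#'   monomer, for mode matching and contact-RMSF comparison.
#' @return list with `embedded`, `modes`, `profile`, `contact_nodes`,
#'   `mode_match` (when `free_result` given), `contact_rmsf_change`,
#'   `provenance`.
#' @export
run_membrane <- function(config, slab = build_bilayer_slab(),
                         clash_radius = 3, free_result = NULL) {
  stopifnot(inherits(config, "run_config"))
  struct <- resolve_input(config$input)
  nodes <- select_nodes(struct, scheme = config$scheme)
  heavy <- as.matrix(struct$atoms[, c("x", "y", "z")])
  emb <- embed_protein(nodes, slab, clash_radius = clash_radius,
                       heavy_xyz = heavy)
  struts <- membrane_struts(emb$nodes,
                            lateral = attr(slab, "spacing") %||% 5)
  net <- build_network(emb$nodes, cutoff = config$cutoff,
                       extra_pairs = struts)
  part <- make_blocks(emb$nodes, config$residues_per_block)
  modes <- solve_modes(hessian(net), emb$nodes, partition = part)
  prof <- flexibility_profile(modes, n_v = config$n_v)
  contacts <- membrane_contacts(emb)
  out <- list(embedded = emb, network = net, modes = modes, profile = prof,
              contact_nodes = contacts,
              provenance = provenance_record(config, list(
                n_lipid_removed = emb$n_removed,
                n_nodes = n_nodes(emb$nodes))))
  if (!is.null(free_result)) {
    prot <- seq_len(emb$n_protein)
    out$mode_match <- match_modes(free_result$modes, modes,
                                  free_result$nodes, emb$nodes,
                                  shared_a = prot, shared_b = prot,
                                  modes_a = internal_modes(free_result$modes,
                                                           10),
                                  modes_b = internal_modes(modes, 30))
    # relative RMSF of membrane-contacting residues, renormalized over the
    # shared protein nodes so free and embedded profiles are comparable
    free_rel <- relative_rmsf(free_result$profile$msf[prot], prot)
    emb_rel <- relative_rmsf(prof$msf[prot], prot)
    out$contact_rmsf_change <- mean(emb_rel[contacts]) -
      mean(free_rel[contacts])
  }
  invisible(out)
}
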