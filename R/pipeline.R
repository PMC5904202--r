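#' @title Pipeline orchestration
#' @description End-to-end drivers: `cmd_compare()` for multi-crystal
#'   ensemble comparison (loop-shift matrices, displacement profiles,
#'   lattice-contact freedom) and `cmd_flex()` for the flexibility pipeline
#'   (constraint network at the energy cutoff, pebble-game rigidity,
#'   elastic-network modes, 2 x n_modes geometric simulations, loop apex
#'   amplitude report). Both write TSV/CSV outputs plus a run log with full
#'   parameter and input provenance.
#' @name cli_pipeline
NULL

#' Pipeline configuration
#'
#' Defaults reproduce the study settings: energy cutoff -3 kcal/mol, 12
#' Angstrom elastic-network cutoff, 10 nontrivial modes, 2000-frame cap,
#' 4.0 Angstrom lattice-contact rule.
#'
#' @param e_cut polar-interaction energy cutoff, kcal/mol.
#' @param enm_cutoff elastic-network spring cutoff, Angstrom.
#' @param n_modes number of nontrivial modes simulated.
#' @param contact_cutoff lattice-contact distance, Angstrom.
#' @param domain_range stable-base interval for loop alignment.
#' @param sim [sim_params()].
#' @param seed integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(e_cut = -3.0, enm_cutoff = 12, n_modes = 10,
                            contact_cutoff = 4.0, domain_range = c(6, 110),
                            sim = sim_params(), seed = 1L) {
  structure(list(e_cut = e_cut, enm_cutoff = enm_cutoff, n_modes = n_modes,
                 contact_cutoff = contact_cutoff, domain_range = domain_range,
                 sim = sim, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a flat key=value configuration file
#'
#' Recognised keys: `e_cut`, `enm_cutoff`, `n_modes`, `contact_cutoff`,
#' `domain_start`, `domain_end`, `step_size`, `relax_tolerance`,
#' `max_relax_iters`, `max_frames`, `steric_scale`, `seed`. Unknown keys are
#' an error (catches typos silently changing a run).
#'
#' @param path config file path.
#' @param base a [pipeline_config()] supplying defaults.
#' @return Updated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, base = pipeline_config()) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln)
    key <- trimws(kv[1]); val <- as.numeric(trimws(kv[2]))
    switch(key,
      e_cut = { base$e_cut <- val },
      enm_cutoff = { base$enm_cutoff <- val },
      n_modes = { base$n_modes <- as.integer(val) },
      contact_cutoff = { base$contact_cutoff <- val },
      domain_start = { base$domain_range[1] <- val },
      domain_end = { base$domain_range[2] <- val },
      step_size = { base$sim$step_size <- val },
      relax_tolerance = { base$sim$relax_tolerance <- val },
      max_relax_iters = { base$sim$max_relax_iters <- as.integer(val) },
      max_frames = { base$sim$max_frames <- as.integer(val) },
      steric_scale = { base$sim$steric_scale <- val },
      seed = { base$seed <- as.integer(val); base$sim$seed <- as.integer(val) },
      stop("unknown config key: ", key)
    )
  }
  base
}

write_run_log <- function(out_dir, config, inputs, extra = list()) {
  lines <- c(
    paste0("timestamp\t", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed\t", config$seed),
    paste0("e_cut\t", config$e_cut),
    paste0("enm_cutoff\t", config$enm_cutoff),
    paste0("n_modes\t", config$n_modes),
    paste0("contact_cutoff\t", config$contact_cutoff),
    paste0("domain_range\t", paste(config$domain_range, collapse = "-")),
    paste0("step_size\t", config$sim$step_size),
    paste0("relax_tolerance\t", config$sim$relax_tolerance),
    paste0("max_relax_iters\t", config$sim$max_relax_iters),
    paste0("max_frames\t", config$sim$max_frames),
    paste0("steric_scale\t", config$sim$steric_scale)
  )
  for (p in inputs) {
    if (file.exists(p)) {
      lines <- c(lines, paste0("input\t", p, "\tmd5=", unname(tools::md5sum(p))))
    } else {
      lines <- c(lines, paste0("input\t", p, "\t(in-memory)"))
    }
  }
  for (k in names(extra)) lines <- c(lines, paste0(k, "\t", extra[[k]]))
  writeLines(lines, file.path(out_dir, "run_log.tsv"))
}

resolve_structures <- function(structures) {
  lapply(structures, function(s) {
    if (inherits(s, "tcr_structure")) s else read_pdb(s)
  })
}

#' Compare crystal structures of the same protein
#'
#' For every loop: the pairwise maximal loop CA shift matrix (fit on the
#' chain's stable base) and, when cell metadata and operators are available,
#' the lattice-contact freedom table per structure. A summary names the
#' maximally shifting loop and its extreme conformer pair.
#'
#' @param structures list of `tcr_structure`s or PDB paths (>= 2).
#' @param loops loop-definition data frame (see [read_loop_definitions()]).
#' @param config [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param operators optional explicit symmetry operators for the contact
#'   analysis.
#' @return Invisibly, a list: `shift_matrices` (per loop), `summary` data
#'   frame, `contact_freedom` (per structure, or NULL).
#' @export
cmd_compare <- function(structures, loops, config = pipeline_config(),
                        out_dir = ".", operators = NULL) {
  if (length(structures) < 2) stop("need at least 2 structures to compare")
  paths <- vapply(structures, function(s)
    if (is.character(s)) s else "(in-memory)", character(1))
  structures <- resolve_structures(structures)
  chains <- lapply(structures, function(s) sort(unique(s$atoms$chain_id)))
  if (!all(vapply(chains, identical, logical(1), chains[[1]]))) {
    stop("structures have mismatched chains")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  validate_loops(loops, structures[[1]])
  shift_matrices <- list()
  summary_rows <- list()
  for (i in seq_len(nrow(loops))) {
    lp <- loops[i, ]
    base <- stable_base(loops, lp$chain_id, config$domain_range)
    M <- pairwise_loop_shift_matrix(structures, lp, base)
    shift_matrices[[lp$loop_name]] <- M
    utils::write.csv(M, file.path(out_dir, paste0("shift_", lp$loop_name, ".csv")))
    pair <- attr(M, "extreme_pair")
    summary_rows[[i]] <- data.frame(
      loop_name = lp$loop_name, chain_id = lp$chain_id,
      max_shift = attr(M, "max_shift"),
      conformer_1 = structures[[pair[1]]]$id,
      conformer_2 = structures[[pair[2]]]$id)
  }
  summary <- do.call(rbind, summary_rows)
  summary <- summary[order(-summary$max_shift), ]
  rownames(summary) <- NULL
  utils::write.table(summary, file.path(out_dir, "loop_shift_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  contact_freedom <- NULL
  has_cell <- vapply(structures, function(s) !is.null(s$cell), logical(1))
  if (all(has_cell)) {
    contact_freedom <- lapply(structures, function(s) {
      ct <- try(find_crystal_contacts(s, operators, config$contact_cutoff),
                silent = TRUE)
      if (inherits(ct, "try-error")) return(NULL)
      cf <- loop_contact_freedom(ct, loops)
      utils::write.table(cf, file.path(out_dir, paste0("contacts_", s$id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cf
    })
    names(contact_freedom) <- vapply(structures, function(s) s$id, character(1))
  }
  write_run_log(out_dir, config, paths,
                extra = list(max_shift_loop = summary$loop_name[1],
                             max_shift = sprintf("%.3f", summary$max_shift[1])))
  invisible(list(shift_matrices = shift_matrices, summary = summary,
                 contact_freedom = contact_freedom))
}

#' Run the full flexibility pipeline on one structure
#'
#' Constraint network at `e_cut` -> pebble-game rigidity -> rigid-unit
#' templates -> elastic-network modes -> one geometric simulation per
#' (mode, direction) -> stable-base alignment and loop apex amplitudes.
#'
#' @param structure a `tcr_structure` or PDB path.
#' @param loops loop-definition data frame.
#' @param config [pipeline_config()].
#' @param out_dir output directory.
#' @param method amplitude definition, see [apex_amplitude()].
#' @return Invisibly, a list: `report` (`amplitude_report`), `amplitudes`
#'   (named vector), `ensembles`, `variants`, `decomposition`, `mode_set`.
#' @export
cmd_flex <- function(structure, loops, config = pipeline_config(),
                     out_dir = ".", method = "max_pairwise") {
  path <- if (is.character(structure)) structure else "(in-memory)"
  if (is.character(structure)) structure <- read_pdb(structure)
  structure <- filter_protein(structure)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  validate_loops(loops, structure)
  np <- network_params(e_cut = config$e_cut)
  network <- apply_energy_cutoff(build_constraint_network(structure, np))
  decomposition <- pebble_game(network)
  templates <- build_templates(structure, decomposition, network)
  ep <- enm_params(cutoff = config$enm_cutoff,
                   n_nontrivial_modes = config$n_modes)
  mode_set <- enm_modes(network$structure, ep)
  sim <- config$sim
  sim$seed <- config$seed
  ensembles <- run_all_modes(network$structure, network, templates, mode_set, sim)
  jammed0 <- vapply(ensembles, function(e)
    e$termination == "jammed" && e$n_frames == 0, logical(1))
  if (any(jammed0)) {
    message("mode(s) jammed at frame 0: ",
            paste(vapply(ensembles[jammed0], function(e)
      sprintf("%d%+d", e$mode_index, e$direction), character(1)),
      collapse = ", "))
  }
  variants <- select_extreme_variants(ensembles)
  amplitudes <- measure_loop_amplitudes(variants, network$structure, loops,
                                        config$domain_range, method)
  report <- amplitude_report(matrix(amplitudes, ncol = 1,
                                    dimnames = list(names(amplitudes),
                                                    structure$id)))
  # outputs
  write_network_tsv(network, file.path(out_dir, "network.tsv"))
  write_decomposition_tsv(decomposition, file.path(out_dir, "clusters.tsv"))
  write_modes_tsv(mode_set, file.path(out_dir, "modes.tsv"))
  write_amplitude_report(report, file.path(out_dir, "amplitude_report.tsv"),
                         method = method)
  write_pdb(network$structure, file.path(out_dir, "variants.pdb"),
            multi_model = lapply(variants, `[[`, "coords"))
  diag <- do.call(rbind, lapply(ensembles, function(e) {
    cbind(mode_index = e$mode_index, direction = e$direction,
          termination = e$termination, e$diagnostics)
  }))
  utils::write.table(diag, file.path(out_dir, "simulation_diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_log(out_dir, config, path,
                extra = list(structure = structure$id,
                             n_variants = length(variants),
                             floppy_modes = decomposition$floppy_modes,
                             mean_amplitude = sprintf("%.3f", mean(amplitudes))))
  invisible(list(report = report, amplitudes = amplitudes,
                 ensembles = ensembles, variants = variants,
                 decomposition = decomposition, mode_set = mode_set))
}
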