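#' Read and validate a pipeline configuration
#'
#' A single JSON file drives the pipeline commands. Recognised fields
#' (all optional unless a command needs them): `seed` (required),
#' `sequences` (FASTA path) or `generator`
#' (`n_strains`, `divergence`, `families`), `instrument` (overrides for
#' [instrument_model()]), `mass_constants` (overrides, see
#' [mass_constants_from_json()]), `mixture` (list of `label`/`weight`, or
#' `n_random` for seeded random hexamer weights), `assignment`
#' (`max_pct_error`, `z_min`, `z_max`, `min_states`, `cluster_tol_ppm`),
#' `spectrum` (CSV path), `alignment` (aligned FASTA path), `structure`
#' (PDB/mmCIF path), `grouping`, `chain_map`, `chain_roles`,
#' `interface_columns`, `cutoff`.
#'
#' @param path Path to the JSON config.
#' @return Object of class `pipeline_config` (a validated list, with the
#'   file's md5 hash attached for provenance).
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(cfg$seed)) stop("config must set a 'seed' for reproducibility")
  cfg$seed <- as.integer(cfg$seed)
  for (f in c("sequences", "spectrum", "alignment", "structure")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop(sprintf("config path '%s' (%s) does not exist", cfg[[f]], f))
    }
  }
  cfg$config_hash <- unname(tools::md5sum(path))
  class(cfg) <- "pipeline_config"
  cfg
}

config_constants <- function(config) {
  if (is.null(config$mass_constants)) return(mass_constants())
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config$mass_constants, tmp, auto_unbox = TRUE)
  mass_constants_from_json(tmp)
}

config_instrument <- function(config) {
  args <- config$instrument
  if (is.null(args)) args <- list()
  if (is.null(args$seed)) args$seed <- config$seed
  do.call(instrument_model, args)
}

config_sequences <- function(config) {
  if (!is.null(config$sequences)) return(read_subunit_fasta(config$sequences))
  g <- config$generator
  if (is.null(g)) stop("config needs either 'sequences' or a 'generator' block")
  gen <- generate_strain_set(
    n_strains = if (is.null(g$n_strains)) 2L else as.integer(g$n_strains),
    divergence = if (is.null(g$divergence)) 0.05 else g$divergence,
    seed = config$seed,
    families = if (is.null(g$families)) c("APC", "PC") else unlist(g$families)
  )
  gen$sequences
}

provenance_block <- function(config) {
  list(
    config_hash = config$config_hash,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("phycomix"))
  )
}

#' Simulate a spectrum from a pipeline config
#'
#' Builds (or reads) the strain sequence set, constructs the configured
#' mixture of theoretical complexes, renders the spectrum and writes
#' `spectrum.csv` and `truth.csv` to `out_dir`. Fully deterministic given
#' the config and its seed.
#'
#' @param config A [read_pipeline_config()] object (or path to one).
#' @param out_dir Output directory (created if missing).
#' @return List with the `synthetic_spectrum`, the truth table and output
#'   paths.
#' @export
run_simulate <- function(config, out_dir = tempfile("phycomix_sim_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  constants <- config_constants(config)
  model <- config_instrument(config)
  seqs <- config_sequences(config)
  cands <- candidate_table(seqs, constants, n_dimers = 3L, include_decoys = FALSE)

  mix_cfg <- config$mixture
  if (!is.null(mix_cfg) && !is.null(mix_cfg$members)) {
    labels <- vapply(mix_cfg$members, `[[`, character(1L), "label")
    weights <- vapply(mix_cfg$members, `[[`, numeric(1L), "weight")
    idx <- match(labels, cands$label)
    if (anyNA(idx)) stop("mixture label(s) not in the candidate table: ",
                         paste(labels[is.na(idx)], collapse = ", "))
    masses <- cands$neutral_mass[idx]
  } else {
    # seeded random weights over the pure/heterologous hexamers per family
    base <- cands[!duplicated(cands$label), , drop = FALSE]
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(config$seed + 7L)
    weights <- stats::runif(nrow(base))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    labels <- base$label
    masses <- base$neutral_mass
  }
  mixture <- mixture_spec(masses, weights, labels)
  spec <- render_spectrum(mixture, model, seed = config$seed)
  spath <- file.path(out_dir, "spectrum.csv")
  tpath <- file.path(out_dir, "truth.csv")
  write_spectrum(spec, spath)
  utils::write.csv(spec$truth, tpath, row.names = FALSE)
  jsonlite::write_json(provenance_block(config),
                       file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  list(spectrum = spec, truth = spec$truth,
       paths = list(spectrum = spath, truth = tpath))
}

#' Assign a spectrum from a pipeline config
#'
#' Chains proteoform mass calculation, candidate enumeration, peak picking,
#' charge-series deconvolution, candidate matching and quantification. When
#' the config has no `spectrum` path, the candidate table alone is written
#' (candidates-only run).
#'
#' @param config A [read_pipeline_config()] object (or path to one).
#' @param spectrum Optional spectrum (list with `mz`, `intensity`)
#'   overriding the config's `spectrum` path.
#' @param out_dir Output directory for stage artifacts.
#' @param include_decoys Enumerate decoy candidates.
#' @param verbose Log accepted/rejected matches.
#' @return A run report: list with `proteoforms`, `candidates`,
#'   `assignments`, `abundance` (NULL in candidates-only runs) and
#'   `provenance`.
#' @export
run_assign <- function(config, spectrum = NULL,
                       out_dir = tempfile("phycomix_assign_"),
                       include_decoys = TRUE, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  constants <- config_constants(config)
  seqs <- config_sequences(config)
  pf <- proteoform_table(seqs, constants)
  cands <- candidate_table(seqs, constants, include_decoys = include_decoys)
  write_candidate_table(cands, file.path(out_dir, "candidates.csv"))
  utils::write.csv(pf, file.path(out_dir, "proteoforms.csv"), row.names = FALSE)

  if (is.null(spectrum) && !is.null(config$spectrum)) {
    spectrum <- read_spectrum(config$spectrum)
  }
  report <- list(proteoforms = pf, candidates = cands, assignments = NULL,
                 abundance = NULL, provenance = provenance_block(config))
  if (is.null(spectrum)) return(report)

  asn_cfg <- config$assignment
  if (is.null(asn_cfg)) asn_cfg <- list()
  get_or <- function(name, default) {
    if (is.null(asn_cfg[[name]])) default else asn_cfg[[name]]
  }
  centroids <- pick_centroids(spectrum, snr_threshold = get_or("snr_threshold", 5))
  series <- infer_charge_series(
    centroids,
    z_range = c(get_or("z_min", 5L), get_or("z_max", 40L)),
    cluster_tol_ppm = get_or("cluster_tol_ppm", 50),
    min_states = get_or("min_states", 3L),
    proton_mass = constants$proton_mass
  )
  max_pct <- get_or("max_pct_error", 0.1)
  assignments <- lapply(series, match_series, candidates = cands,
                        max_pct_error = max_pct)
  if (verbose) {
    for (a in assignments) {
      message(sprintf("series M=%.2f Da -> %s (%d candidates <= %.3g%%)",
                      a$series$neutral_mass, a$status, nrow(a$candidates), max_pct))
      for (k in seq_len(nrow(a$candidates))) {
        message(sprintf("  %s %s: %.4f%% (%.1f ppm)%s",
                        a$candidates$label[k], a$candidates$variant_key[k],
                        a$candidates$percent_error[k], a$candidates$ppm_error[k],
                        if (a$candidates$is_decoy[k]) " [decoy]" else ""))
      }
    }
  }
  report$assignments <- assignments
  assigned <- Filter(function(a) a$status != "unassigned", assignments)
  if (length(assigned)) {
    report$abundance <- quantify(assignments)
    utils::write.csv(report$abundance$per_composition,
                     file.path(out_dir, "abundance.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  report
}

#' Interface conservation from a pipeline config
#'
#' Scores identity/similarity over interface columns. The columns either
#' come directly from the config (`interface_columns`) or are derived from
#' a structure by contact analysis (`structure` + `grouping` + `chain_map`).
#'
#' @param config A [read_pipeline_config()] object (or path to one).
#' @return List with `summary` (per role, or overall when columns were
#'   given directly), `columns` and `provenance`.
#' @export
run_conserve <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$alignment)) stop("config needs an 'alignment' path")
  aln <- read_alignment(config$alignment)
  if (!is.null(config$interface_columns)) {
    cols <- as.integer(unlist(config$interface_columns))
    summary <- interface_conservation_summary(aln, cols)
    return(list(summary = summary, columns = cols,
                provenance = provenance_block(config)))
  }
  if (is.null(config$structure)) {
    stop("config needs 'interface_columns' or a 'structure' path")
  }
  if (is.null(config$chain_map)) {
    stop("config needs a 'chain_map' (chain id -> alignment row) to project contacts")
  }
  if (is.null(config$grouping)) {
    stop("config needs a 'grouping' (chain id -> dimer index)")
  }
  struct <- read_structure(config$structure)
  cols_by_role <- derive_interface_columns(
    struct, config$grouping, aln, config$chain_map,
    cutoff = if (is.null(config$cutoff)) 3.0 else config$cutoff,
    chain_roles = config$chain_roles
  )
  summaries <- lapply(cols_by_role, function(cols) {
    interface_conservation_summary(aln, cols)
  })
  list(summary = summaries, columns = cols_by_role,
       provenance = provenance_block(config))
}
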