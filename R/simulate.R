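#' Instrument model for synthetic native-MS spectra
#'
#' Parameters of the simulated Orbitrap-like measurement: acquisition
#' window, resolving power at the m/z 400 reference (decaying as
#' 1/sqrt(m/z)), the charge-envelope model, baseline noise and the sampling
#' grid.
#'
#' @param mz_min,mz_max Acquisition window, m/z (defaults 1000-8000).
#' @param resolution_ref Resolving power at m/z 400 (default 7500).
#' @param envelope_center_scale Multiplier on the electrospray charge
#'   scaling z0 = 0.078 sqrt(M).
#' @param envelope_width Gaussian width of the charge envelope, in charge
#'   units.
#' @param noise_sd Baseline noise standard deviation, relative to the
#'   maximum clean signal (0 disables noise).
#' @param grid_step Spacing of the uniform m/z grid.
#' @param seed Default RNG seed used by [render_spectrum()].
#' @return Object of class `instrument_model`.
#' @export
instrument_model <- function(mz_min = 1000, mz_max = 8000,
                             resolution_ref = 7500,
                             envelope_center_scale = 1.0,
                             envelope_width = 1.5,
                             noise_sd = 0,
                             grid_step = 0.25,
                             seed = 1L) {
  stopifnot(mz_min < mz_max, resolution_ref > 0, grid_step > 0,
            envelope_width > 0, noise_sd >= 0)
  structure(
    list(mz_min = mz_min, mz_max = mz_max, resolution_ref = resolution_ref,
         envelope_center_scale = envelope_center_scale,
         envelope_width = envelope_width, noise_sd = noise_sd,
         grid_step = grid_step, seed = as.integer(seed)),
    class = "instrument_model"
  )
}

#' m/z of a protonated ion
#'
#' Positive-ion electrospray convention: m/z = (M + z * m_proton) / z.
#'
#' @param M Neutral mass, Da.
#' @param z Integer charge (>= 1).
#' @param proton_mass Proton mass, Da.
#' @return m/z value(s).
#' @export
mass_to_mz <- function(M, z, proton_mass = 1.00728) {
  stopifnot(all(M > 0))
  if (any(z < 1) || any(z != as.integer(z))) stop("charge z must be an integer >= 1")
  (M + z * proton_mass) / z
}

#' Neutral mass from an m/z value and charge
#'
#' Algebraic inverse of [mass_to_mz()].
#'
#' @param mz m/z value(s).
#' @param z Integer charge (>= 1).
#' @param proton_mass Proton mass, Da.
#' @return Neutral mass, Da.
#' @export
neutral_mass_from_mz <- function(mz, z, proton_mass = 1.00728) {
  if (any(z < 1) || any(z != as.integer(z))) stop("charge z must be an integer >= 1")
  z * mz - z * proton_mass
}

#' Charge-state envelope of a neutral mass
#'
#' Discrete Gaussian over integer charges, centred at
#' z0 = `envelope_center_scale` * 0.078 * sqrt(M) (the usual electrospray
#' scaling for natively folded proteins), truncated to charges whose m/z
#' falls inside the acquisition window, and normalised to sum 1.
#'
#' @param M Neutral mass, Da.
#' @param model An [instrument_model()].
#' @return Data frame with columns `z` and `weight`.
#' @export
charge_envelope <- function(M, model = instrument_model()) {
  stopifnot(M > 0)
  z0 <- model$envelope_center_scale * 0.078 * sqrt(M)
  z_lo <- max(1L, ceiling(M / (model$mz_max - 1.00728)))
  z_hi <- floor(M / (model$mz_min - 1.00728))
  if (z_hi < z_lo) {
    stop(sprintf("no integer charge places mass %.1f Da inside [%g, %g] m/z",
                 M, model$mz_min, model$mz_max))
  }
  z <- z_lo:z_hi
  w <- stats::dnorm(z, mean = z0, sd = model$envelope_width)
  if (sum(w) <= 0) {
    # envelope centre far outside the window; fall back to nearest charge
    w <- as.numeric(z == z[which.min(abs(z - z0))])
  }
  data.frame(z = z, weight = w / sum(w))
}

resolution_at <- function(mz, model) {
  model$resolution_ref * sqrt(400 / mz)
}

#' Specify a mixture of complexes for spectrum synthesis
#'
#' @param masses Numeric vector of neutral masses, Da.
#' @param weights Non-negative abundance weights (normalised internally).
#' @param labels Optional species labels.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(masses, weights, labels = NULL) {
  stopifnot(length(masses) == length(weights), all(weights >= 0), any(weights > 0),
            all(masses > 0))
  if (is.null(labels)) labels <- sprintf("species_%d", seq_along(masses))
  structure(
    list(members = data.frame(label = labels, mass = masses,
                              weight = weights / sum(weights),
                              stringsAsFactors = FALSE)),
    class = "mixture_spec"
  )
}

#' Render a synthetic profile-mode spectrum
#'
#' For each mixture member and each charge in its envelope, adds a Gaussian
#' peak at the protonated m/z with FWHM = mz / R(mz), where
#' R(mz) = `resolution_ref` * sqrt(400 / mz). Peak area is proportional to
#' member weight times envelope weight, so with noise off the integrated
#' intensity (sum times grid step) equals the sum of normalised weights.
#' Seeded Gaussian baseline noise is added when `noise_sd > 0`; identical
#' seeds give bit-identical spectra. The caller's RNG state is left
#' untouched.
#'
#' @param mixture A [mixture_spec()].
#' @param model An [instrument_model()].
#' @param seed RNG seed; defaults to `model$seed`.
#' @return Object of class `synthetic_spectrum`: list with `mz`,
#'   `intensity`, `truth` (member table with modal charge) and `model`.
#' @export
render_spectrum <- function(mixture, model = instrument_model(), seed = model$seed) {
  stopifnot(inherits(mixture, "mixture_spec"), inherits(model, "instrument_model"))
  if (is.null(seed)) stop("a seed is required for reproducible spectrum synthesis")
  mz <- seq(model$mz_min, model$mz_max, by = model$grid_step)
  intensity <- numeric(length(mz))
  members <- mixture$members
  modal_z <- integer(nrow(members))
  provenance <- vector("list", nrow(members))
  for (i in seq_len(nrow(members))) {
    env <- charge_envelope(members$mass[i], model)
    modal_z[i] <- env$z[which.max(env$weight)]
    centers <- mass_to_mz(members$mass[i], env$z)
    fwhm <- centers / resolution_at(centers, model)
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    for (j in seq_along(centers)) {
      lo <- max(1L, ceiling((centers[j] - 6 * sigma[j] - model$mz_min) / model$grid_step) + 1L)
      hi <- min(length(mz), floor((centers[j] + 6 * sigma[j] - model$mz_min) / model$grid_step) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      area <- members$weight[i] * env$weight[j]
      intensity[idx] <- intensity[idx] +
        area * stats::dnorm(mz[idx], mean = centers[j], sd = sigma[j]) * model$grid_step
    }
    provenance[[i]] <- data.frame(label = members$label[i], z = env$z,
                                  mz = centers, envelope_weight = env$weight)
  }
  intensity <- intensity / model$grid_step
  if (model$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    sigma <- model$noise_sd * max(intensity)
    # constant offset of 3 noise SDs emulates a detector noise floor and
    # keeps the trace non-negative without distorting the noise statistics
    intensity <- intensity + 3 * sigma +
      stats::rnorm(length(intensity), 0, sigma)
    intensity <- pmax(intensity, 0)
  }
  truth <- members
  truth$modal_z <- modal_z
  structure(
    list(mz = mz, intensity = intensity, truth = truth,
         peaks = do.call(rbind, provenance), model = model, seed = seed),
    class = "synthetic_spectrum"
  )
}

#' @export
print.synthetic_spectrum <- function(x, ...) {
  cat(sprintf("<synthetic_spectrum> %d points, %g-%g m/z, %d species, seed %d\n",
              length(x$mz), min(x$mz), max(x$mz), nrow(x$truth), x$seed))
  invisible(x)
}

#' Write a spectrum as two-column CSV
#'
#' @param spectrum A `synthetic_spectrum` or any list with `mz` and
#'   `intensity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(data.frame(mz = spectrum$mz, intensity = spectrum$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column (m/z, intensity) spectrum
#'
#' Accepts CSV with a header or plain two-column whitespace text.
#'
#' @param path Input path.
#' @return List with `mz` and `intensity` (ascending m/z).
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1L)
  df <- if (grepl(",", first, fixed = TRUE)) {
    utils::read.csv(path)
  } else {
    utils::read.table(path, header = grepl("[A-Za-z]", first))
  }
  if (ncol(df) < 2L) stop("spectrum file must have two columns (m/z, intensity)")
  ord <- order(df[[1L]])
  list(mz = as.numeric(df[[1L]][ord]), intensity = as.numeric(df[[2L]][ord]))
}

#' Synthetic base sequences for the strain-family generator
#'
#' Fixed, explicitly synthetic subunit sequences with realistic lengths
#' (APC alpha/beta 161/161 aa, PC alpha/beta 162/172 aa), amino-acid
#' composition and unmodified chain masses (about 17.3, 17.2, 17.6 and
#' 19.3 kDa respectively, so APC and PC dimers are separated by roughly
#' 3 kDa as in real phycobiliproteins). They are not the sequence of any
#' real organism; they anchor the synthetic strain generator so that
#' subunit, dimer and hexamer masses fall in the ranges typical of
#' phycobiliproteins.
#'
#' @return Named list with elements `APC` and `PC`, each a list with
#'   `alpha` and `beta` residue strings.
#' @export
phyco_base_sequences <- function() {
  list(
    APC = list(
      alpha = paste0(
        "MYMVFDGPADTIGMGGMCAIKYACMLISYSFGNEGLFLGYRASGHSHQDHREESNLPDAV",
        "IDCPKFGVFTGLAGIGTLEILGAEGPKGLLVDLGGGTEKPRRGGSMHPTKLGFYSKKLER",
        "FESRRTSYGGTYRDMFRNAPRALIPTNAMVATEPGDPGLAD"),
      beta = paste0(
        "MAPTQKFSASHGVVKDELSFREKQIAKHVNGGLGEAGLWNLQKSLKLGKIAAIMEGVKLG",
        "AKKRTAVMIAQGYQANSAQEVSIEILGCEAGLELQTVEELPRALIGLEQMSAVGAGILGM",
        "VDYWSSAVKMEFTPYLASDIKVNVSLNGLLHGNYSRLAPIT")
    ),
    PC = list(
      alpha = paste0(
        "MATHGALFRIEVRNAHALQKDGTIHYKLLIDSQACVLEARGTAAVPSLAICNKLIETIKK",
        "SLMLSGAIDYEFVIANDLSSTDSVVDQPSLFLADEGSQELYMIIRYANGRFAQSQGLLCI",
        "FSIGPVALAAKNAQRAYVAPGVKEAVERNMFADTLYIVFGND"),
      beta = paste0(
        "MLKKGTHKCKPDGEVYGDAALYVQPNGLLVEPVKPDGWLGDLLRKGYDDGICWSTVFSWN",
        "WKELIIVPWKIPASKIKTEFYAGIWIRGTATVSTIEGGGWTAKWTVARFKTIEHYGHQTI",
        "WGAIVPYEFGPKSFVIPLWLAGVVEIQPHEFAATKRAQFLTKMYIPIGTPTG")
    )
  )
}

substitute_sequence <- function(residues, divergence, protected) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  letters20 <- names(average_residue_masses())
  editable <- setdiff(seq_along(chars), protected)
  hit <- editable[stats::runif(length(editable)) < divergence]
  for (p in hit) {
    chars[p] <- sample(setdiff(letters20, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a diverged family of strain sequences
#'
#' Emulates strain-level sequence divergence in one phycobiliprotein
#' family: each strain substitutes residues of the base alpha and beta
#' chains independently at the given per-site rate, outside protected
#' columns. Position 1 is protected by default so the initiator methionine
#' (required by the Met-loss PTM rules) is always retained.
#'
#' @param base_alpha,base_beta Base chain residue strings.
#' @param n_strains Number of strains to generate.
#' @param divergence Per-site substitution probability in `[0, 1)`.
#' @param protected_columns 1-based positions never substituted (applied to
#'   both chains; default position 1).
#' @param seed RNG seed.
#' @param family Family tag for the emitted sequences.
#' @param strain_ids Optional strain labels.
#' @return List with `sequences` (list of [subunit_sequence()]) and `truth`
#'   (data frame of per-strain chain masses under the default PTM-free
#'   chain mass).
#' @export
generate_strain_family <- function(base_alpha, base_beta, n_strains,
                                   divergence = 0.05,
                                   protected_columns = 1L,
                                   seed = 1L, family = "PC",
                                   strain_ids = NULL) {
  stopifnot(divergence >= 0, divergence < 1, n_strains >= 1L)
  nmax <- max(nchar(base_alpha), nchar(base_beta))
  if (length(protected_columns) && any(protected_columns < 1 | protected_columns > nmax)) {
    stop("protected_columns out of sequence range")
  }
  if (is.null(strain_ids)) strain_ids <- sprintf("S%02d", seq_len(n_strains))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  seqs <- list()
  truth <- list()
  for (i in seq_len(n_strains)) {
    a <- substitute_sequence(base_alpha, divergence, protected_columns)
    b <- substitute_sequence(base_beta, divergence, protected_columns)
    sa <- subunit_sequence(strain_ids[i], family, "alpha", a)
    sb <- subunit_sequence(strain_ids[i], family, "beta", b)
    seqs <- c(seqs, list(sa, sb))
    truth[[i]] <- data.frame(
      strain_id = strain_ids[i], family = family,
      alpha_chain_mass = residue_chain_mass(sa),
      beta_chain_mass = residue_chain_mass(sb),
      stringsAsFactors = FALSE
    )
  }
  list(sequences = seqs, truth = do.call(rbind, truth))
}

#' Generate a full synthetic strain set over both families
#'
#' Convenience wrapper around [generate_strain_family()] using the bundled
#' synthetic base sequences for APC and PC.
#'
#' @param n_strains Number of strains.
#' @param divergence Per-site substitution probability.
#' @param seed RNG seed (per-family seeds are derived from it).
#' @param families Families to generate.
#' @return List with `sequences` (all subunits) and `truth`.
#' @export
generate_strain_set <- function(n_strains = 2L, divergence = 0.05, seed = 1L,
                                families = c("APC", "PC")) {
  base <- phyco_base_sequences()
  out_seqs <- list()
  out_truth <- list()
  for (k in seq_along(families)) {
    fam <- families[k]
    g <- generate_strain_family(
      base[[fam]]$alpha, base[[fam]]$beta, n_strains,
      divergence = divergence, seed = seed * 131L + k, family = fam
    )
    out_seqs <- c(out_seqs, g$sequences)
    out_truth[[k]] <- g$truth
  }
  list(sequences = out_seqs, truth = do.call(rbind, out_truth))
}
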