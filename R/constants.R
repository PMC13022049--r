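#' Average residue masses of the 20 canonical amino acids
#'
#' Standard IUPAC average masses of amino-acid residues (the monomer mass
#' minus one water), in Da. Average rather than monoisotopic masses are used
#' throughout: at the resolving powers typical of native MS of ~100 kDa
#' complexes only the average-mass envelope is observed.
#'
#' @return Named numeric vector of length 20 (one-letter codes).
#' @export
average_residue_masses <- function() {
  c(
    A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
  )
}

#' Mass constants for proteoform and complex mass calculation
#'
#' Bundles the modification masses used by the PTM rules together with the
#' residue mass table. Defaults follow the values conventionally used for
#' phycobiliproteins: a covalently bound phycocyanobilin chromophore adds
#' 586.7 Da (average mass after thioether formation), loss of the initiator
#' methionine removes 131.2 Da, and N4-methylation of the conserved
#' beta-subunit asparagine adds 14 Da.
#'
#' @param chromophore_mass Mass added per phycocyanobilin, Da.
#' @param met_loss_mass Mass removed on initiator-Met loss, Da.
#' @param methylation_mass Mass added per methylation, Da.
#' @param water_mass Mass of water (terminal H/OH), Da.
#' @param proton_mass Mass of a proton, Da.
#' @param residue_masses Named numeric vector of 20 average residue masses.
#' @return Object of class `mass_constants`.
#' @export
mass_constants <- function(chromophore_mass = 586.7,
                           met_loss_mass = 131.2,
                           methylation_mass = 14.0,
                           water_mass = 18.0153,
                           proton_mass = 1.00728,
                           residue_masses = average_residue_masses()) {
  stopifnot(
    is.numeric(chromophore_mass), chromophore_mass > 0,
    is.numeric(met_loss_mass), met_loss_mass > 0,
    is.numeric(methylation_mass), methylation_mass > 0,
    is.numeric(water_mass), water_mass > 0,
    is.numeric(proton_mass), proton_mass > 0
  )
  if (length(residue_masses) != 20L || is.null(names(residue_masses)) ||
      !setequal(names(residue_masses), names(average_residue_masses())) ||
      any(residue_masses <= 0)) {
    stop("'residue_masses' must be a positive named vector over exactly the 20 canonical one-letter codes")
  }
  structure(
    list(
      chromophore_mass = chromophore_mass,
      met_loss_mass = met_loss_mass,
      methylation_mass = methylation_mass,
      water_mass = water_mass,
      proton_mass = proton_mass,
      residue_masses = residue_masses[names(average_residue_masses())]
    ),
    class = "mass_constants"
  )
}

#' Read mass constants from a JSON configuration file
#'
#' Any subset of the `mass_constants()` fields may be given; missing fields
#' keep their defaults. `residue_masses` may override individual letters.
#'
#' @param path Path to a JSON file.
#' @return Object of class `mass_constants`.
#' @export
mass_constants_from_json <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  defaults <- mass_constants()
  rm_tab <- defaults$residue_masses
  if (!is.null(cfg$residue_masses)) {
    ov <- unlist(cfg$residue_masses)
    bad <- setdiff(names(ov), names(rm_tab))
    if (length(bad)) stop("unknown residue letters in config: ", paste(bad, collapse = ", "))
    rm_tab[names(ov)] <- ov
  }
  pick <- function(field) if (!is.null(cfg[[field]])) cfg[[field]] else defaults[[field]]
  mass_constants(
    chromophore_mass = pick("chromophore_mass"),
    met_loss_mass = pick("met_loss_mass"),
    methylation_mass = pick("methylation_mass"),
    water_mass = pick("water_mass"),
    proton_mass = pick("proton_mass"),
    residue_masses = rm_tab
  )
}

#' @export
print.mass_constants <- function(x, ...) {
  cat("Mass constants (Da):\n")
  cat(sprintf("  chromophore %+.1f, Met loss %+.1f, methylation %+.1f\n",
              x$chromophore_mass, -x$met_loss_mass, x$methylation_mass))
  cat(sprintf("  water %.4f, proton %.5f, %d residue masses\n",
              x$water_mass, x$proton_mass, length(x$residue_masses)))
  invisible(x)
}
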