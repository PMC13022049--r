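#' Construct a subunit sequence record
#'
#' A phycobiliprotein subunit: one strain, one family (allophycocyanin `APC`
#' or phycocyanin `PC`), one chain (`alpha`, `alphaB` or `beta`), and its
#' amino-acid sequence in one-letter code.
#'
#' @param strain_id Strain label, e.g. `"L.maxima"`.
#' @param family `"APC"` or `"PC"`.
#' @param chain `"alpha"`, `"alphaB"` or `"beta"`.
#' @param residues One-letter amino-acid string (canonical 20 letters only).
#' @return Object of class `subunit_sequence`.
#' @export
subunit_sequence <- function(strain_id, family, chain, residues) {
  family <- match.arg(family, c("APC", "PC"))
  chain <- match.arg(chain, c("alpha", "alphaB", "beta"))
  stopifnot(is.character(strain_id), length(strain_id) == 1L, nzchar(strain_id))
  residues <- toupper(residues)
  check_residues(residues, sprintf("%s|%s|%s", strain_id, family, chain))
  if (nchar(residues) < 1L) stop("sequence must contain at least one residue")
  structure(
    list(strain_id = strain_id, family = family, chain = chain, residues = residues),
    class = "subunit_sequence"
  )
}

check_residues <- function(residues, label) {
  letters20 <- names(average_residue_masses())
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% letters20)
  if (length(bad)) {
    stop(sprintf(
      "non-canonical residue letter(s) in %s: %s",
      label,
      paste(sprintf("'%s' at position %d", chars[bad], bad), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' @export
print.subunit_sequence <- function(x, ...) {
  cat(sprintf("<subunit_sequence> %s | %s | %s (%d aa)\n",
              x$strain_id, x$family, x$chain, nchar(x$residues)))
  invisible(x)
}

#' Read subunit sequences from a FASTA file
#'
#' Headers must follow the convention `>strain_id|family|chain`, e.g.
#' `>L.maxima|PC|beta`.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return List of [subunit_sequence()] objects.
#' @export
read_subunit_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    parts <- strsplit(trimws(header), "|", fixed = TRUE)[[1L]]
    if (length(parts) != 3L) {
      stop(sprintf("FASTA header '%s' does not follow 'strain_id|family|chain'", header))
    }
    subunit_sequence(parts[1L], parts[2L], parts[3L], as.character(set[[i]]))
  })
}

#' Write subunit sequences to a FASTA file
#'
#' @param seqs List of [subunit_sequence()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subunit_fasta <- function(seqs, path) {
  lines <- unlist(lapply(seqs, function(s) {
    c(sprintf(">%s|%s|%s", s$strain_id, s$family, s$chain), s$residues)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Neutral average mass of an unmodified polypeptide chain
#'
#' Sum of average residue masses plus one water. The accumulation is a plain
#' vectorised sum; order of terms does not affect the result beyond floating
#' point noise well below 1e-6 Da for chains of this size.
#'
#' @param seq A [subunit_sequence()] or a plain residue string.
#' @param constants A [mass_constants()] object.
#' @return Neutral average mass, Da.
#' @export
residue_chain_mass <- function(seq, constants = mass_constants()) {
  residues <- if (inherits(seq, "subunit_sequence")) seq$residues else toupper(seq)
  label <- if (inherits(seq, "subunit_sequence")) {
    sprintf("%s|%s|%s", seq$strain_id, seq$family, seq$chain)
  } else "sequence"
  if (nchar(residues) == 0L) return(constants$water_mass)
  check_residues(residues, label)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  sum(constants$residue_masses[chars]) + constants$water_mass
}

#' Construct a PTM rule
#'
#' @param n_chromophores Number of phycocyanobilin chromophores (>= 0).
#' @param met_loss `"never"`, `"always"` or `"variable"` (0 or 1 losses of
#'   the initiator methionine).
#' @param n_methylations Number of methylations (>= 0).
#' @return Object of class `ptm_rule`.
#' @export
ptm_rule <- function(n_chromophores, met_loss, n_methylations) {
  met_loss <- match.arg(met_loss, c("never", "always", "variable"))
  stopifnot(
    n_chromophores >= 0, n_chromophores == as.integer(n_chromophores),
    n_methylations >= 0, n_methylations == as.integer(n_methylations)
  )
  structure(
    list(n_chromophores = as.integer(n_chromophores), met_loss = met_loss,
         n_methylations = as.integer(n_methylations)),
    class = "ptm_rule"
  )
}

#' Default PTM rules per phycobiliprotein family and chain
#'
#' The rule table applied to theoretical subunit masses:
#' * APC alpha: 1 chromophore, initiator Met always lost.
#' * APC beta: 1 chromophore, Asn71 methylation (+14 Da), Met retained.
#' * PC alpha: 1 chromophore, Met retained.
#' * PC beta: 2 chromophores, Asn72 methylation, 0 or 1 Met losses
#'   (two proteoforms).
#'
#' `alphaB` (ApcD-type) chains follow the APC alpha rule.
#'
#' @param family `"APC"` or `"PC"`.
#' @param chain `"alpha"`, `"alphaB"` or `"beta"`.
#' @return A [ptm_rule()].
#' @export
default_ptm_rules <- function(family, chain) {
  key <- paste(family, chain, sep = "/")
  table <- list(
    "APC/alpha"  = ptm_rule(1L, "always", 0L),
    "APC/alphaB" = ptm_rule(1L, "always", 0L),
    "APC/beta"   = ptm_rule(1L, "never", 1L),
    "PC/alpha"   = ptm_rule(1L, "never", 0L),
    "PC/beta"    = ptm_rule(2L, "variable", 1L)
  )
  if (is.null(table[[key]])) {
    stop(sprintf("no PTM rule for '%s'; known combinations: %s",
                 key, paste(names(table), collapse = ", ")))
  }
  table[[key]]
}

#' Apply a PTM rule to a subunit sequence
#'
#' Yields one proteoform for `met_loss` `"never"`/`"always"` and two (with
#' and without the initiator methionine) for `"variable"`. Each mass is the
#' unmodified chain mass plus the rule's chromophore and methylation
#' increments, minus the methionine mass where lost.
#'
#' @param seq A [subunit_sequence()].
#' @param rule A [ptm_rule()]; defaults to the family/chain rule table.
#' @param constants A [mass_constants()] object.
#' @return Data frame with columns `strain_id`, `family`, `chain`,
#'   `met_lost` (logical) and `mass` (Da).
#' @export
apply_ptm_rules <- function(seq, rule = NULL, constants = mass_constants()) {
  stopifnot(inherits(seq, "subunit_sequence"))
  if (is.null(rule)) rule <- default_ptm_rules(seq$family, seq$chain)
  stopifnot(inherits(rule, "ptm_rule"))
  if (rule$met_loss %in% c("always", "variable") &&
      substr(seq$residues, 1L, 1L) != "M") {
    stop(sprintf(
      "Met-loss rule for %s %s chain of strain '%s' requires a sequence starting with M",
      seq$family, seq$chain, seq$strain_id
    ))
  }
  base <- residue_chain_mass(seq, constants) +
    rule$n_chromophores * constants$chromophore_mass +
    rule$n_methylations * constants$methylation_mass
  met_lost <- switch(rule$met_loss,
    never = FALSE,
    always = TRUE,
    variable = c(FALSE, TRUE)
  )
  data.frame(
    strain_id = seq$strain_id,
    family = seq$family,
    chain = seq$chain,
    met_lost = met_lost,
    mass = base - ifelse(met_lost, constants$met_loss_mass, 0),
    stringsAsFactors = FALSE
  )
}

#' Proteoform mass table for a set of subunit sequences
#'
#' Applies the default (or supplied) PTM rules to every sequence.
#'
#' @param seqs List of [subunit_sequence()] objects.
#' @param constants A [mass_constants()] object.
#' @param rules Optional named list of [ptm_rule()]s keyed `"family/chain"`,
#'   overriding [default_ptm_rules()].
#' @return Data frame with one row per proteoform.
#' @export
proteoform_table <- function(seqs, constants = mass_constants(), rules = NULL) {
  rows <- lapply(seqs, function(s) {
    key <- paste(s$family, s$chain, sep = "/")
    rule <- if (!is.null(rules) && !is.null(rules[[key]])) rules[[key]] else NULL
    apply_ptm_rules(s, rule, constants)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
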