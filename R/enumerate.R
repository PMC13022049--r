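#' Construct a complex composition
#'
#' A composition is a multiset of alpha-beta dimer units. A unit is normally
#' a "pure" dimer (alpha and beta chains from the same strain, one family);
#' decoy units may pair chains across strains or mix families across units.
#'
#' @param units Data frame with columns `family`, `alpha_strain`,
#'   `beta_strain` (one row per dimer unit).
#' @param is_decoy Logical flag; non-decoy compositions must be
#'   single-family with pure dimer units.
#' @return Object of class `complex_composition`.
#' @export
complex_composition <- function(units, is_decoy = FALSE) {
  stopifnot(is.data.frame(units),
            all(c("family", "alpha_strain", "beta_strain") %in% names(units)),
            nrow(units) >= 1L)
  units <- units[order(units$family, units$alpha_strain, units$beta_strain), ,
                 drop = FALSE]
  rownames(units) <- NULL
  if (!is_decoy) {
    if (length(unique(units$family)) != 1L) {
      stop("non-decoy compositions must be single-family")
    }
    if (any(units$alpha_strain != units$beta_strain)) {
      stop("non-decoy compositions must use pure (same-strain) dimer units")
    }
  }
  structure(
    list(units = units, n_dimers = nrow(units), is_decoy = is_decoy,
         label = composition_label(units)),
    class = "complex_composition"
  )
}

composition_label <- function(units) {
  mixed_family <- length(unique(units$family)) > 1L
  token <- function(fam, a, b) {
    strain <- if (a == b) a else paste0(a, "/", b)
    if (mixed_family) paste0(fam, ".", strain) else strain
  }
  toks <- mapply(token, units$family, units$alpha_strain, units$beta_strain)
  tab <- table(factor(toks, levels = unique(toks)))
  body <- paste(sprintf("%dx%s", as.integer(tab), names(tab)), collapse = "+")
  prefix <- if (mixed_family) "MIX" else units$family[1L]
  paste0(prefix, ":", body)
}

#' @export
print.complex_composition <- function(x, ...) {
  cat(sprintf("<complex_composition> %s (n_dimers=%d%s)\n",
              x$label, x$n_dimers, if (x$is_decoy) ", decoy" else ""))
  invisible(x)
}

# all multisets of size n over k items, as a list of index vectors
multiset_indices <- function(k, n) {
  if (k == 1L) return(list(rep(1L, n)))
  combs <- utils::combn(k + n - 1L, n)
  lapply(seq_len(ncol(combs)), function(j) combs[, j] - seq_len(n) + 1L)
}

check_family_sequences <- function(sequences, strains, family) {
  if (is.null(sequences)) return(invisible(TRUE))
  for (s in strains) {
    for (ch in c("alpha", "beta")) {
      ok <- any(vapply(sequences, function(x) {
        x$strain_id == s && x$family == family && x$chain == ch
      }, logical(1L)))
      if (!ok) {
        stop(sprintf("strain '%s' lacks the %s %s chain sequence", s, family, ch))
      }
    }
  }
  invisible(TRUE)
}

#' Enumerate candidate dimer/hexamer compositions over a strain set
#'
#' All multisets of `n_dimers` pure dimer units over the given strains, one
#' family at a time. With `cross_family = TRUE`, multisets mixing APC and PC
#' units are appended, flagged as decoys (mixed-family hexamers serve as
#' negative controls).
#'
#' @param strains Character vector of strain ids.
#' @param family `"APC"` or `"PC"`.
#' @param n_dimers Number of dimer units (1 for a dimer, 3 for a hexamer).
#' @param cross_family Also enumerate mixed APC/PC multisets as decoys.
#' @param sequences Optional list of [subunit_sequence()]s used to verify
#'   that every strain has both chains for the family.
#' @return List of [complex_composition()] objects.
#' @export
enumerate_compositions <- function(strains, family, n_dimers,
                                   cross_family = FALSE, sequences = NULL) {
  stopifnot(length(strains) >= 1L, n_dimers >= 1L)
  family <- match.arg(family, c("APC", "PC"))
  strains <- sort(unique(strains))
  check_family_sequences(sequences, strains, family)
  pure_units <- data.frame(
    family = family, alpha_strain = strains, beta_strain = strains,
    stringsAsFactors = FALSE
  )
  out <- lapply(multiset_indices(nrow(pure_units), n_dimers), function(idx) {
    complex_composition(pure_units[idx, , drop = FALSE], is_decoy = FALSE)
  })
  if (cross_family) {
    other <- setdiff(c("APC", "PC"), family)
    check_family_sequences(sequences, strains, other)
    both_units <- rbind(
      pure_units,
      data.frame(family = other, alpha_strain = strains, beta_strain = strains,
                 stringsAsFactors = FALSE)
    )
    mixed <- lapply(multiset_indices(nrow(both_units), n_dimers), function(idx) {
      u <- both_units[idx, , drop = FALSE]
      if (length(unique(u$family)) < 2L) return(NULL)
      complex_composition(u, is_decoy = TRUE)
    })
    out <- c(out, Filter(Negate(is.null), mixed))
  }
  out
}

#' Enumerate decoy compositions for negative-control matching
#'
#' Two kinds of decoys, mirroring species never observed in native MS of
#' phycobiliprotein mixtures: hexamers mixing APC and PC dimer units, and
#' single alpha-beta dimers whose two chains come from different strains.
#'
#' @param strains Character vector of strain ids.
#' @param families Families to consider (default both).
#' @param include_hexamers Include cross-family hexamer decoys.
#' @param include_dimers Include cross-strain dimer decoys.
#' @param sequences Optional list of [subunit_sequence()]s for validation.
#' @return List of [complex_composition()] objects (possibly empty).
#' @export
decoy_compositions <- function(strains, families = c("APC", "PC"),
                               include_hexamers = TRUE, include_dimers = TRUE,
                               sequences = NULL) {
  strains <- sort(unique(strains))
  out <- list()
  if (include_hexamers && length(families) == 2L) {
    units <- do.call(rbind, lapply(families, function(fam) {
      data.frame(family = fam, alpha_strain = strains, beta_strain = strains,
                 stringsAsFactors = FALSE)
    }))
    mixed <- lapply(multiset_indices(nrow(units), 3L), function(idx) {
      u <- units[idx, , drop = FALSE]
      if (length(unique(u$family)) < 2L) return(NULL)
      complex_composition(u, is_decoy = TRUE)
    })
    out <- c(out, Filter(Negate(is.null), mixed))
  }
  if (include_dimers && length(strains) >= 2L) {
    for (fam in families) {
      check_family_sequences(sequences, strains, fam)
      for (a in strains) {
        for (b in strains) {
          if (a == b) next
          u <- data.frame(family = fam, alpha_strain = a, beta_strain = b,
                          stringsAsFactors = FALSE)
          out <- c(out, list(complex_composition(u, is_decoy = TRUE)))
        }
      }
    }
  }
  out
}

#' Theoretical neutral masses of a composition
#'
#' Expands the variable Met-loss combinatorics of the constituent
#' proteoforms (assembly is non-covalent: the complex mass is the exact sum
#' of its subunit proteoform masses). Distinct masses only, ascending.
#'
#' @param comp A [complex_composition()].
#' @param proteoforms Proteoform table from [proteoform_table()].
#' @return Data frame with columns `label`, `family`, `n_dimers`,
#'   `is_decoy`, `variant_key` (number of Met losses) and `neutral_mass`.
#' @export
composition_mass_variants <- function(comp, proteoforms) {
  stopifnot(inherits(comp, "complex_composition"))
  chain_options <- function(strain, family, chain) {
    rows <- proteoforms[proteoforms$strain_id == strain &
                          proteoforms$family == family &
                          proteoforms$chain == chain, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop(sprintf("no proteoform for strain '%s' %s %s chain", strain, family, chain))
    }
    rows
  }
  # per-unit option table: mass and number of Met losses
  unit_opts <- lapply(seq_len(comp$n_dimers), function(i) {
    u <- comp$units[i, ]
    a <- chain_options(u$alpha_strain, u$family, "alpha")
    b <- chain_options(u$beta_strain, u$family, "beta")
    grid <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
    data.frame(
      mass = a$mass[grid$ia] + b$mass[grid$ib],
      n_met_lost = as.integer(a$met_lost[grid$ia]) + as.integer(b$met_lost[grid$ib])
    )
  })
  combos <- Reduce(function(acc, opt) {
    grid <- expand.grid(i = seq_len(nrow(acc)), j = seq_len(nrow(opt)))
    data.frame(
      mass = acc$mass[grid$i] + opt$mass[grid$j],
      n_met_lost = acc$n_met_lost[grid$i] + opt$n_met_lost[grid$j]
    )
  }, unit_opts)
  combos <- combos[!duplicated(round(combos$mass, 6L)), , drop = FALSE]
  combos <- combos[order(combos$mass), , drop = FALSE]
  data.frame(
    label = comp$label,
    family = if (length(unique(comp$units$family)) == 1L) comp$units$family[1L] else "MIX",
    n_dimers = comp$n_dimers,
    is_decoy = comp$is_decoy,
    variant_key = sprintf("met_loss=%d", combos$n_met_lost),
    neutral_mass = combos$mass,
    stringsAsFactors = FALSE
  )
}

#' Build the full candidate mass table for a strain set
#'
#' Enumerates pure and heterologous dimer and hexamer compositions per
#' family (plus decoys, if requested), expands proteoform variants, and
#' returns one row per distinct theoretical neutral mass. This table is the
#' candidate list consumed by [match_series()].
#'
#' @param seqs List of [subunit_sequence()] objects covering every strain.
#' @param constants A [mass_constants()] object.
#' @param n_dimers Integer vector of stoichiometries to enumerate
#'   (default dimer and hexamer).
#' @param include_decoys Append cross-family hexamer and cross-strain dimer
#'   decoys.
#' @return Data frame (see [composition_mass_variants()] for columns).
#' @export
candidate_table <- function(seqs, constants = mass_constants(),
                            n_dimers = c(1L, 3L), include_decoys = TRUE) {
  pf <- proteoform_table(seqs, constants)
  strains_by_family <- lapply(c(APC = "APC", PC = "PC"), function(fam) {
    a <- unique(pf$strain_id[pf$family == fam & pf$chain == "alpha"])
    b <- unique(pf$strain_id[pf$family == fam & pf$chain == "beta"])
    sort(intersect(a, b))
  })
  comps <- list()
  for (fam in c("APC", "PC")) {
    strains <- strains_by_family[[fam]]
    if (length(strains) == 0L) next
    for (n in n_dimers) {
      comps <- c(comps, enumerate_compositions(strains, fam, n, sequences = seqs))
    }
  }
  if (include_decoys) {
    fams <- names(Filter(function(s) length(s) > 0L, strains_by_family))
    shared <- Reduce(intersect, strains_by_family[fams])
    all_strains <- sort(unique(unlist(strains_by_family[fams])))
    comps <- c(comps, decoy_compositions(
      if (length(fams) == 2L) shared else all_strains,
      families = fams,
      include_hexamers = length(fams) == 2L && length(shared) > 0L,
      include_dimers = TRUE
    ))
  }
  out <- do.call(rbind, lapply(comps, composition_mass_variants, proteoforms = pf))
  rownames(out) <- NULL
  out
}

#' Write a candidate table to CSV
#'
#' @param candidates Data frame from [candidate_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  utils::write.csv(candidates, path, row.names = FALSE)
  invisible(path)
}

#' Read a candidate table from CSV
#'
#' @param path Path to a CSV written by [write_candidate_table()].
#' @return Data frame of candidates.
#' @export
read_candidate_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
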