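#' Construct a structure model from an atom table
#'
#' The atom table is the package's working representation of a (predicted)
#' complex structure: one row per heavy atom with chain id, 1-based residue
#' number, residue name, atom name, element and Cartesian coordinates in
#' Angstrom.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `element`, `x`, `y`, `z`.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, chains: %s\n",
              nrow(x$atoms), paste(sort(unique(x$atoms$chain)), collapse = ", ")))
  invisible(x)
}

#' Read a structure from PDB or mmCIF
#'
#' Hydrogens are always excluded; hetero atoms (ligands, waters) are
#' excluded by default since predicted phycobiliprotein models carry no
#' bilins.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param include_hetero Keep HETATM records.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, include_hetero = FALSE) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  if (!include_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(trimws(at$elety), 1L, 1L)
  }
  at <- at[!(toupper(trimws(elem)) == "H"), , drop = FALSE]
  elem <- toupper(trimws(if (is.null(at$elesy)) substr(trimws(at$elety), 1L, 1L) else at$elesy))
  structure_model(data.frame(
    chain = at$chain, resno = at$resno, resid = at$resid,
    elety = at$elety, element = elem,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  ))
}

#' Inter-dimer residue contacts within a distance cutoff
#'
#' All residue pairs whose dimer groups differ and whose minimum heavy-atom
#' distance is at or below `cutoff` (inclusive, default 3 Angstrom).
#' Contacts are reported once under canonical ordering (lower group first,
#' then chain, then residue number).
#'
#' @param structure A [structure_model()].
#' @param grouping Named vector/list mapping every chain id to a dimer
#'   group index.
#' @param cutoff Distance cutoff, Angstrom.
#' @return Data frame with one row per contact: chains, residue numbers and
#'   names of both partners, their groups, and `min_dist`.
#' @export
find_contacts <- function(structure, grouping, cutoff = 3.0) {
  stopifnot(inherits(structure, "structure_model"), cutoff > 0)
  at <- structure$atoms
  grouping <- unlist(grouping)
  missing <- setdiff(unique(at$chain), names(grouping))
  if (length(missing)) {
    stop(sprintf("chain(s) %s present in the structure but absent from the grouping",
                 paste(sprintf("'%s'", missing), collapse = ", ")))
  }
  at$group <- as.integer(grouping[at$chain])
  groups <- sort(unique(at$group))
  if (length(groups) < 2L) stop("interface analysis needs at least 2 dimer groups")
  out <- list()
  for (gi in seq_along(groups)) {
    for (gj in seq_along(groups)) {
      if (gj <= gi) next
      A <- at[at$group == groups[gi], , drop = FALSE]
      B <- at[at$group == groups[gj], , drop = FALSE]
      # chunk the second block to bound memory on large structures
      step <- max(1L, floor(4e6 / nrow(A)))
      for (start in seq(1L, nrow(B), by = step)) {
        idx <- start:min(start + step - 1L, nrow(B))
        Bb <- B[idx, , drop = FALSE]
        d2 <- outer(A$x, Bb$x, "-")^2 + outer(A$y, Bb$y, "-")^2 +
          outer(A$z, Bb$z, "-")^2
        hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
        if (!nrow(hit)) next
        out[[length(out) + 1L]] <- data.frame(
          chain_a = A$chain[hit[, 1L]], resno_a = A$resno[hit[, 1L]],
          resid_a = A$resid[hit[, 1L]], group_a = groups[gi],
          chain_b = Bb$chain[hit[, 2L]], resno_b = Bb$resno[hit[, 2L]],
          resid_b = Bb$resid[hit[, 2L]], group_b = groups[gj],
          dist = sqrt(d2[hit]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      resid_a = character(0), group_a = integer(0),
                      chain_b = character(0), resno_b = integer(0),
                      resid_b = character(0), group_b = integer(0),
                      min_dist = numeric(0), stringsAsFactors = FALSE))
  }
  all_hits <- do.call(rbind, out)
  key <- paste(all_hits$chain_a, all_hits$resno_a, all_hits$chain_b,
               all_hits$resno_b, sep = "\r")
  min_d <- tapply(all_hits$dist, key, min)
  first <- all_hits[!duplicated(key), , drop = FALSE]
  first$min_dist <- as.numeric(min_d[paste(first$chain_a, first$resno_a,
                                           first$chain_b, first$resno_b,
                                           sep = "\r")])
  first$dist <- NULL
  first <- first[order(first$group_a, first$chain_a, first$resno_a,
                       first$group_b, first$chain_b, first$resno_b), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Interface residues per dimer group
#'
#' Union of the residues appearing in any contact pair, grouped by dimer.
#'
#' @param contacts Data frame from [find_contacts()].
#' @return Named list (by group) of data frames with `chain` and `resno`.
#' @export
interface_residues <- function(contacts) {
  if (nrow(contacts) == 0L) return(list())
  long <- rbind(
    data.frame(group = contacts$group_a, chain = contacts$chain_a,
               resno = contacts$resno_a, stringsAsFactors = FALSE),
    data.frame(group = contacts$group_b, chain = contacts$chain_b,
               resno = contacts$resno_b, stringsAsFactors = FALSE)
  )
  long <- unique(long)
  long <- long[order(long$group, long$chain, long$resno), ]
  out <- split(long[, c("chain", "resno")], long$group)
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Read a predicted-aligned-error matrix from JSON
#'
#' Accepts the common dialects of structure-prediction confidence files:
#' a top-level (or singleton-list-wrapped) object with a
#' `predicted_aligned_error` (or `pae`) matrix of rows, or the flat triplet
#' form with `residue1`, `residue2` and `distance`.
#'
#' @param path Path to a JSON file.
#' @return Square numeric matrix of PAE values.
#' @export
read_pae <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.data.frame(obj)) obj <- as.list(obj)
  if (!is.null(obj$predicted_aligned_error) || !is.null(obj$pae)) {
    m <- if (!is.null(obj$predicted_aligned_error)) obj$predicted_aligned_error else obj$pae
    if (is.list(m) && !is.matrix(m)) m <- do.call(rbind, m)
    m <- as.matrix(m)
  } else if (!is.null(obj$residue1)) {
    r1 <- unlist(obj$residue1); r2 <- unlist(obj$residue2)
    d <- unlist(if (!is.null(obj$distance)) obj$distance else obj$pae)
    n <- max(r1, r2)
    m <- matrix(NA_real_, n, n)
    m[cbind(r1, r2)] <- d
  } else if (is.list(obj) && length(obj) == 1L) {
    return(read_pae_obj(obj[[1L]]))
  } else {
    stop("unrecognised PAE JSON dialect")
  }
  if (nrow(m) != ncol(m)) stop("PAE matrix must be square")
  m
}

read_pae_obj <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE)
  read_pae(tmp)
}

# global residue index (order of first appearance chain-by-chain), matching
# the residue order of prediction confidence files
residue_index_table <- function(structure) {
  at <- structure$atoms
  key <- paste(at$chain, at$resno, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = at$chain[first], resno = at$resno[first],
             index = seq_len(sum(first)), stringsAsFactors = FALSE)
}

#' Summarise prediction confidence over an interface
#'
#' Mean PAE over all cross-group interface residue pairs (both
#' orientations, since PAE is asymmetric) and mean pLDDT over all interface
#' residues.
#'
#' @param pae Square PAE matrix over all residues (chain order as in the
#'   structure).
#' @param plddt Numeric vector of per-residue pLDDT values (same order).
#' @param interface List from [interface_residues()].
#' @param structure The [structure_model()] the indices refer to.
#' @param n_contacts Optional contact count to carry into the summary.
#' @return List with `mean_interface_pae`, `mean_interface_plddt`,
#'   `n_contacts`, `n_interface_residues`.
#' @export
summarize_confidence <- function(pae, plddt, interface, structure,
                                 n_contacts = NA_integer_) {
  if (length(interface) == 0L) {
    stop("empty interface: no contact residues (check the distance cutoff)")
  }
  itab <- residue_index_table(structure)
  idx_of <- function(d) {
    m <- merge(d, itab, by = c("chain", "resno"), sort = FALSE)
    if (nrow(m) != nrow(d)) stop("interface residue missing from the structure")
    m$index
  }
  sets <- lapply(interface, idx_of)
  if (nrow(pae) < max(unlist(sets)) || length(plddt) < max(unlist(sets))) {
    stop("PAE/pLDDT dimensions smaller than the structure's residue count")
  }
  if (any(plddt < 0 | plddt > 100)) stop("pLDDT values must lie in [0, 100]")
  pae_vals <- c()
  gs <- seq_along(sets)
  for (i in gs) {
    for (j in gs) {
      if (j <= i) next
      grid <- expand.grid(a = sets[[i]], b = sets[[j]])
      pae_vals <- c(pae_vals, pae[cbind(grid$a, grid$b)], pae[cbind(grid$b, grid$a)])
    }
  }
  all_idx <- unique(unlist(sets))
  list(
    mean_interface_pae = mean(pae_vals),
    mean_interface_plddt = mean(plddt[all_idx]),
    n_contacts = n_contacts,
    n_interface_residues = length(all_idx)
  )
}

#' Interface confidence from structure, grouping and confidence files
#'
#' Convenience wrapper: [find_contacts()] then [interface_residues()] then
#' [summarize_confidence()].
#'
#' @param structure A [structure_model()].
#' @param grouping Chain-to-dimer-group mapping.
#' @param pae Square PAE matrix.
#' @param plddt Per-residue pLDDT vector.
#' @param cutoff Contact cutoff, Angstrom.
#' @return See [summarize_confidence()].
#' @export
interface_confidence <- function(structure, grouping, pae, plddt, cutoff = 3.0) {
  contacts <- find_contacts(structure, grouping, cutoff)
  summarize_confidence(pae, plddt, interface_residues(contacts), structure,
                       n_contacts = nrow(contacts))
}

#' One-letter sequence of a chain in a structure
#'
#' @param structure A [structure_model()].
#' @param chain Chain id.
#' @return One-letter residue string (in residue-number order).
#' @export
chain_sequence <- function(structure, chain) {
  at <- structure$atoms[structure$atoms$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop(sprintf("no chain '%s' in structure", chain))
  first <- !duplicated(at$resno)
  res <- at$resid[first][order(at$resno[first])]
  paste(bio3d::aa321(res), collapse = "")
}

#' Project structure-derived interface residues to alignment columns
#'
#' Composes [find_contacts()], [interface_residues()] and
#' [unmap_position()]: the contact residues of each chain are mapped
#' through the chain's alignment row to 1-based alignment columns. Each
#' chain's residue sequence must match the ungapped alignment row exactly.
#'
#' @param structure A [structure_model()].
#' @param grouping Chain-to-dimer-group mapping.
#' @param alignment An [msa()].
#' @param chain_map Named vector mapping chain ids to alignment row ids.
#' @param cutoff Contact cutoff, Angstrom.
#' @param chain_roles Optional named vector mapping chain ids to roles
#'   (e.g. `"alpha"`, `"beta"`); columns are pooled per role. Defaults to
#'   one role per chain.
#' @return Named list of sorted unique alignment column vectors, per role.
#' @export
derive_interface_columns <- function(structure, grouping, alignment, chain_map,
                                     cutoff = 3.0, chain_roles = NULL) {
  chain_map <- unlist(chain_map)
  contacts <- find_contacts(structure, grouping, cutoff)
  ifres <- interface_residues(contacts)
  if (length(ifres) == 0L) return(list())
  chains_used <- unique(unlist(lapply(ifres, function(d) d$chain)))
  for (ch in chains_used) {
    if (is.na(chain_map[ch])) {
      stop(sprintf("chain '%s' has no alignment row in chain_map", ch))
    }
    row_seq <- gsub("-", "", alignment$rows[match(chain_map[ch], alignment$ids)],
                    fixed = TRUE)
    str_seq <- chain_sequence(structure, ch)
    if (!identical(row_seq, str_seq)) {
      cmp <- utils::head(which(strsplit(row_seq, "")[[1L]] !=
                                 strsplit(str_seq, "")[[1L]]), 1L)
      pos <- if (length(cmp)) cmp else min(nchar(row_seq), nchar(str_seq)) + 1L
      stop(sprintf(
        "chain '%s' sequence disagrees with alignment row '%s' at residue %d",
        ch, chain_map[ch], pos
      ))
    }
  }
  if (is.null(chain_roles)) {
    chain_roles <- stats::setNames(chains_used, chains_used)
  } else {
    chain_roles <- unlist(chain_roles)
  }
  cols <- list()
  for (grp in ifres) {
    for (k in seq_len(nrow(grp))) {
      ch <- grp$chain[k]
      role <- chain_roles[ch]
      col <- unmap_position(alignment, chain_map[ch], grp$resno[k])
      cols[[role]] <- c(cols[[role]], col)
    }
  }
  lapply(cols, function(v) sort(unique(v)))
}
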