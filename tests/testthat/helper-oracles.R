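# Independent oracles, coded separately from the package implementation.

# residue-sum oracle: counts residue occurrences and multiplies by an
# independently typed copy of the average-mass table
ORACLE_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

oracle_chain_mass <- function(residues, water = 18.0153) {
  if (nchar(residues) == 0L) return(water)
  counts <- table(strsplit(residues, "", fixed = TRUE)[[1L]])
  sum(ORACLE_RESIDUE_MASS[names(counts)] * as.integer(counts)) + water
}

random_sequence <- function(n, first_m = FALSE) {
  chars <- sample(names(ORACLE_RESIDUE_MASS), n, replace = TRUE)
  if (first_m) chars[1L] <- "M"
  paste(chars, collapse = "")
}

# brute-force multiset counting: enumerate all k^n tuples, canonicalise, count
oracle_n_multisets <- function(k, n) {
  tuples <- do.call(expand.grid, rep(list(seq_len(k)), n))
  keys <- apply(tuples, 1L, function(r) paste(sort(r), collapse = ","))
  length(unique(keys))
}

# all-pairs identity/similarity counting on a character vector (gaps removed
# by the caller); 'map' sends each letter to its class (identity: itself)
oracle_pair_pct <- function(chars, map = NULL) {
  if (!is.null(map)) chars <- map[chars]
  n <- length(chars)
  if (n < 2L) return(NA_real_)
  same <- 0L; total <- 0L
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      total <- total + 1L
      if (chars[i] == chars[j]) same <- same + 1L
    }
  }
  100 * same / total
}

# O(n^2) contact scan over an atom table: min heavy-atom distance per
# cross-group residue pair
oracle_contacts <- function(atoms, grouping, cutoff) {
  atoms$group <- unlist(grouping)[atoms$chain]
  res <- unique(atoms[, c("chain", "resno", "group")])
  out <- list()
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (j <= i) next
      a <- res[i, ]; b <- res[j, ]
      if (a$group == b$group) next
      if (a$group > b$group) { tmp <- a; a <- b; b <- tmp }
      A <- atoms[atoms$chain == a$chain & atoms$resno == a$resno, ]
      B <- atoms[atoms$chain == b$chain & atoms$resno == b$resno, ]
      dmin <- Inf
      for (p in seq_len(nrow(A))) {
        for (q in seq_len(nrow(B))) {
          d <- sqrt((A$x[p] - B$x[q])^2 + (A$y[p] - B$y[q])^2 + (A$z[p] - B$z[q])^2)
          if (d < dmin) dmin <- d
        }
      }
      if (dmin <= cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          chain_a = a$chain, resno_a = a$resno, chain_b = b$chain,
          resno_b = b$resno, min_dist = dmin, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) return(NULL)
  d <- do.call(rbind, out)
  d[order(d$chain_a, d$resno_a, d$chain_b, d$resno_b), ]
}

# toy structure builder: residues given as list(chain=, resno=, atoms=matrix xyz)
toy_structure <- function(residues) {
  rows <- lapply(residues, function(r) {
    xyz <- r$xyz
    data.frame(
      chain = r$chain, resno = r$resno,
      resid = if (is.null(r$resid)) "ALA" else r$resid,
      elety = paste0("C", seq_len(nrow(xyz))),
      element = "C",
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      stringsAsFactors = FALSE
    )
  })
  structure_model(do.call(rbind, rows))
}
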