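two_dimer_toy <- function() {
  # two "dimer" groups, a handful of single/multi-atom residues
  set.seed(404)
  res <- list(
    list(chain = "A", resno = 1L, xyz = matrix(c(0, 0, 0), 1)),
    list(chain = "A", resno = 2L, xyz = matrix(c(0, 0, 2, 1, 0, 2), 2, byrow = TRUE)),
    list(chain = "B", resno = 1L, xyz = matrix(c(0, 0, 4.5), 1)),
    list(chain = "B", resno = 2L, xyz = matrix(c(3, 0, 2), 1)),
    list(chain = "C", resno = 1L, xyz = matrix(c(0, 3, 0, 0, 4, 0), 2, byrow = TRUE)),
    list(chain = "C", resno = 2L, xyz = matrix(c(8, 8, 8), 1))
  )
  list(struct = toy_structure(res),
       grouping = c(A = 1L, B = 1L, C = 2L))
}

test_that("contact search equals the all-pairs distance oracle", {
  toy <- two_dimer_toy()
  got <- find_contacts(toy$struct, toy$grouping, cutoff = 3.0)
  want <- oracle_contacts(toy$struct$atoms, toy$grouping, 3.0)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$chain_a, want$chain_a)
  expect_equal(got$resno_a, want$resno_a)
  expect_equal(got$chain_b, want$chain_b)
  expect_equal(got$resno_b, want$resno_b)
  expect_equal(got$min_dist, want$min_dist, tolerance = 1e-12)

  # a larger random toy: 20 single-atom residues across two groups
  set.seed(88)
  res <- lapply(1:20, function(i) {
    list(chain = if (i <= 10) "A" else "C", resno = ((i - 1) %% 10) + 1L,
         xyz = matrix(runif(3, 0, 8), 1))
  })
  st <- toy_structure(res)
  grp <- c(A = 1L, C = 2L)
  got <- find_contacts(st, grp, 3.0)
  want <- oracle_contacts(st$atoms, grp, 3.0)
  expect_equal(got$min_dist, want$min_dist, tolerance = 1e-12)
})

test_that("contacts use an inclusive cutoff and exclude within-group pairs", {
  res <- list(
    list(chain = "A", resno = 1L, xyz = matrix(c(0, 0, 0), 1)),
    list(chain = "B", resno = 1L, xyz = matrix(c(0, 0, 2.5), 1))
  )
  st <- toy_structure(res)
  expect_equal(nrow(find_contacts(st, c(A = 1L, B = 2L), 3.0)), 1L)
  expect_equal(nrow(find_contacts(st, c(A = 1L, B = 2L), 2.5)), 1L)  # inclusive
  # same pair at 3.5 Angstrom: no contact
  st2 <- st
  st2$atoms$z[2L] <- 3.5
  expect_equal(nrow(find_contacts(st2, c(A = 1L, B = 2L), 3.0)), 0L)
  # same group: never a contact
  expect_error(find_contacts(st, c(A = 1L, B = 1L), 3.0), "2 dimer groups")
  # chain missing from the grouping is an error naming the chain
  expect_error(find_contacts(st, c(A = 1L), 3.0), "'B'")
})

test_that("contacts are invariant under rigid motion and monotone in cutoff", {
  toy <- two_dimer_toy()
  base <- find_contacts(toy$struct, toy$grouping, 3.0)
  # random rotation (QR of a random matrix) plus translation
  set.seed(11)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- c(5, -3, 11)
  at <- toy$struct$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + shift[1]; at$y <- xyz[, 2] + shift[2]; at$z <- xyz[, 3] + shift[3]
  moved <- find_contacts(structure_model(at), toy$grouping, 3.0)
  expect_equal(moved$resno_a, base$resno_a)
  expect_equal(moved$resno_b, base$resno_b)
  expect_equal(moved$min_dist, base$min_dist, tolerance = 1e-6)

  tight <- find_contacts(toy$struct, toy$grouping, 2.5)
  key <- function(d) paste(d$chain_a, d$resno_a, d$chain_b, d$resno_b)
  expect_true(all(key(tight) %in% key(base)))
})

test_that("interface residues are the per-group union of contact partners", {
  toy <- two_dimer_toy()
  contacts <- find_contacts(toy$struct, toy$grouping, 3.0)
  ir <- interface_residues(contacts)
  long <- rbind(
    data.frame(g = contacts$group_a, chain = contacts$chain_a, resno = contacts$resno_a),
    data.frame(g = contacts$group_b, chain = contacts$chain_b, resno = contacts$resno_b)
  )
  for (g in names(ir)) {
    want <- unique(long[long$g == as.integer(g), c("chain", "resno")])
    expect_equal(nrow(ir[[g]]), nrow(want))
  }
  expect_equal(interface_residues(find_contacts(toy$struct, toy$grouping, 0.1)),
               list())
})

test_that("PAE JSON dialects parse to the same matrix", {
  m <- matrix(c(0, 2, 3, 4,
                2.5, 0, 1, 2,
                3, 1.5, 0, 5,
                4, 2, 5.5, 0), 4, 4, byrow = TRUE)
  t1 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(predicted_aligned_error = m), t1)
  expect_equal(read_pae(t1), m)
  # singleton-list wrapper (as emitted alongside some prediction pipelines)
  t2 <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(list(predicted_aligned_error = m))), t2)
  expect_equal(read_pae(t2), m)
  # flat triplet dialect
  grid <- expand.grid(r1 = 1:4, r2 = 1:4)
  t3 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(residue1 = grid$r1, residue2 = grid$r2,
                            distance = m[cbind(grid$r1, grid$r2)]), t3)
  expect_equal(read_pae(t3), m)
  unlink(c(t1, t2, t3))
})

test_that("confidence summaries average PAE pairs and pLDDT residues", {
  toy <- two_dimer_toy()
  contacts <- find_contacts(toy$struct, toy$grouping, 3.0)
  ir <- interface_residues(contacts)
  n_res <- 6L  # A:2, B:2, C:2 in chain order
  pae_u <- matrix(5, n_res, n_res)
  plddt <- rep(90, n_res)
  s <- summarize_confidence(pae_u, plddt, ir, toy$struct, n_contacts = nrow(contacts))
  expect_equal(s$mean_interface_pae, 5)
  expect_equal(s$mean_interface_plddt, 90)
  expect_equal(s$n_contacts, nrow(contacts))

  # asymmetric hand-filled PAE over a 2-residue interface
  res <- list(
    list(chain = "A", resno = 1L, xyz = matrix(c(0, 0, 0), 1)),
    list(chain = "A", resno = 2L, xyz = matrix(c(50, 0, 0), 1)),
    list(chain = "B", resno = 1L, xyz = matrix(c(0, 0, 2), 1))
  )
  st <- toy_structure(res)
  cc <- find_contacts(st, c(A = 1L, B = 2L), 3.0)
  ir2 <- interface_residues(cc)
  pae <- matrix(0, 3, 3)
  pae[1, 3] <- 4; pae[3, 1] <- 6   # A:1 (index 1) vs B:1 (index 3)
  pl <- c(80, 10, 90)
  s2 <- summarize_confidence(pae, pl, ir2, st)
  expect_equal(s2$mean_interface_pae, (4 + 6) / 2)
  expect_equal(s2$mean_interface_plddt, (80 + 90) / 2)
  expect_error(summarize_confidence(pae, pl, list(), st), "empty interface")
})

test_that("interface columns compose contact search with position mapping", {
  res <- list(
    list(chain = "A", resno = 1L, resid = "MET", xyz = matrix(c(0, 0, 0), 1)),
    list(chain = "A", resno = 2L, resid = "LYS", xyz = matrix(c(0, 0, 2), 1)),
    list(chain = "B", resno = 1L, resid = "MET", xyz = matrix(c(0, 0, 3.5), 1)),
    list(chain = "B", resno = 2L, resid = "LEU", xyz = matrix(c(0, 0, 50), 1))
  )
  st <- toy_structure(res)
  aln <- msa(c("rowA", "rowB"), c("M-K", "ML-"))
  grouping <- c(A = 1L, B = 2L)
  chain_map <- c(A = "rowA", B = "rowB")
  roles <- c(A = "alpha", B = "beta")
  cols <- derive_interface_columns(st, grouping, aln, chain_map,
                                   cutoff = 3.0, chain_roles = roles)
  # contact: A residue 2 (unaligned position 2 -> column 3) with B residue 1
  expect_equal(cols$alpha, 3L)
  expect_equal(cols$beta, 1L)

  # no contacts: empty result
  far <- st
  far$atoms$z[3L] <- 40
  expect_equal(derive_interface_columns(far, grouping, aln, chain_map,
                                        cutoff = 3.0), list())

  # sequence/structure mismatch is rejected at the first discrepant residue
  bad_aln <- msa(c("rowA", "rowB"), c("M-W", "ML-"))
  expect_error(derive_interface_columns(st, grouping, bad_aln, chain_map,
                                        cutoff = 3.0), "residue 2")
})

test_that("PDB files parse to heavy-atom tables", {
  pdb_line <- function(serial, name, resn, chain, resno, x, y, z, elem) {
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, paste0(" ", name), resn, chain, resno, x, y, z, elem)
  }
  lines <- c(
    pdb_line(1, "N", "MET", "A", 1, 0, 0, 0, "N"),
    pdb_line(2, "CA", "MET", "A", 1, 1.4, 0, 0, "C"),
    pdb_line(3, "H", "MET", "A", 1, 0.5, 0.5, 0, "H"),
    pdb_line(4, "CA", "LYS", "B", 1, 0, 0, 3.0, "C"),
    "END"
  )
  tmp <- tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  st <- read_structure(tmp)
  expect_equal(nrow(st$atoms), 3L)  # hydrogen dropped
  expect_false(any(st$atoms$element == "H"))
  cc <- find_contacts(st, c(A = 1L, B = 2L), 3.0)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$min_dist, 3.0, tolerance = 1e-6)
  expect_equal(chain_sequence(st, "A"), "M")
  unlink(tmp)
})
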