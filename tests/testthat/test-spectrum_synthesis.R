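test_that("m/z conversions follow the protonation convention and invert", {
  expect_equal(mass_to_mz(5000, 1L), 5001.00728, tolerance = 1e-9)
  expect_equal(mass_to_mz(110000, 22L), (110000 + 22 * 1.00728) / 22,
               tolerance = 1e-9)
  expect_equal(mass_to_mz(110000, 22L), 5001.0073, tolerance = 1e-3 / 5000)
  expect_error(mass_to_mz(5000, 0L), "charge")
  set.seed(5)
  for (i in 1:20) {
    M <- runif(1, 1e4, 2e5)
    z <- sample(1:40, 1L)
    expect_equal(neutral_mass_from_mz(mass_to_mz(M, z), z), M, tolerance = 1e-9)
  }
})

test_that("charge envelopes are normalised and centred at 0.078 sqrt(M)", {
  model <- instrument_model()
  for (M in c(37000, 110000, 230000)) {
    env <- charge_envelope(M, model)
    expect_equal(sum(env$weight), 1, tolerance = 1e-12)
    expect_true(all(env$weight >= 0))
    mzs <- mass_to_mz(M, env$z)
    expect_true(all(mzs >= model$mz_min & mzs <= model$mz_max))
  }
  env <- charge_envelope(110000, model)
  expect_equal(env$z[which.max(env$weight)], 26L)  # z0 = 0.078*sqrt(110000) = 25.9
  scale <- 22 / (0.078 * sqrt(110000))
  env <- charge_envelope(110000, instrument_model(envelope_center_scale = scale))
  expect_equal(env$z[which.max(env$weight)], 22L)
  expect_error(charge_envelope(10, model), "charge")
})

test_that("noiseless rendering conserves area per charge and in total", {
  model <- instrument_model(noise_sd = 0, grid_step = 0.2)
  mix <- mixture_spec(c(110000, 150000), c(3, 1))
  sp <- render_spectrum(mix, model, seed = 1L)
  total <- sum(sp$intensity) * model$grid_step
  expect_equal(total, 1, tolerance = 1e-6)

  # integrated intensity per charge proportional to envelope weight
  single <- mixture_spec(110000, 1)
  sp1 <- render_spectrum(single, model, seed = 1L)
  env <- charge_envelope(110000, model)
  for (k in head(order(-env$weight), 3L)) {
    center <- mass_to_mz(110000, env$z[k])
    win <- abs(sp1$mz - center) < 25
    got <- sum(sp1$intensity[win]) * model$grid_step
    expect_equal(got, env$weight[k], tolerance = 1e-4)
  }
})

test_that("two species 400 Da apart are locally resolvable at z = 22", {
  model <- instrument_model(noise_sd = 0, envelope_center_scale = 22 / (0.078 * sqrt(110000)))
  mix <- mixture_spec(c(110000, 110400), c(1, 1))
  sp <- render_spectrum(mix, model, seed = 1L)
  m1 <- mass_to_mz(110000, 22L)
  m2 <- mass_to_mz(110400, 22L)
  i1 <- sp$intensity[which.min(abs(sp$mz - m1))]
  i2 <- sp$intensity[which.min(abs(sp$mz - m2))]
  valley <- min(sp$intensity[sp$mz > m1 & sp$mz < m2])
  expect_lt(valley, 0.5 * min(i1, i2))
})

test_that("spectrum synthesis is a pure function of mixture, model and seed", {
  model <- instrument_model(noise_sd = 0.01, seed = 42L)
  mix <- mixture_spec(c(110000, 113000), c(2, 1))
  a <- render_spectrum(mix, model)
  b <- render_spectrum(mix, model)
  expect_identical(a$mz, b$mz)
  expect_identical(a$intensity, b$intensity)
  c <- render_spectrum(mix, model, seed = 43L)
  expect_false(identical(a$intensity, c$intensity))
  # rendering does not disturb the caller's RNG stream
  set.seed(9); x1 <- runif(1)
  set.seed(9); invisible(render_spectrum(mix, model)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("spectrum CSV round trip preserves the arrays", {
  sp <- render_spectrum(mixture_spec(110000, 1),
                        instrument_model(noise_sd = 0, grid_step = 1))
  tmp <- tempfile(fileext = ".csv")
  write_spectrum(sp, tmp)
  back <- read_spectrum(tmp)
  expect_equal(back$mz, sp$mz)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-12)
  unlink(tmp)
})

test_that("strain generation respects divergence and protected columns", {
  base <- phyco_base_sequences()
  # divergence 0 reproduces the base
  g <- generate_strain_family(base$PC$alpha, base$PC$beta, 2L, divergence = 0,
                              seed = 1L)
  expect_equal(g$sequences[[1L]]$residues, base$PC$alpha)
  expect_equal(g$sequences[[2L]]$residues, base$PC$beta)

  # full protection blocks all substitutions
  n <- nchar(base$PC$alpha)
  g <- generate_strain_family(base$PC$alpha, base$PC$alpha, 1L,
                              divergence = 0.5,
                              protected_columns = seq_len(n), seed = 1L)
  expect_equal(g$sequences[[1L]]$residues, base$PC$alpha)

  # substitution counts fall in the binomial 99% interval (pooled over seeds)
  n_sub <- integer(0)
  alpha160 <- substr(base$PC$alpha, 1, 160)
  for (seed in 1:40) {
    g <- generate_strain_family(alpha160, alpha160, 1L, divergence = 0.05,
                                protected_columns = integer(0), seed = seed)
    for (s in g$sequences) {
      n_sub <- c(n_sub, sum(strsplit(s$residues, "")[[1L]] !=
                              strsplit(alpha160, "")[[1L]]))
    }
  }
  expect_equal(mean(n_sub), 160 * 0.05, tolerance = 0.15)
  q <- qbinom(c(0.005, 0.995), 160, 0.05)
  expect_gt(mean(n_sub >= q[1L] & n_sub <= q[2L]), 0.95)

  # generation is seeded and reproducible
  g1 <- generate_strain_set(2L, 0.05, seed = 5L)
  g2 <- generate_strain_set(2L, 0.05, seed = 5L)
  expect_identical(vapply(g1$sequences, `[[`, character(1L), "residues"),
                   vapply(g2$sequences, `[[`, character(1L), "residues"))
})

test_that("strain dimer mass differences equal per-substitution residue deltas", {
  base <- phyco_base_sequences()
  g <- generate_strain_family(base$APC$alpha, base$APC$beta, 2L,
                              divergence = 0.05, seed = 17L, family = "APC")
  for (k in 1:2) {
    s <- g$sequences[[k]]
    ref <- if (s$chain == "alpha") base$APC$alpha else base$APC$beta
    delta <- residue_chain_mass(s$residues) - oracle_chain_mass(ref)
    ref_c <- strsplit(ref, "")[[1L]]
    new_c <- strsplit(s$residues, "")[[1L]]
    diff_pos <- which(ref_c != new_c)
    oracle_delta <- sum(ORACLE_RESIDUE_MASS[new_c[diff_pos]] -
                          ORACLE_RESIDUE_MASS[ref_c[diff_pos]])
    expect_equal(delta, oracle_delta, tolerance = 1e-9)
  }
})
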