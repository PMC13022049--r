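test_that("centroid picking recovers apexes and ignores noise-only traces", {
  # single noiseless Gaussian at 5000
  mz <- seq(4990, 5010, by = 0.25)
  y <- dnorm(mz, 5000, 1.2)
  cen <- pick_centroids(list(mz = mz, intensity = y))
  expect_equal(nrow(cen), 1L)
  expect_equal(cen$mz, 5000, tolerance = 0.025)

  # two Gaussians 3 FWHM apart
  fwhm <- 2
  sd <- fwhm / 2.3548
  y2 <- dnorm(mz, 4998, sd) + dnorm(mz, 4998 + 3 * fwhm, sd)
  cen <- pick_centroids(list(mz = mz, intensity = y2))
  expect_equal(nrow(cen), 2L)

  # pure noise at threshold 5: empty
  set.seed(31)
  noise <- rnorm(5000, 0.03, 0.005)
  cen <- pick_centroids(list(mz = seq_along(noise), intensity = noise), 5)
  expect_equal(nrow(cen), 0L)

  # flat and empty spectra: empty, not an error
  expect_equal(nrow(pick_centroids(list(mz = 1:10, intensity = rep(0, 10)))), 0L)
  expect_equal(nrow(pick_centroids(list(mz = numeric(0), intensity = numeric(0)))), 0L)
})

test_that("charge-series inference round-trips simulated masses", {
  model <- instrument_model(noise_sd = 0)
  sp <- render_spectrum(mixture_spec(110000, 1), model, seed = 1L)
  ser <- infer_charge_series(pick_centroids(sp), z_range = c(5L, 40L))
  expect_equal(length(ser), 1L)
  expect_equal(ser[[1L]]$neutral_mass, 110000, tolerance = 2e-6)
  expect_gte(nrow(ser[[1L]]$members), 3L)
  expect_equal(anyDuplicated(ser[[1L]]$members$z), 0L)

  sp2 <- render_spectrum(mixture_spec(c(110000, 113000), c(1, 1)), model, seed = 1L)
  ser2 <- infer_charge_series(pick_centroids(sp2))
  expect_equal(length(ser2), 2L)
  got <- sort(vapply(ser2, `[[`, numeric(1L), "neutral_mass"))
  expect_equal(got, c(110000, 113000), tolerance = 5e-6)
})

test_that("unrelated centroids never reach the minimum charge support", {
  # brute-force check that 4 arbitrary centroids admit no (z, M) cluster with
  # 3 supports at 10 ppm, then confirm the implementation agrees
  cen <- data.frame(mz = c(1523.77, 2411.13, 3301.59, 4187.23),
                    intensity = rep(1, 4))
  zs <- 5:40
  hyp <- expand.grid(i = 1:4, z = zs)
  hyp$M <- hyp$z * (cen$mz[hyp$i] - 1.00728)
  found <- FALSE
  for (a in seq_len(nrow(hyp))) {
    close <- abs(hyp$M - hyp$M[a]) <= hyp$M[a] * 10e-6
    if (length(unique(hyp$z[close])) >= 3L) found <- TRUE
  }
  expect_false(found)
  expect_equal(length(infer_charge_series(cen, cluster_tol_ppm = 10,
                                          min_states = 3L)), 0L)
})

test_that("percent error is exact, scale-invariant and guarded", {
  expect_equal(percent_error(110000, 110000), 0)
  expect_equal(percent_error(110055, 110000), 0.05, tolerance = 1e-9)
  expect_gt(percent_error(110200, 110000), 0.1)
  expect_equal(percent_error(110200, 110000), 0.18181818, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:20) {
    m1 <- runif(1, 1e4, 2e5); m2 <- runif(1, 1e4, 2e5); k <- runif(1, 0.1, 10)
    expect_equal(percent_error(k * m1, k * m2), percent_error(m1, m2),
                 tolerance = 1e-9)
  }
  expect_error(percent_error(1, 0), "positive")
})

test_that("matching surfaces ambiguity instead of resolving it", {
  cand <- data.frame(
    label = c("X", "Y", "Z"), family = "PC", n_dimers = 3L,
    is_decoy = FALSE, variant_key = "met_loss=0",
    neutral_mass = c(110000, 110060, 112000), stringsAsFactors = FALSE
  )
  ser <- structure(list(neutral_mass = 110000,
                        members = data.frame(z = 20:24, mz = 0, intensity = 1),
                        intensity_sum = 5), class = "charge_series")
  a <- match_series(ser, cand)
  # 60 Da apart at 110 kDa is 0.055%: both pass, never unique
  expect_equal(a$status, "ambiguous")
  expect_equal(nrow(a$candidates), 2L)
  expect_equal(a$candidates$label, c("X", "Y"))
  expect_true(all(diff(a$candidates$percent_error) >= 0))

  ser$neutral_mass <- 112000
  expect_equal(match_series(ser, cand)$status, "unique")
  ser$neutral_mass <- 114000
  expect_equal(match_series(ser, cand)$status, "unassigned")
})

test_that("quantification reports family shares and the dimer:hexamer ratio", {
  mk_series <- function(M, I) {
    structure(list(neutral_mass = M,
                   members = data.frame(z = 20:22, mz = 0, intensity = I / 3),
                   intensity_sum = I), class = "charge_series")
  }
  cand <- data.frame(
    label = c("APC:3xA", "APC:1xA"), family = "APC", n_dimers = c(3L, 1L),
    is_decoy = FALSE, variant_key = "met_loss=0",
    neutral_mass = c(107000, 35666), stringsAsFactors = FALSE
  )
  # single unique hexamer: 100%
  rep1 <- quantify(list(match_series(mk_series(107000, 10), cand)))
  expect_equal(rep1$per_composition$rel_abundance_pct, 100)
  expect_true(is.na(rep1$dimer_to_hexamer_pct[["APC"]]) ||
                rep1$dimer_to_hexamer_pct[["APC"]] == 0)

  # 95:5 hexamer:dimer mixture gives the 5.26% ratio
  rep2 <- quantify(list(
    match_series(mk_series(107000, 95), cand),
    match_series(mk_series(35666, 5), cand)
  ))
  expect_equal(rep2$dimer_to_hexamer_pct[["APC"]], 100 * 5 / 95, tolerance = 1e-9)
  expect_equal(sum(rep2$per_composition$rel_abundance_pct), 100, tolerance = 1e-9)

  # zero hexamer intensity: undefined ratio, not infinity
  rep3 <- quantify(list(match_series(mk_series(35666, 5), cand)))
  expect_true(is.na(rep3$dimer_to_hexamer_pct[["APC"]]))

  # decoy bookkeeping
  cand_decoy <- cand
  cand_decoy$is_decoy <- c(FALSE, TRUE)
  rep4 <- quantify(list(
    match_series(mk_series(107000, 90), cand_decoy),
    match_series(mk_series(35666, 10), cand_decoy)
  ))
  expect_equal(rep4$decoy_intensity_pct, 10, tolerance = 1e-9)
})

test_that("dimer:hexamer ratio never decreases with the simulated dimer weight", {
  seqs <- generate_strain_set(1L, 0, seed = 2L)$sequences
  cands <- candidate_table(seqs, include_decoys = FALSE)
  apc <- cands[cands$family == "APC", ]
  hex_mass <- apc$neutral_mass[apc$n_dimers == 3L][1L]
  dim_mass <- apc$neutral_mass[apc$n_dimers == 1L][1L]
  model <- instrument_model(noise_sd = 0.002)
  ratios <- vapply(c(0.02, 0.05, 0.15, 0.30), function(w) {
    mix <- mixture_spec(c(hex_mass, dim_mass), c(1 - w, w))
    sp <- render_spectrum(mix, model, seed = 7L)
    rep <- quantify(lapply(infer_charge_series(pick_centroids(sp)),
                           match_series, candidates = cands))
    rep$dimer_to_hexamer_pct[["APC"]]
  }, numeric(1L))
  expect_true(all(diff(ratios) > 0))
  expect_equal(ratios[2L], 100 * 5 / 95, tolerance = 0.25 * 100 * 5 / 95)
})

test_that("mixture absorbance prediction is the pointwise mean", {
  wl <- seq(400, 700, by = 5)
  pa <- data.frame(wavelength = wl, absorbance = dnorm(wl, 620, 30))
  pb <- data.frame(wavelength = wl, absorbance = dnorm(wl, 650, 25))
  # identical profiles: prediction equals both, RMS 0
  out <- predict_mixture_absorbance(pa, pa, pa)
  expect_equal(out$predicted, pa$absorbance, tolerance = 1e-12)
  expect_equal(out$rms, 0, tolerance = 1e-12)
  # constant 0 and 2: midpoint 1
  p0 <- data.frame(wavelength = wl, absorbance = 0)
  p2 <- data.frame(wavelength = wl, absorbance = 2)
  expect_equal(unique(predict_mixture_absorbance(p0, p2)$predicted), 1)
  # measured equal to the mean: RMS 0
  mixm <- data.frame(wavelength = wl, absorbance = (pa$absorbance + pb$absorbance) / 2)
  expect_equal(predict_mixture_absorbance(pa, pb, mixm)$rms, 0, tolerance = 1e-12)
  # disjoint ranges rejected
  pfar <- data.frame(wavelength = wl + 1000, absorbance = 1)
  expect_error(predict_mixture_absorbance(pa, pfar), "disjoint")
})
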