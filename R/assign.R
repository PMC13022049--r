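#' Pick peak centroids from a profile spectrum
#'
#' Local maxima above the baseline (trace median) plus `snr_threshold`
#' times a robust noise estimate (1.4826 * MAD about the baseline), with
#' the apex position refined by three-point parabolic interpolation on log
#' baseline-subtracted intensity (exact for Gaussian peaks). Reported
#' centroid intensities are estimated peak areas: baseline-subtracted apex
#' height times the Gaussian width implied by the half-maximum crossings
#' (using the cleaner side when a neighbouring peak overlaps one flank).
#' Areas, unlike heights, are comparable across the m/z range even though
#' resolving power, and hence peak width, varies with m/z. On a noiseless
#' spectrum the threshold falls back to a small fraction of the maximum so
#' envelope peaks are still picked.
#'
#' @param spectrum List with ascending `mz` and `intensity`.
#' @param snr_threshold Signal-to-noise threshold (default 5).
#' @return Data frame with columns `mz` and `intensity` (possibly empty).
#' @export
pick_centroids <- function(spectrum, snr_threshold = 5) {
  mz <- spectrum$mz
  y <- spectrum$intensity
  n <- length(y)
  if (n < 3L || max(y) <= 0) {
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  }
  baseline <- stats::median(y)
  noise <- stats::mad(y, center = baseline)
  thr <- baseline + max(snr_threshold * noise, 1e-6 * (max(y) - baseline))
  i <- 2:(n - 1L)
  is_max <- y[i] > y[i - 1L] & y[i] >= y[i + 1L] & y[i] > thr
  apex <- i[is_max]
  if (!length(apex)) return(data.frame(mz = numeric(0), intensity = numeric(0)))
  refine <- function(k) {
    y0 <- y[k - 1L] - baseline; y1 <- y[k] - baseline; y2 <- y[k + 1L] - baseline
    step <- mz[k + 1L] - mz[k]
    logs <- y0 > 0 && y2 > 0
    if (logs) { y0 <- log(y0); y1 <- log(y1); y2 <- log(y2) }
    denom <- y0 - 2 * y1 + y2
    delta <- if (denom < 0) 0.5 * (y0 - y2) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    mz[k] + delta * step
  }
  # half-width at half maximum from interpolated half-max crossings; each
  # side is walked only while the trace keeps descending, so an overlapping
  # neighbour invalidates that side and the cleaner side is used
  half_width <- function(k) {
    half <- baseline + (y[k] - baseline) / 2
    side <- function(dir) {
      j <- k
      while (j + dir >= 1L && j + dir <= n && y[j + dir] < y[j]) {
        j <- j + dir
        if (y[j] <= half) {
          frac <- (half - y[j]) / (y[j - dir] - y[j])
          return(abs(mz[j] + frac * (mz[j - dir] - mz[j]) - mz[k]))
        }
      }
      NA_real_
    }
    w <- c(side(-1L), side(1L))
    if (all(is.na(w))) return(mz[min(k + 1L, n)] - mz[k])
    min(w, na.rm = TRUE)
  }
  height <- y[apex] - baseline
  hwhm <- vapply(apex, half_width, numeric(1L))
  sigma <- 2 * hwhm / (2 * sqrt(2 * log(2)))
  data.frame(
    mz = vapply(apex, refine, numeric(1L)),
    intensity = height * sigma * sqrt(2 * pi)
  )
}

#' Deconvolve centroids into charge-state series
#'
#' Forms a neutral-mass hypothesis M = z * (mz - m_proton) for every
#' centroid and candidate charge, clusters hypotheses within
#' `cluster_tol_ppm`, and keeps clusters supported by at least `min_states`
#' distinct charges. Each centroid is assigned to at most one series;
#' clusters are accepted greedily by their longest consecutive charge run
#' (genuine electrospray envelopes populate consecutive charges, while
#' harmonic artifacts collect systematically gapped ones), then by distinct
#' charge support, then summed intensity. The series neutral mass is the
#' intensity-weighted mean of its member hypotheses.
#'
#' @param centroids Data frame from [pick_centroids()].
#' @param z_range Integer vector `c(z_min, z_max)` of charges to consider.
#' @param cluster_tol_ppm Clustering tolerance for mass hypotheses, ppm.
#' @param min_states Minimum number of distinct supporting charges.
#' @param proton_mass Proton mass, Da.
#' @param share_collisions Re-apportion centroids claimed by several series
#'   with [share_collided_peaks()] (default TRUE).
#' @return List of `charge_series` objects: each has `neutral_mass`,
#'   `members` (data frame of z, mz, intensity) and `intensity_sum`.
#' @export
infer_charge_series <- function(centroids, z_range = c(5L, 40L),
                                cluster_tol_ppm = 50, min_states = 3L,
                                proton_mass = 1.00728,
                                share_collisions = TRUE) {
  stopifnot(length(z_range) == 2L, all(is.finite(z_range)), min_states >= 2L)
  if (nrow(centroids) == 0L) return(list())
  zs <- seq.int(z_range[1L], z_range[2L])
  nc <- nrow(centroids)
  ci <- rep(seq_len(nc), each = length(zs))
  z <- rep(zs, times = nc)
  mzv <- centroids$mz[ci]
  inten <- centroids$intensity[ci]
  M <- neutral_mass_from_mz(mzv, z, proton_mass)

  ord <- order(M)
  ci <- ci[ord]; z <- z[ord]; mzv <- mzv[ord]; inten <- inten[ord]; M <- M[ord]
  n <- length(M)
  cid <- cumsum(c(1L, as.integer(diff(M) > M[-n] * cluster_tol_ppm * 1e-6)))

  longest_run <- function(v) {
    v <- sort(unique(v))
    if (length(v) == 1L) return(1L)
    r <- rle(diff(v) == 1L)
    runs <- r$lengths[r$values]
    if (length(runs)) max(runs) + 1L else 1L
  }
  support <- vapply(split(z, cid), function(v) length(unique(v)), integer(1L))
  run <- vapply(split(z, cid), longest_run, integer(1L))
  csum <- vapply(split(inten, cid), sum, numeric(1L))
  keep <- which(support >= min_states)
  if (!length(keep)) return(list())
  # rank by the longest consecutive charge run first: genuine electrospray
  # envelopes populate consecutive charges, while harmonic artifacts (masses
  # at integer multiples/fractions) collect systematically gapped charges
  keep <- keep[order(-run[keep], -support[keep], -csum[keep])]
  idx_by_cluster <- split(seq_len(n), cid)

  series <- list()
  used <- logical(nc)
  for (k in keep) {
    idx <- idx_by_cluster[[k]]
    idx <- idx[!used[ci[idx]]]
    if (!length(idx)) next
    # one member per charge (most intense centroid), each centroid once
    o <- idx[order(z[idx], -inten[idx])]
    o <- o[!duplicated(z[o])]
    o <- o[!duplicated(ci[o])]
    if (length(unique(z[o])) < min_states) next
    series[[length(series) + 1L]] <- structure(
      list(
        neutral_mass = stats::weighted.mean(M[o], inten[o]),
        members = data.frame(z = z[o], mz = mzv[o], intensity = inten[o]),
        intensity_sum = sum(inten[o])
      ),
      class = "charge_series"
    )
    used[ci[o]] <- TRUE
  }
  series <- series[order(vapply(series, `[[`, numeric(1L), "neutral_mass"))]
  if (share_collisions) {
    series <- share_collided_peaks(series, proton_mass = proton_mass)
  }
  series
}

#' @export
print.charge_series <- function(x, ...) {
  cat(sprintf("<charge_series> M = %.2f Da, %d charge states (z %d-%d), intensity %.3g\n",
              x$neutral_mass, nrow(x$members), min(x$members$z), max(x$members$z),
              x$intensity_sum))
  invisible(x)
}

# robust log-quadratic (Gaussian in z) envelope fit over a series'
# substantive members (negligible members — remnants of shared-away
# collisions, below 1e-4 of the base member — are excluded). Returns NULL
# when no concave fit is obtainable; otherwise a list with a `predict(z)`
# function (capped), `bad` (flagged outlier members) and `run` (the member
# subset used for fitting).
robust_envelope_fit <- function(members, k_mad = 2.5) {
  members <- members[members$intensity >= 1e-4 * max(members$intensity), ,
                     drop = FALSE]
  # genuine envelopes span a few charges around the base member; members
  # far outside (harmonic coincidences at integer mass ratios) would have
  # high leverage in the quadratic fit and are excluded from it
  z_peak <- members$z[which.max(members$intensity)]
  members <- members[abs(members$z - z_peak) <= 6L, , drop = FALSE]
  members <- members[order(members$z), , drop = FALSE]
  z <- members$z
  iy <- members$intensity
  if (length(z) < 4L) return(NULL)
  ly <- log(pmax(iy, 1e-300))
  fit <- stats::lm(ly ~ z + I(z^2))
  r <- stats::residuals(fit)
  s <- stats::mad(r)
  bad <- if (s > 0) abs(r) > k_mad * s else rep(FALSE, length(r))
  if (any(bad) && sum(!bad) >= 3L) {
    # refit on the clean members so collided states cannot tilt the fit
    fit <- stats::lm(ly ~ z + I(z^2), subset = !bad)
    r <- ly - stats::predict(fit, newdata = data.frame(z = z))
    s <- stats::mad(r[!bad])
    if (is.finite(s) && s > 0) bad <- abs(r) > k_mad * s
  }
  if (!is.finite(stats::coef(fit)[3L]) || stats::coef(fit)[3L] >= 0) return(NULL)
  cap <- 5 * max(iy)
  predictor <- function(zz) {
    p <- exp(stats::predict(fit, newdata = data.frame(z = zz)))
    p[!is.finite(p)] <- 0
    pmin(p, cap)
  }
  list(predict = predictor, bad = bad, run = members)
}

# envelope predictor used when apportioning collided centroids; falls back
# to the observed members (zero elsewhere) when no concave fit exists
fit_envelope <- function(members) {
  rf <- robust_envelope_fit(members)
  if (!is.null(rf)) return(rf$predict)
  z <- members$z
  iy <- members$intensity
  function(zz) {
    out <- iy[match(zz, z)]
    ifelse(is.na(out), 0, out)
  }
}

#' Split peak intensities collided between charge series
#'
#' In mixtures, two species' peaks at different charges occasionally fall
#' on the same m/z (mass ratios near small-integer charge ratios), so a
#' single centroid carries the summed intensity of both and the greedy
#' deconvolution awards it to one series. This pass finds centroids that
#' are consistent, at the clustering tolerance, with more than one series'
#' neutral mass at a plausible charge, and splits their intensity between
#' the claimants in proportion to each series' fitted charge-envelope
#' prediction at the respective charge. Series neutral masses are left
#' untouched (a merged apex position is not a reliable mass for either
#' partner).
#'
#' @param series List of `charge_series` from [infer_charge_series()].
#' @param collision_tol_ppm Mass tolerance for claiming a centroid, ppm.
#'   Merged apexes shift by up to about a peak width, so this is on the
#'   peak-width scale (hundreds of ppm), much wider than the series
#'   clustering tolerance.
#' @param proton_mass Proton mass, Da.
#' @return The series list with member intensities re-apportioned.
#' @export
share_collided_peaks <- function(series, collision_tol_ppm = 500,
                                 proton_mass = 1.00728, iterations = 2L) {
  if (length(series) < 2L) return(series)
  # claim ranges are fixed up front so claims cannot chain outward as
  # shared members are appended; negligible members do not extend them
  zranges <- lapply(series, function(s) {
    m <- s$members
    m <- m[m$intensity >= 1e-4 * max(m$intensity), , drop = FALSE]
    zr <- (min(m$z) - 5L):(max(m$z) + 5L)
    zr[zr >= 1L]
  })
  all_mz <- unique(unlist(lapply(series, function(s) s$members$mz)))
  # original centroid totals, keyed by m/z (each centroid is a member of
  # exactly one series before any sharing)
  totals <- new.env(parent = emptyenv())
  for (s in series) {
    for (k in seq_len(nrow(s$members))) {
      assign(format(s$members$mz[k], digits = 15L), s$members$intensity[k],
             envir = totals)
    }
  }
  for (iter in seq_len(iterations)) {
    # envelope fits from the current member intensities; on the first pass
    # these are the raw (possibly collision-corrupted) series
    envs <- lapply(series, function(s) fit_envelope(s$members))
    for (mzc in all_mz) {
      claims <- list()
      for (si in seq_along(series)) {
        s <- series[[si]]
        zr <- zranges[[si]]
        Mh <- zr * (mzc - proton_mass)
        okz <- zr[abs(Mh - s$neutral_mass) <= s$neutral_mass * collision_tol_ppm * 1e-6]
        if (!length(okz)) next
        zstar <- okz[1L]
        k <- which(s$members$z == zstar)
        # a series already holding a different centroid at this charge is
        # not missing the state and does not claim this one
        if (length(k) && s$members$mz[k] != mzc) next
        claims[[length(claims) + 1L]] <- list(si = si, z = zstar,
                                              member = length(k) > 0L)
      }
      if (length(claims) < 2L ||
          !any(vapply(claims, `[[`, logical(1L), "member"))) next
      I_tot <- get(format(mzc, digits = 15L), envir = totals)
      w <- vapply(claims, function(cl) max(envs[[cl$si]](cl$z), 1e-300), numeric(1L))
      w <- w / sum(w)
      for (ci in seq_along(claims)) {
        cl <- claims[[ci]]
        s <- series[[cl$si]]
        k <- which(s$members$mz == mzc)
        if (length(k)) {
          s$members$intensity[k] <- I_tot * w[ci]
        } else {
          s$members <- rbind(s$members,
                             data.frame(z = cl$z, mz = mzc, intensity = I_tot * w[ci]))
          s$members <- s$members[order(s$members$z), , drop = FALSE]
          rownames(s$members) <- NULL
        }
        s$intensity_sum <- sum(s$members$intensity)
        series[[cl$si]] <- s
      }
    }
  }
  series
}

#' Robust total intensity of a charge series
#'
#' Charge-state envelopes of natively folded ions are approximately
#' Gaussian in z, i.e. log-quadratic. In mixtures, peaks from different
#' species occasionally collide in m/z, corrupting (or stealing) single
#' charge states. This estimator fits a quadratic to log intensity over z,
#' flags members whose residual exceeds `k_mad` robust standard deviations,
#' and sums observed clean states plus fitted envelope values for flagged
#' and missing charge states over the plausible charge range, yielding a
#' total that is insensitive to isolated peak collisions. Series with fewer
#' than 4 members, or without a concave envelope fit, fall back to the
#' plain sum.
#'
#' @param series A `charge_series`.
#' @param k_mad Outlier threshold in robust standard deviations.
#' @return Estimated total intensity.
#' @export
series_intensity <- function(series, k_mad = 2.5) {
  m <- series$members
  rf <- robust_envelope_fit(m, k_mad)
  if (is.null(rf)) return(series$intensity_sum)
  run <- rf$run
  # integrate over the fitted members' charge range, extended so states
  # lost to collisions at the envelope edges are restored from the fit
  zz <- seq(min(run$z) - 5L, max(run$z) + 5L)
  pred <- rf$predict(zz)
  obs <- m$intensity[match(zz, m$z)]
  flagged <- zz %in% run$z[rf$bad]
  # any member far above the fitted envelope (a harmonic coincidence with
  # another species' peak, or an unrepaired collision) is replaced by it
  inconsistent <- !is.na(obs) & obs > 3 * pred
  use_pred <- is.na(obs) | flagged | inconsistent
  sum(ifelse(use_pred, pred, obs))
}

#' Percent mass error between observed and theoretical mass
#'
#' 100 * |observed - theoretical| / theoretical. The assignment criterion
#' used throughout is a percent error below 0.1.
#'
#' @param observed Observed neutral mass, Da.
#' @param theoretical Theoretical neutral mass, Da (> 0).
#' @return Percent error (vectorised).
#' @export
percent_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  100 * abs(observed - theoretical) / theoretical
}

#' Match a charge series against candidate complexes
#'
#' Computes the percent mass error against every candidate and retains
#' those at or below `max_pct_error`. Status is `"unique"` when exactly one
#' candidate passes, `"ambiguous"` for several (ambiguity is surfaced, not
#' resolved: compositions whose masses differ by less than the threshold
#' are genuinely indistinguishable), and `"unassigned"` for none. Decoy
#' candidates compete on the same footing and are reported distinctly.
#'
#' @param series A `charge_series` from [infer_charge_series()].
#' @param candidates Candidate table from [candidate_table()].
#' @param max_pct_error Assignment threshold in percent (default 0.1).
#' @return Object of class `assignment`: list with `series`, `candidates`
#'   (passing rows with `percent_error` and `ppm_error`, ascending error)
#'   and `status`.
#' @export
match_series <- function(series, candidates, max_pct_error = 0.1) {
  stopifnot(nrow(candidates) >= 1L)
  pe <- percent_error(series$neutral_mass, candidates$neutral_mass)
  hits <- candidates[pe <= max_pct_error, , drop = FALSE]
  hits$percent_error <- pe[pe <= max_pct_error]
  hits$ppm_error <- hits$percent_error * 1e4
  hits <- hits[order(hits$percent_error), , drop = FALSE]
  rownames(hits) <- NULL
  status <- if (nrow(hits) == 0L) "unassigned"
            else if (nrow(hits) == 1L) "unique"
            else "ambiguous"
  structure(list(series = series, candidates = hits, status = status),
            class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("<assignment> M = %.2f Da: %s (%d candidate(s) under threshold)\n",
              x$series$neutral_mass, x$status, nrow(x$candidates)))
  if (nrow(x$candidates)) {
    print(x$candidates[, c("label", "variant_key", "neutral_mass",
                           "percent_error", "is_decoy")])
  }
  invisible(x)
}

#' Quantify relative abundances from a set of assignments
#'
#' Series intensity is shared among the distinct candidate compositions
#' under the threshold and aggregated per composition. The default
#' `"weighted"` split shares in proportion to a Gaussian likelihood of each
#' candidate's mass error at the instrument-level precision
#' (`instrument_ppm`): the 0.1% assignment threshold is a biological
#' plausibility criterion three orders of magnitude looser than the
#' measurement precision, so candidates many instrument sigmas from the
#' observed mass contribute negligibly, while genuinely mass-degenerate
#' candidates still share roughly equally. `"equal"` ignores the mass
#' errors and shares equally. Relative abundances are percentages of
#' assigned intensity within each family; the dimer:hexamer ratio and the
#' decoy intensity share are reported per family. Compositions that ever
#' co-occur under the threshold form ambiguity groups (connected
#' components); group-summed abundances are reported alongside, since
#' members of a group are not distinguishable at the assignment tolerance.
#'
#' @param assignments List of `assignment` objects from [match_series()].
#' @param split `"weighted"` (default) or `"equal"`, see above.
#' @param instrument_ppm Instrument-level mass precision used by the
#'   `"weighted"` split, ppm.
#' @param intensity `"robust"` (default) estimates each series total with
#'   [series_intensity()], which repairs charge states corrupted by peak
#'   collisions between species; `"sum"` uses the plain summed centroid
#'   intensities.
#' @return Object of class `abundance_report`: list with
#'   `per_composition`, `dimer_to_hexamer_pct`, `decoy_intensity_pct`,
#'   `ambiguity_groups` and `unassigned_intensity`.
#' @export
quantify <- function(assignments, split = c("weighted", "equal"),
                     instrument_ppm = 50,
                     intensity = c("robust", "sum")) {
  split <- match.arg(split)
  intensity <- match.arg(intensity)
  series_total <- function(s) {
    if (intensity == "robust") series_intensity(s) else s$intensity_sum
  }
  stopifnot(length(assignments) >= 1L)
  rows <- list()
  unassigned <- 0
  pair_edges <- list()
  for (a in assignments) {
    if (a$status == "unassigned") {
      unassigned <- unassigned + series_total(a$series)
      next
    }
    comp <- unique(a$candidates[, c("label", "family", "n_dimers", "is_decoy")])
    w <- if (split == "equal") {
      rep(1, nrow(comp))
    } else {
      best_ppm <- vapply(comp$label, function(l) {
        min(a$candidates$ppm_error[a$candidates$label == l])
      }, numeric(1L))
      exp(-0.5 * (best_ppm / instrument_ppm)^2) + 1e-300
    }
    w <- w / sum(w)
    comp$intensity <- series_total(a$series) * w
    rows[[length(rows) + 1L]] <- comp
    if (nrow(comp) > 1L) {
      pair_edges[[length(pair_edges) + 1L]] <- comp$label
    }
  }
  if (!length(rows)) stop("no assigned series to quantify")
  per <- do.call(rbind, rows)
  agg <- stats::aggregate(intensity ~ label + family + n_dimers + is_decoy,
                          data = per, FUN = sum)
  # family-wise relative abundance (decoys included in the bookkeeping but
  # percentages are over each reported family tag, MIX decoys forming their own)
  agg$rel_abundance_pct <- NA_real_
  for (fam in unique(agg$family)) {
    sel <- agg$family == fam
    agg$rel_abundance_pct[sel] <- 100 * agg$intensity[sel] / sum(agg$intensity[sel])
  }
  agg <- agg[order(agg$family, -agg$intensity), ]
  rownames(agg) <- NULL

  dimer_hex <- lapply(split(agg, agg$family), function(d) {
    hex <- sum(d$intensity[d$n_dimers == 3L & !d$is_decoy])
    dim <- sum(d$intensity[d$n_dimers == 1L & !d$is_decoy])
    if (hex <= 0) NA_real_ else 100 * dim / hex
  })

  total_assigned <- sum(agg$intensity)
  decoy_pct <- 100 * sum(agg$intensity[agg$is_decoy]) / total_assigned

  # ambiguity groups: connected components over co-candidacy edges
  labels <- agg$label
  parent <- seq_along(labels)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in pair_edges) {
    idx <- match(e, labels)
    idx <- idx[!is.na(idx)]
    for (k in idx[-1L]) {
      ri <- find(idx[1L]); rk <- find(k)
      if (ri != rk) parent[rk] <- ri
    }
  }
  root <- vapply(seq_along(labels), find, integer(1L))
  groups <- lapply(split(seq_along(labels), root), function(ix) {
    list(members = labels[ix],
         family = unique(agg$family[ix]),
         intensity = sum(agg$intensity[ix]),
         rel_abundance_pct = sum(agg$rel_abundance_pct[ix]))
  })
  names(groups) <- vapply(groups, function(g) paste(g$members, collapse = " | "),
                          character(1L))

  structure(
    list(per_composition = agg,
         dimer_to_hexamer_pct = unlist(dimer_hex),
         decoy_intensity_pct = decoy_pct,
         ambiguity_groups = groups,
         unassigned_intensity = unassigned),
    class = "abundance_report"
  )
}

#' @export
print.abundance_report <- function(x, ...) {
  cat("Abundance report\n")
  print(x$per_composition)
  cat("dimer:hexamer (%):\n")
  print(round(x$dimer_to_hexamer_pct, 2))
  cat(sprintf("decoy intensity: %.3f%%, unassigned intensity: %.3g\n",
              x$decoy_intensity_pct, x$unassigned_intensity))
  invisible(x)
}

#' Predicted absorbance profile of a two-species mixture
#'
#' The UV-vis absorbance profile of an equal mixture is modelled as the
#' pointwise mean of the two individual profiles. Profiles on different
#' wavelength grids are linearly interpolated onto the overlapping range.
#'
#' @param profile_a,profile_b Data frames with columns `wavelength` and
#'   `absorbance`.
#' @param measured_mix Optional measured mixture profile (same columns);
#'   when given, the RMS deviation between prediction and measurement is
#'   returned.
#' @return List with `wavelength`, `predicted` and (if measured) `rms`.
#' @export
predict_mixture_absorbance <- function(profile_a, profile_b, measured_mix = NULL) {
  rng <- c(max(min(profile_a$wavelength), min(profile_b$wavelength)),
           min(max(profile_a$wavelength), max(profile_b$wavelength)))
  if (rng[1L] >= rng[2L]) stop("absorbance profiles have disjoint wavelength ranges")
  grid <- if (!is.null(measured_mix)) {
    w <- measured_mix$wavelength
    w[w >= rng[1L] & w <= rng[2L]]
  } else {
    w <- sort(unique(c(profile_a$wavelength, profile_b$wavelength)))
    w[w >= rng[1L] & w <= rng[2L]]
  }
  if (!length(grid)) stop("no wavelengths in the overlapping range")
  ya <- stats::approx(profile_a$wavelength, profile_a$absorbance, xout = grid)$y
  yb <- stats::approx(profile_b$wavelength, profile_b$absorbance, xout = grid)$y
  pred <- (ya + yb) / 2
  out <- list(wavelength = grid, predicted = pred)
  if (!is.null(measured_mix)) {
    ym <- stats::approx(measured_mix$wavelength, measured_mix$absorbance, xout = grid)$y
    out$rms <- sqrt(mean((pred - ym)^2))
  }
  out
}
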