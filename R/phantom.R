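#' Anisotropic cellulose scattering background
#'
#' A minimal model of the oriented-fibril background that plant tissue
#' contributes to a SAXS frame: a power law in q modulated azimuthally
#' around a preferred orientation,
#' `I_bg(q, theta) = A (q/q_ref)^-p [1 - f + f cos^2(theta - theta0)]`
#' with `q_ref = 0.01` 1/Angstrom, so `amplitude` is the unmodulated
#' background intensity at q = 0.01. The q-exponent of real leaf tissue is
#' not characterized here; `p` is a free simulator parameter.
#'
#' @param amplitude Background intensity at q = 0.01 1/Angstrom (a.u.,
#'   >= 0).
#' @param power_law_exponent Power-law exponent p (default 2.5).
#' @param anisotropy_fraction Fraction f of the background that is
#'   orientation-modulated, in \[0, 1\].
#' @param preferred_orientation Preferred azimuth theta0 in radians.
#' @return An object of class `cellulose_background`.
#' @export
cellulose_background <- function(amplitude = 50, power_law_exponent = 2.5,
                                 anisotropy_fraction = 0.5,
                                 preferred_orientation = 0) {
  stopifnot(amplitude >= 0,
            anisotropy_fraction >= 0, anisotropy_fraction <= 1)
  structure(list(amplitude = amplitude,
                 power_law_exponent = power_law_exponent,
                 anisotropy_fraction = anisotropy_fraction,
                 preferred_orientation = preferred_orientation),
            class = "cellulose_background")
}

.BG_QREF <- 0.01  # 1/Angstrom; reference q at which `amplitude` is quoted

#' Default phantom beam geometry
#'
#' 20.129 keV on a 64 x 64 detector of 172 um pixels at 2250 mm, beam
#' center mid-frame: the frame then spans q up to ~0.025 1/Angstrom,
#' covering the 0.004-0.022 analysis window.
#'
#' @param frame_dim Detector side length in pixels (default 64).
#' @return A [beam_geometry()].
#' @export
phantom_beam <- function(frame_dim = 64) {
  beam_geometry(energy_kev = 20.129, distance_mm = 2250, pixel_um = 172,
                center = c((frame_dim + 1) / 2, (frame_dim + 1) / 2))
}

#' Specification of a synthetic SAXS mesh scan
#'
#' Every pixel of every frame is the sum of an isotropic particle term
#' (the model's form factor at the pixel's q, scaled by the local
#' concentration) and the anisotropic cellulose background, optionally
#' Poisson-sampled. A fixed seed makes all outputs bit-identical.
#'
#' @param beam A [beam_geometry()] (default [phantom_beam()]).
#' @param mesh_shape `c(rows, cols)` of the scan grid.
#' @param particle A [particle_model()].
#' @param concentration_field Non-negative matrix over the mesh scaling
#'   the particle concentration per point (default all 1).
#' @param background A [cellulose_background()].
#' @param anisotropy_field,orientation_field Optional per-point matrices
#'   overriding the background's scalar anisotropy fraction / preferred
#'   orientation.
#' @param noise `"poisson"` or `"none"`.
#' @param frame_dim Detector side length in pixels.
#' @param seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(beam = NULL, mesh_shape = c(8, 8),
                         particle = particle_model("cylinder", length = 280,
                                                   radius = 80,
                                                   concentration = 200),
                         concentration_field = NULL,
                         background = cellulose_background(),
                         anisotropy_field = NULL, orientation_field = NULL,
                         noise = c("poisson", "none"),
                         frame_dim = 64, seed = 1) {
  noise <- match.arg(noise)
  if (is.null(beam)) beam <- phantom_beam(frame_dim)
  if (is.null(concentration_field))
    concentration_field <- matrix(1, mesh_shape[1], mesh_shape[2])
  stopifnot(all(dim(concentration_field) == mesh_shape),
            all(concentration_field >= 0),
            inherits(particle, "particle_model"),
            inherits(background, "cellulose_background"))
  for (fld in list(anisotropy_field, orientation_field))
    if (!is.null(fld)) stopifnot(all(dim(fld) == mesh_shape))
  structure(list(beam = beam, mesh_shape = as.integer(mesh_shape),
                 particle = particle,
                 concentration_field = concentration_field,
                 background = background,
                 anisotropy_field = anisotropy_field,
                 orientation_field = orientation_field,
                 noise = noise, frame_dim = as.integer(frame_dim),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# per-spec precomputation: q/theta maps and the unit-concentration form
# factor evaluated on the pixel q values
.phantom_cache <- function(spec) {
  qt <- .qtheta_map(spec$beam, c(spec$frame_dim, spec$frame_dim))
  unit <- spec$particle
  unit$concentration <- 1
  ff <- matrix(form_factor_intensity(unit, as.vector(qt$q)),
               spec$frame_dim, spec$frame_dim)
  # floor q at the half-pixel value so the power-law background stays
  # finite at the beam center
  qfloor <- pixel_q_theta(spec$beam, spec$beam$center + c(0, 0.5))$q
  qb <- pmax(qt$q, qfloor)
  list(qt = qt, ff = ff, qb = qb)
}

.phantom_point_intensity <- function(spec, row, col, cache) {
  f <- if (is.null(spec$anisotropy_field)) spec$background$anisotropy_fraction
       else spec$anisotropy_field[row, col]
  th0 <- if (is.null(spec$orientation_field)) spec$background$preferred_orientation
         else spec$orientation_field[row, col]
  conc <- spec$concentration_field[row, col] * spec$particle$concentration
  theta <- cache$qt$theta
  theta[is.na(theta)] <- 0  # center pixel: modulation value is arbitrary
  bg <- spec$background$amplitude * (cache$qb / .BG_QREF)^(-spec$background$power_law_exponent) *
    (1 - f + f * cos(theta - th0)^2)
  conc * cache$ff + bg
}

.point_seed <- function(spec, idx) {
  as.integer((abs(spec$seed) * 7919 + idx * 104729) %% .Machine$integer.max)
}

#' Render one synthetic detector frame
#'
#' @param spec A [phantom_spec()].
#' @param point `c(row, col)` within the mesh.
#' @return A [detector_frame()]. Deterministic for a fixed spec (the
#'   Poisson stream is seeded per point from the spec seed).
#' @export
render_frame <- function(spec, point) {
  stopifnot(inherits(spec, "phantom_spec"),
            point[1] >= 1, point[1] <= spec$mesh_shape[1],
            point[2] >= 1, point[2] <= spec$mesh_shape[2])
  cache <- .phantom_cache(spec)
  .render_frame_cached(spec, point[1], point[2], cache)
}

.render_frame_cached <- function(spec, row, col, cache) {
  lambda <- .phantom_point_intensity(spec, row, col, cache)
  counts <- if (spec$noise == "poisson") {
    idx <- (row - 1L) * spec$mesh_shape[2] + col
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(.point_seed(spec, idx))
    matrix(stats::rpois(length(lambda), as.vector(lambda)),
           spec$frame_dim, spec$frame_dim)
  } else lambda
  detector_frame(counts, exposure_time = spec$beam$exposure_time)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Render a full synthetic mesh scan
#'
#' @param spec A [phantom_spec()].
#' @return A [mesh_scan()]; identical to calling [render_frame()] at every
#'   point.
#' @export
render_mesh_scan <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cache <- .phantom_cache(spec)
  frames <- vector("list", prod(spec$mesh_shape))
  k <- 0L
  for (r in seq_len(spec$mesh_shape[1])) for (cc in seq_len(spec$mesh_shape[2])) {
    k <- k + 1L
    frames[[k]] <- .render_frame_cached(spec, r, cc, cache)
  }
  mesh_scan(frames, spec$mesh_shape, spec$beam)
}

#' Simulate a noisy Guinier-regime scattering curve
#'
#' I(q) = i0 exp(-q^2 rg^2 / 3) with multiplicative Gaussian noise of
#' relative standard deviation `noise`; the reported sigma is the true
#' per-point standard deviation `noise * I(q)`.
#'
#' @param rg Gyration radius in Angstrom.
#' @param i0 Forward intensity (a.u.).
#' @param q Scattering vector grid (default 30 points on 0.0015-0.0044).
#' @param noise Relative noise level (default 0.01; 0 for noiseless).
#' @param seed Optional integer seed.
#' @return A [curve1d()].
#' @export
simulate_guinier_curve <- function(rg, i0, q = seq(0.0015, 0.0044,
                                                   length.out = 30),
                                   noise = 0.01, seed = NULL) {
  stopifnot(rg > 0, i0 > 0, noise >= 0)
  ideal <- i0 * exp(-q^2 * rg^2 / 3)
  if (noise == 0) return(curve1d(q, ideal))
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  curve1d(q, ideal * (1 + stats::rnorm(length(q), 0, noise)), noise * ideal)
}

#' Simulate a dilution series of a particle model
#'
#' Generates one noisy low-q curve per dilution factor from the model's
#' form factor (concentration divided by the factor) and Guinier-fits each,
#' returning a ready [dilution_series()].
#'
#' @param particle A [particle_model()]; its concentration is the
#'   baseline.
#' @param dilution_factors Numeric factors (the baseline 1 is added if
#'   absent).
#' @param q Scattering vector grid; default covers the model's Guinier
#'   regime (q_max x Rg ~ 1.3).
#' @param noise Relative noise level (default 0.01).
#' @param seed Integer seed.
#' @return A [dilution_series()].
#' @export
simulate_dilution_series <- function(particle, dilution_factors = c(5, 9),
                                     q = NULL, noise = 0.01, seed = 1) {
  stopifnot(inherits(particle, "particle_model"))
  if (!1 %in% dilution_factors) dilution_factors <- c(1, dilution_factors)
  if (is.null(q)) {
    rg <- radius_of_gyration(particle)
    q <- seq(0.3 / rg, 1.3 / rg, length.out = 40)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  fits <- lapply(dilution_factors, function(d) {
    ideal <- form_factor_intensity(particle, q) / d
    noisy <- ideal * (1 + stats::rnorm(length(q), 0, noise))
    guinier_fit(curve1d(q, noisy, noise * ideal))
  })
  labels <- ifelse(dilution_factors == 1, "baseline",
                   sprintf("%g-fold", dilution_factors))
  dilution_series(labels, dilution_factors, fits, baseline_label = "baseline")
}

# ---------------------------------------------------------------------------
# time-series phantoms: per-mode signal evolution

# per-mode multipliers as functions of day; chosen so that every modality
# either moves well clear of the +/-10% stability band by the last day or
# stays well inside it. ct_n multiplies the cluster count (fragmentation),
# ct_amp the cluster peak gray, ct_spread the cluster width.
.MODE_FACTORS <- list(
  dissolution = function(d) list(saxs = exp(-0.55 * d), ct_amp = 1,
                                 ct_spread = 1, ct_n = 1,
                                 p = exp(-0.8 * d), ce = 1),
  aggregation = function(d) list(saxs = exp(-0.4 * d), ct_amp = 1 + 0.25 * d,
                                 ct_spread = 1 / (1 + 0.08 * d), ct_n = 1,
                                 p = 1, ce = 1),
  translocation = function(d) list(saxs = exp(-0.6 * d), ct_amp = exp(-0.35 * d),
                                   ct_spread = 1, ct_n = 1,
                                   p = exp(-0.4 * d), ce = exp(-0.4 * d)),
  dispersion = function(d) list(saxs = 1 + 0.3 * d, ct_amp = 1 / (1 + 0.4 * d),
                                ct_spread = 1 + 0.1 * d, ct_n = 1 + 0.6 * d,
                                p = 1, ce = 1)
)

# candidate cluster centers with a minimum mutual distance, drawn once per
# seed so that a day series shares the same sites (fragmentation appends
# new sites after the original ones)
.cluster_sites <- function(dim3, n, sigma0, seed) {
  d <- dim3
  zlo <- round(d * 0.3); zhi <- round(d * 0.7)
  m <- round(d * 0.1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  min_dist <- 4.2 * sigma0
  pts <- matrix(numeric(0), 0, 3)
  tries <- 0
  while (nrow(pts) < n && tries < 500 * n) {
    tries <- tries + 1
    cand <- c(stats::runif(1, m + sigma0 * 2, d - m - sigma0 * 2),
              stats::runif(1, m + sigma0 * 2, d - m - sigma0 * 2),
              stats::runif(1, zlo + 2, zhi - 2))
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 3, byrow = TRUE))^2))) >= min_dist)
      pts <- rbind(pts, cand)
  }
  pts
}

# synthetic leaf volume with Gaussian nanoparticle clusters.
# cluster sites are drawn once from `seed` (shared across a day series);
# the additive noise stream varies with `noise_seed`. the default cluster
# count scales with the volume so the nanoparticle-labelled fraction of the
# leaf is size-independent; each blob only touches its 4-sigma neighbourhood.
.render_ct_volume <- function(dim3 = 48, amp = 0.6, spread = 1,
                              n_clusters = NULL, sigma0 = 2.5, seed = 1,
                              noise_seed = seed) {
  d <- dim3
  if (is.null(n_clusters)) n_clusters <- max(1L, round(5 * (d / 48)^3))
  zlo <- round(d * 0.3); zhi <- round(d * 0.7)
  m <- round(d * 0.1)  # x-y air margin
  centers <- .cluster_sites(d, n_clusters, sigma0, seed)
  n_clusters <- nrow(centers)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(noise_seed %% .Machine$integer.max))
  gray <- array(stats::rnorm(d^3, 0.08, 0.02), c(d, d, d))
  leaf <- array(FALSE, c(d, d, d))
  leaf[(m + 1):(d - m), (m + 1):(d - m), zlo:zhi] <- TRUE
  gray[leaf] <- stats::rnorm(sum(leaf), 0.35, 0.03)
  sg <- sigma0 * spread
  w <- ceiling(4 * sg)
  for (k in seq_len(n_clusters)) {
    ix <- max(1, floor(centers[k, 1]) - w):min(d, ceiling(centers[k, 1]) + w)
    iy <- max(1, floor(centers[k, 2]) - w):min(d, ceiling(centers[k, 2]) + w)
    iz <- max(1, floor(centers[k, 3]) - w):min(d, ceiling(centers[k, 3]) + w)
    gx <- exp(-(ix - centers[k, 1])^2 / (2 * sg^2))
    gy <- exp(-(iy - centers[k, 2])^2 / (2 * sg^2))
    gz <- exp(-(iz - centers[k, 3])^2 / (2 * sg^2))
    blob <- amp * outer(outer(gx, gy), gz)
    gray[ix, iy, iz] <- gray[ix, iy, iz] + blob * leaf[ix, iy, iz]
  }
  volume3d(gray, description = sprintf("synthetic leaf phantom (amp %.3g, spread %.3g, %d clusters)",
                                       amp, spread, n_clusters))
}

# synthetic element map on the mesh grid: tissue texture plus signal in the
# infiltrated region. the per-pixel deposition pattern (lognormal, from
# `site_seed`) is spatial heterogeneity of the infiltration and is held
# fixed across a day series; only the overall level and a small temporal
# noise (from `seed`) evolve.
.render_xrf_map <- function(element, mesh_shape, region_mask, region_level,
                            seed, site_seed = seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  n <- sum(region_mask)
  set.seed(as.integer(site_seed %% .Machine$integer.max))
  site <- exp(stats::rnorm(n, 0, 0.5))
  set.seed(as.integer(seed %% .Machine$integer.max))
  base <- matrix(stats::rgamma(prod(mesh_shape), shape = 20, rate = 20),
                 mesh_shape[1], mesh_shape[2])
  sig <- matrix(0, mesh_shape[1], mesh_shape[2])
  sig[region_mask] <- region_level * site * (1 + stats::rnorm(n, 0, 0.05))
  element_map(element, pmax(base + sig, 0))
}

# default infiltrated region: a centered disc covering ~1/4 of the mesh
.default_region_mask <- function(mesh_shape) {
  r0 <- (mesh_shape[1] + 1) / 2; c0 <- (mesh_shape[2] + 1) / 2
  rad <- min(mesh_shape) * 0.28
  outer(seq_len(mesh_shape[1]), seq_len(mesh_shape[2]),
        function(r, cc) (r - r0)^2 + (cc - c0)^2 <= rad^2)
}

#' Render a multimodal time series of phantoms
#'
#' For each day, generates the three modalities with the signal evolution
#' characteristic of one nanoparticle process:
#' * `dissolution` -- SAXS total scattering decays, the CT
#'   nanoparticle-region gray level is stable, the mobile element (P)
#'   decays, the immobile tracer (Ce) is stable;
#' * `aggregation` -- SAXS decays, CT gray rises, both elements stable;
#' * `translocation` -- SAXS, CT and both elements all decay;
#' * `dispersion` -- SAXS rises, CT gray falls (clusters spread: the
#'   segmentation threshold falls and the volume fraction rises), elements
#'   stable.
#'
#' Cluster positions (CT) and the infiltrated region (SAXS/XRF) are held
#' fixed across days; only amplitudes, spreads and noise streams evolve.
#'
#' @param days Ascending day numbers, e.g. `c(0, 1, 3)`.
#' @param mode One of `"dissolution"`, `"dispersion"`, `"translocation"`,
#'   `"aggregation"`.
#' @param seed Integer seed; all randomness derives from it.
#' @param mesh_shape Mesh grid of the SAXS scan (default `c(8, 8)`).
#' @param frame_dim SAXS detector side length (default 32).
#' @param vol_dim CT volume side length in voxels (default 48).
#' @param noise SAXS frame noise, `"poisson"` or `"none"`.
#' @return A list of class `phantom_timeseries`: per day a list with
#'   `day`, `scan` ([mesh_scan()]), `volume` ([volume3d()]), `xrf` (list
#'   of `P` and `Ce` [element_map()]s); plus attributes `region_mask`,
#'   `mode`, `days`.
#' @export
render_timeseries_phantoms <- function(days, mode = c("dissolution",
                                                      "dispersion",
                                                      "translocation",
                                                      "aggregation"),
                                       seed = 1, mesh_shape = c(8, 8),
                                       frame_dim = 32, vol_dim = 48,
                                       noise = "poisson") {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(days))
  factors <- .MODE_FACTORS[[mode]]
  region <- .default_region_mask(mesh_shape)
  out <- lapply(seq_along(days), function(i) {
    d <- days[i]
    fx <- factors(d)
    conc <- matrix(0.05, mesh_shape[1], mesh_shape[2])
    conc[region] <- fx$saxs
    spec <- phantom_spec(mesh_shape = mesh_shape,
                         concentration_field = conc,
                         background = cellulose_background(amplitude = 5,
                                                           anisotropy_fraction = 0.4,
                                                           preferred_orientation = 0.8),
                         noise = noise, frame_dim = frame_dim,
                         seed = seed + 13 * i)
    vol <- .render_ct_volume(vol_dim, amp = 0.6 * fx$ct_amp,
                             spread = fx$ct_spread,
                             n_clusters = max(1L, round(5 * (vol_dim / 48)^3 * fx$ct_n)),
                             seed = seed, noise_seed = seed + 101 * i)
    xrf <- list(
      P = .render_xrf_map("P", mesh_shape, region, 5 * fx$p,
                          seed + 211 * i, site_seed = seed + 7),
      Ce = .render_xrf_map("Ce", mesh_shape, region, 5 * fx$ce,
                           seed + 307 * i, site_seed = seed + 11))
    list(day = d, scan = render_mesh_scan(spec), volume = vol, xrf = xrf)
  })
  structure(out, region_mask = region, mode = mode, days = days,
            class = "phantom_timeseries")
}

#' Classify a phantom (or real) multimodal time series
#'
#' Convenience round trip: total-scattering maps from each day's mesh scan,
#' then [correlate_case()] with the immobile-tracer (Ce) maps.
#'
#' @param ts A `phantom_timeseries` from [render_timeseries_phantoms()],
#'   or any list with the same per-day structure plus a `region_mask`
#'   attribute.
#' @param q_lo,q_hi Analysis q-window for the total-scattering maps.
#' @param band Stability half-band.
#' @return The [correlate_case()] result.
#' @export
classify_timeseries <- function(ts, q_lo = 0.004, q_hi = 0.022, band = 0.10) {
  days <- attr(ts, "days")
  if (length(days) < 2) stop("insufficient timepoints: need at least 2 days")
  maps <- lapply(ts, function(x) total_scattering_map(x$scan, q_lo, q_hi))
  correlate_case(maps,
                 lapply(ts, `[[`, "volume"),
                 lapply(ts, function(x) x$xrf$Ce),
                 attr(ts, "region_mask"), days, band = band)
}
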