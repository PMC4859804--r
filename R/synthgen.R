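#' Topography parameters of the synthetic generator
#'
#' Defines the generative topography a synthetic study obeys: the terminal
#' field's dorsoventral center falls linearly with the injection's
#' rostrocaudal coordinate (caudal injections label ventral target levels),
#' and its transverse center rises linearly with the injection's dorsoventral
#' coordinate (ventral injections label proximal/medial positions). Labeling
#' density grows with age: animals in the first postnatal days carry a
#' handful of single fibers, while from about postnatal day 12 an adult-like
#' dense plexus is emitted as graded boundary intervals instead of fiber
#' lists. All numeric defaults are generator choices calibrated to produce
#' study-like synthetic data; none is an empirical measurement.
#'
#' @param slope_rc_to_dv change of terminal dorsoventral center per unit
#'   injection rc (negative: caudal -> ventral).
#' @param intercept_dv terminal dorsoventral center at rc = 0.
#' @param slope_dv_to_tr change of terminal transverse center per unit
#'   injection dv (positive: dorsal -> distal/lateral).
#' @param intercept_tr terminal transverse center at dv = 0.
#' @param spread standard deviation of the terminal field (flatmap units).
#' @param center_jitter per-experiment biological jitter of the terminal
#'   center (flatmap units).
#' @param density_base,density_rate expected fiber count per subdivision is
#'   `density_base * exp(density_rate * (age - 1))` (non-decreasing in age).
#' @param plexus_age age (days) from which labeling is emitted as a graded
#'   dense plexus rather than single fibers.
#' @return a `topography_params` list.
#' @export
topography_params <- function(slope_rc_to_dv = -0.4, intercept_dv = 0.75,
                              slope_dv_to_tr = 0.4, intercept_tr = 0.3,
                              spread = 0.08, center_jitter = 0.05,
                              density_base = 3, density_rate = 0.25,
                              plexus_age = 12) {
  stopifnot(spread > 0, density_base > 0, density_rate >= 0)
  structure(list(slope_rc_to_dv = slope_rc_to_dv,
                 intercept_dv = intercept_dv,
                 slope_dv_to_tr = slope_dv_to_tr,
                 intercept_tr = intercept_tr,
                 spread = spread, center_jitter = center_jitter,
                 density_base = density_base, density_rate = density_rate,
                 plexus_age = plexus_age),
            class = "topography_params")
}

density_by_age <- function(age, params) {
  params$density_base * exp(params$density_rate * (age - 1))
}

#' Generate a synthetic cortical strip with embedded injection points
#'
#' Builds dorsal and ventral border polylines of a strip running along the
#' rostrocaudal axis — flat for `curvature = 0`, cylindrically bent across
#' the dorsoventral axis otherwise — and places points at known normalized
#' (rc, dv) ground truth, displaced off the surface by a fixed offset along
#' the outward normal, so surface transposition and coordinate normalization
#' can be tested against the generating parameters.
#'
#' @param curvature bending curvature (1/mm, >= 0).
#' @param n_sites number of embedded points.
#' @param length_mm,width_mm strip dimensions (mm).
#' @param n_points vertices per border polyline.
#' @param offset_mm off-surface displacement of the embedded points (mm).
#' @param seed optional RNG seed for the site coordinates.
#' @return list with `borders` (named list of [border_polyline()]s) and
#'   `sites` (data.frame `rc_true`, `dv_true`, `x`, `y`, `z`).
#' @export
gen_surface <- function(curvature = 0, n_sites = 20L, length_mm = 8,
                        width_mm = 3, n_points = 41L, offset_mm = 0.4,
                        seed = NULL) {
  if (curvature < 0) stop("curvature must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  embed <- function(u, v_frac) {
    ## u: rostrocaudal fraction, v_frac: dorsoventral fraction (0 = ventral)
    x <- u * length_mm
    v <- v_frac * width_mm
    if (curvature == 0) cbind(x = x, y = v, z = 0 * v)
    else {
      R <- 1 / curvature
      phi <- v / R
      cbind(x = x, y = R * sin(phi), z = R * (1 - cos(phi)))
    }
  }
  normal_at <- function(v_frac) {
    if (curvature == 0) return(cbind(0, 0 * v_frac, -1 + 0 * v_frac))
    phi <- v_frac * width_mm * curvature
    cbind(0, sin(phi), -cos(phi))
  }
  u <- seq(0, 1, length.out = n_points)
  borders <- list(
    dorsal_of_area = border_polyline(embed(u, 1), role = "dorsal_of_area"),
    ventral_of_area = border_polyline(embed(u, 0), role = "ventral_of_area"))
  sites <- data.frame(rc_true = numeric(0), dv_true = numeric(0),
                      x = numeric(0), y = numeric(0), z = numeric(0))
  if (n_sites > 0L) {
    rc <- stats::runif(n_sites)
    dv <- stats::runif(n_sites)
    p <- embed(rc, dv) + offset_mm * normal_at(dv)
    sites <- data.frame(rc_true = rc, dv_true = dv,
                        x = p[, 1], y = p[, 2], z = p[, 3])
  }
  list(borders = borders, sites = sites)
}

## smooth unimodal transverse-extent profile (normalized position x in [0,1])
.profile_shape <- function(x, peak) 0.3 + 0.7 * exp(-(x - peak)^2 / (2 * 0.25^2))

## baseline transverse extents (um) and profile peaks per subdivision
.SUB_BASE <- c(PrS_sup = 1200, PrS_deep = 1000, PaS_deep = 800,
               MEC_deep = 2000, LEC_deep = 1800)
.SUB_PEAK <- c(PrS_sup = 0.45, PrS_deep = 0.45, PaS_deep = 0.55,
               MEC_deep = 0.5, LEC_deep = 0.6)

#' Generate per-animal section-measurement records
#'
#' Each animal gets a smooth unimodal transverse-extent profile per
#' subdivision, scaled by a monotone growth factor `1 + 0.05 * age` so older
#' brains are larger, sampled at its own sections (count set by the animal's
#' dorsoventral extent over the series spacing) with multiplicative lognormal
#' noise. Section counts therefore differ across ages, and the oldest animal
#' sets the flatmap row count.
#'
#' @param n number of animals.
#' @param ages postnatal ages in days (recycled to length `n`).
#' @param spacing_um series spacing between sections (µm).
#' @param noise_sdlog lognormal measurement noise (0 = exact profiles).
#' @param subdivisions which subdivisions to measure.
#' @param base_dv_um dorsoventral extent of the region at age 0 (µm).
#' @param seed optional RNG seed.
#' @return list of [animal_record()]s, ids `"A001"`, `"A002"`, ...
#' @export
gen_animals <- function(n, ages = 1:19, spacing_um = 300,
                        noise_sdlog = 0.08,
                        subdivisions = PHR_SUBDIVISIONS,
                        base_dv_um = 4500, seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ages <- rep_len(ages, n)
  recs <- vector("list", n)
  for (k in seq_len(n)) {
    g <- 1 + 0.05 * ages[k]
    dv_um <- base_dv_um * g
    n_sec <- max(3L, as.integer(round(dv_um / spacing_um)))
    x <- (seq_len(n_sec) - 0.5) / n_sec
    rows <- list()
    for (sub in subdivisions) {
      s <- .SUB_BASE[[sub]] * g * .profile_shape(x, .SUB_PEAK[[sub]])
      if (noise_sdlog > 0)
        s <- s * exp(stats::rnorm(n_sec, 0, noise_sdlog))
      rows[[sub]] <- data.frame(section_index = seq_len(n_sec),
                                subdivision = sub, transverse_um = s,
                                stringsAsFactors = FALSE)
    }
    recs[[k]] <- animal_record(sprintf("A%03d", k), ages[k],
                               do.call(rbind, rows), spacing_um = spacing_um)
  }
  names(recs) <- vapply(recs, function(r) r$animal_id, character(1))
  recs
}

#' Generate labeling observations for one injection
#'
#' The terminal field center follows the linear topography maps: its
#' dorsoventral position is a function of the injection's rc, its transverse
#' position a function of the injection's dv, plus per-experiment center
#' jitter. Young animals (below `plexus_age`) yield Poisson-many single-fiber
#' positions drawn from a truncated bivariate Gaussian around the center;
#' older animals yield graded dense-plexus intervals per section, the grade
#' obtained by thresholding the generating Gaussian density (grade 3 at the
#' modal rows, 1-2 at the flanks) and the interval from the density's
#' 10%-of-peak level set. Distances are emitted in µm from each
#' subdivision's reference border, in the table layout the pipeline reads.
#'
#' @param experiment_id scalar id.
#' @param rc,dv ground-truth normalized injection coordinates.
#' @param age postnatal age (days) of the injected animal.
#' @param animal the injected animal's [animal_record()] (its sections carry
#'   the observations).
#' @param params a [topography_params()].
#' @param subdivisions subdivisions in which labeling is generated.
#' @return list with `obs` (observation data.frame) and `truth`
#'   (`mu_dv`, `mu_tr`).
#' @export
gen_projection <- function(experiment_id, rc, dv, age, animal,
                           params = topography_params(),
                           subdivisions = PHR_SUBDIVISIONS) {
  clamp <- function(x, lo = 0.02, hi = 0.98) pmin(pmax(x, lo), hi)
  mu_dv <- clamp(params$intercept_dv + params$slope_rc_to_dv * rc +
                 stats::rnorm(1, 0, params$center_jitter))
  mu_tr <- clamp(params$intercept_tr + params$slope_dv_to_tr * dv +
                 stats::rnorm(1, 0, params$center_jitter))
  n_sec <- animal$n_sections
  sec <- animal$sections
  sec_idx <- sec$section_index; sec_sub <- sec$subdivision
  sec_ext <- sec$transverse_um
  ext_of <- function(j, sub) sec_ext[sec_idx == j & sec_sub == sub]
  acc <- list(sub = character(0), j = integer(0), kind = character(0),
              start = numeric(0), end = numeric(0), grade = numeric(0))
  emit <- function(sub, j, kind, start_um, end_um, grade) {
    acc$sub <<- c(acc$sub, sub); acc$j <<- c(acc$j, j)
    acc$kind <<- c(acc$kind, kind); acc$start <<- c(acc$start, start_um)
    acc$end <<- c(acc$end, end_um); acc$grade <<- c(acc$grade, grade)
  }
  rtrunc_norm <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    for (it in 1:50) {
      bad <- x < 0 | x > 1
      if (!any(bad)) break
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    pmin(pmax(x, 0), 1)
  }
  for (sub in subdivisions) {
    flip <- is_distal_referenced(sub)
    if (age < params$plexus_age) {
      n_fib <- stats::rpois(1, density_by_age(age, params))
      if (n_fib == 0) next
      y <- rtrunc_norm(n_fib, mu_dv, params$spread)   # 1 = dorsal
      x <- rtrunc_norm(n_fib, mu_tr, params$spread)
      j <- pmin(pmax(ceiling((1 - y) * n_sec), 1L), n_sec)
      for (f in seq_len(n_fib)) {
        ext <- ext_of(j[f], sub)
        pos <- if (flip) (1 - x[f]) * ext else x[f] * ext
        emit(sub, j[f], "fiber", pos, NA_real_, NA_real_)
      }
    } else {
      for (j in seq_len(n_sec)) {
        y_c <- 1 - (j - 0.5) / n_sec
        w <- exp(-(y_c - mu_dv)^2 / (2 * params$spread^2))
        if (w < 0.1) next
        grade <- if (w >= 0.75) 3L else if (w >= 0.4) 2L else 1L
        h <- params$spread * sqrt(2 * log(10 * w))
        a <- max(0, mu_tr - h); b <- min(1, mu_tr + h)
        if (b <= a) next
        ext <- ext_of(j, sub)
        if (flip) { tmp <- a; a <- 1 - b; b <- 1 - tmp }
        emit(sub, j, "plexus", a * ext, b * ext, grade)
      }
    }
  }
  obs <- data.frame(experiment_id = rep(experiment_id, length(acc$sub)),
                    animal_id = rep(animal$animal_id, length(acc$sub)),
                    section_index = acc$j, subdivision = acc$sub,
                    kind = acc$kind, start_um = acc$start, end_um = acc$end,
                    grade = acc$grade, stringsAsFactors = FALSE)
  list(obs = obs, truth = c(mu_dv = mu_dv, mu_tr = mu_tr))
}

#' Generate a complete synthetic tracing study
#'
#' Composes the surface, animal-measurement and projection generators into
#' one seeded, fully reproducible study: every experiment is an injected
#' animal with an age, a ground-truth injection location embedded off a
#' synthetic curved strip, per-section measurements of the target region,
#' and topographically organized labeling observations on its own sections.
#' The same `(config, seed)` always yields identical tables.
#'
#' @param config named list overriding defaults: `n_experiments` (100),
#'   `ages` (sampled from 1..19 days), `curvature` (0.15/mm), `spacing_um`
#'   (300), `noise_sdlog` (0.08), `subdivisions` (all five),
#'   `params` (a [topography_params()]), `length_mm`, `width_mm`,
#'   `n_points`, `offset_mm`. Unknown keys are an error.
#' @param seed integer RNG seed.
#' @return a `synthetic_study`: list with `measurements`, `injections`
#'   (including ground-truth `rc_true`/`dv_true`), `observations`, `borders`
#'   (polyline table), `truth` (per-experiment terminal centers), `animals`,
#'   `border_polylines`, `spec` (the average flatmap), `params`, `config`,
#'   `seed`.
#' @export
gen_study <- function(config = list(), seed = 1L) {
  defaults <- list(n_experiments = 100L, ages = NULL, curvature = 0.15,
                   spacing_um = 300, noise_sdlog = 0.08,
                   subdivisions = PHR_SUBDIVISIONS,
                   params = topography_params(),
                   length_mm = 8, width_mm = 3, n_points = 41L,
                   offset_mm = 0.4)
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop("invalid config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  set.seed(seed)
  n <- as.integer(cfg$n_experiments)
  empty_study <- function() {
    structure(list(
      measurements = data.frame(animal_id = character(0),
                                age_days = numeric(0),
                                section_index = integer(0),
                                subdivision = character(0),
                                transverse_um = numeric(0),
                                series_spacing_um = numeric(0)),
      injections = data.frame(experiment_id = character(0),
                              animal_id = character(0), age_days = numeric(0),
                              x = numeric(0), y = numeric(0), z = numeric(0),
                              rc_true = numeric(0), dv_true = numeric(0)),
      observations = data.frame(experiment_id = character(0),
                                animal_id = character(0),
                                section_index = integer(0),
                                subdivision = character(0),
                                kind = character(0), start_um = numeric(0),
                                end_um = numeric(0), grade = numeric(0)),
      borders = .borders_to_table(gen_surface(cfg$curvature, 0L)$borders),
      truth = data.frame(experiment_id = character(0), mu_dv = numeric(0),
                         mu_tr = numeric(0)),
      animals = list(), border_polylines = NULL, spec = NULL,
      params = cfg$params, config = cfg, seed = seed),
      class = "synthetic_study")
  }
  if (n == 0L) return(empty_study())
  ages <- if (is.null(cfg$ages)) sample(1:19, n, replace = TRUE) else
    rep_len(cfg$ages, n)
  animals <- gen_animals(n, ages, spacing_um = cfg$spacing_um,
                         noise_sdlog = cfg$noise_sdlog,
                         subdivisions = cfg$subdivisions)
  surf <- gen_surface(cfg$curvature, n_sites = n, length_mm = cfg$length_mm,
                      width_mm = cfg$width_mm, n_points = cfg$n_points,
                      offset_mm = cfg$offset_mm)
  meas <- do.call(rbind, lapply(animals, function(a) {
    data.frame(animal_id = a$animal_id, age_days = a$age_days,
               a$sections, series_spacing_um = a$spacing_um,
               stringsAsFactors = FALSE)
  }))
  rownames(meas) <- NULL
  spec <- average_flatmap(animals)
  inj <- data.frame(experiment_id = sprintf("E%03d", seq_len(n)),
                    animal_id = names(animals),
                    age_days = ages,
                    x = surf$sites$x, y = surf$sites$y, z = surf$sites$z,
                    rc_true = surf$sites$rc_true,
                    dv_true = surf$sites$dv_true,
                    stringsAsFactors = FALSE)
  obs_list <- vector("list", n)
  truth <- data.frame(experiment_id = inj$experiment_id,
                      mu_dv = NA_real_, mu_tr = NA_real_)
  for (k in seq_len(n)) {
    pr <- gen_projection(inj$experiment_id[k], inj$rc_true[k],
                         inj$dv_true[k], ages[k], animals[[k]],
                         params = cfg$params,
                         subdivisions = cfg$subdivisions)
    obs_list[[k]] <- pr$obs
    truth$mu_dv[k] <- pr$truth[["mu_dv"]]
    truth$mu_tr[k] <- pr$truth[["mu_tr"]]
  }
  obs <- do.call(rbind, obs_list)
  rownames(obs) <- NULL
  structure(list(measurements = meas, injections = inj, observations = obs,
                 borders = .borders_to_table(surf$borders), truth = truth,
                 animals = animals, border_polylines = surf$borders,
                 spec = spec, params = cfg$params, config = cfg,
                 seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> seed=%d: %d experiments, %d observation rows, smax=%s\n",
    x$seed, nrow(x$injections), nrow(x$observations),
    if (is.null(x$spec)) "NA" else x$spec$smax))
  invisible(x)
}

.borders_to_table <- function(borders) {
  do.call(rbind, lapply(names(borders), function(role) {
    b <- borders[[role]]
    data.frame(role = role, point_index = seq_len(nrow(b)),
               x = b[, 1], y = b[, 2], z = b[, 3],
               stringsAsFactors = FALSE)
  }))
}
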