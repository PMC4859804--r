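## All tables are UTF-8, tab-delimited, one header row, decimal point.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.check_cols <- function(d, need, numeric_cols, path) {
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cl in numeric_cols) {
    v <- suppressWarnings(as.numeric(d[[cl]]))
    bad <- which(is.na(v) & !is.na(d[[cl]]) & d[[cl]] != "NA" &
                 d[[cl]] != "")
    if (length(bad))
      stop(sprintf("%s:%d: non-numeric value '%s' in column %s", path,
                   bad[1] + 1L, d[[cl]][bad[1]], cl), call. = FALSE)
    d[[cl]] <- v
  }
  d
}

#' Read a per-section measurement table
#'
#' Expects tab-delimited columns `animal_id`, `age_days`, `section_index`,
#' `subdivision`, `transverse_um`, `series_spacing_um`. Errors cite the
#' offending file and line.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_measurements <- function(path) {
  d <- .read_tsv(path)
  d <- .check_cols(d, c("animal_id", "age_days", "section_index",
                        "subdivision", "transverse_um", "series_spacing_um"),
                   c("age_days", "section_index", "transverse_um",
                     "series_spacing_um"), path)
  dup <- which(duplicated(d[, c("animal_id", "section_index", "subdivision")]))
  if (length(dup))
    stop(sprintf("%s:%d: duplicate (animal, section, subdivision) row",
                 path, dup[1] + 1L), call. = FALSE)
  d
}

#' Read a labeling observation table
#'
#' Expects columns `experiment_id`, `animal_id`, `section_index`,
#' `subdivision`, `kind` (`plexus`/`fiber`), `start_um`, `end_um`, `grade`.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_observations <- function(path) {
  d <- .read_tsv(path)
  d <- .check_cols(d, c("experiment_id", "animal_id", "section_index",
                        "subdivision", "kind", "start_um", "end_um", "grade"),
                   c("section_index", "start_um", "end_um", "grade"), path)
  bad <- which(!d$kind %in% c("plexus", "fiber"))
  if (length(bad))
    stop(sprintf("%s:%d: kind must be 'plexus' or 'fiber'", path,
                 bad[1] + 1L), call. = FALSE)
  d
}

#' Read border polylines from a coordinate table
#'
#' Expects columns `role`, `point_index`, `x`, `y`, `z` (mm), points ordered
#' rostral to caudal within each role.
#'
#' @param path file path.
#' @return named list of [border_polyline()]s keyed by role.
#' @export
read_borders <- function(path) {
  d <- .read_tsv(path)
  d <- .check_cols(d, c("role", "point_index", "x", "y", "z"),
                   c("point_index", "x", "y", "z"), path)
  out <- list()
  for (role in unique(d$role)) {
    b <- d[d$role == role, ]
    b <- b[order(b$point_index), ]
    out[[role]] <- border_polyline(b[, c("x", "y", "z")], role = role)
  }
  out
}

#' Read an injection-site table
#'
#' Expects columns `experiment_id`, `animal_id`, `age_days`, `x`, `y`, `z`.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_injections <- function(path) {
  d <- .read_tsv(path)
  .check_cols(d, c("experiment_id", "animal_id", "age_days", "x", "y", "z"),
              c("age_days", "x", "y", "z"), path)
}

#' Write a flatmap specification as JSON
#'
#' @param spec a [average_flatmap()] specification.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flatmap_spec <- function(spec, path) {
  stopifnot(inherits(spec, "flatmap_spec"))
  jsonlite::write_json(
    list(smax = spec$smax,
         subdivisions = lapply(spec$subdivisions, function(m)
           list(t_bar = m$t_bar, dv_bar = m$dv_bar, T = m$T,
                n_bins = m$n_bins, n_animals = m$n_animals))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a flatmap specification from JSON
#'
#' @param path path written by [write_flatmap_spec()].
#' @return a `flatmap_spec`.
#' @export
read_flatmap_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  subs <- lapply(j$subdivisions, function(m)
    list(t_bar = as.numeric(m$t_bar), dv_bar = as.numeric(m$dv_bar),
         T = as.numeric(m$T), n_bins = as.integer(m$n_bins),
         n_animals = as.integer(m$n_animals)))
  structure(list(smax = as.integer(j$smax), subdivisions = subs),
            class = "flatmap_spec")
}

#' Write a label map in long delimited form
#'
#' One row per bin (`subdivision`, `row`, `bin`, `value`) plus a JSON
#' sidecar (`<path>.json`) recording the experiment id, normalization state
#' and the flatmap geometry so the map is self-describing.
#'
#' @param map an `experiment_label_map`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(map, path) {
  rows <- list()
  for (sub in names(map$values)) {
    for (i in seq_along(map$values[[sub]])) {
      v <- map$values[[sub]][[i]]
      if (!length(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subdivision = sub, row = i, bin = seq_along(v), value = v,
        stringsAsFactors = FALSE)
    }
  }
  .write_tsv(do.call(rbind, rows), path)
  jsonlite::write_json(
    list(experiment_id = map$experiment_id, normalized = map$normalized,
         empty = map$empty, smax = map$spec$smax,
         n_bins = lapply(map$spec$subdivisions, `[[`, "n_bins")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic study's tables to a directory
#'
#' Emits `measurements.tsv`, `injections.tsv`, `observations.tsv`,
#' `borders.tsv` and `truth.tsv` in the formats the pipeline readers expect.
#' Re-writing the same study yields byte-identical files.
#'
#' @param study a [gen_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(study$measurements, file.path(dir, "measurements.tsv"))
  .write_tsv(study$injections, file.path(dir, "injections.tsv"))
  .write_tsv(study$observations, file.path(dir, "observations.tsv"))
  .write_tsv(study$borders, file.path(dir, "borders.tsv"))
  .write_tsv(study$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a study directory back into pipeline inputs
#'
#' @param dir directory written by [write_study()].
#' @return list with `measurements`, `injections`, `observations`,
#'   `borders` (polyline list) and, if present, `truth`.
#' @export
read_study <- function(dir) {
  out <- list(measurements = read_measurements(file.path(dir, "measurements.tsv")),
              injections = read_injections(file.path(dir, "injections.tsv")),
              observations = read_observations(file.path(dir, "observations.tsv")),
              borders = read_borders(file.path(dir, "borders.tsv")))
  tf <- file.path(dir, "truth.tsv")
  if (file.exists(tf)) out$truth <- .read_tsv(tf)
  out
}

#' Assign injections to analysis subgroups
#'
#' Labels each normalized injection with its rostrocaudal quarter
#' (`floor(rc * 4)` clipped to the caudal quarter at rc = 1), rostral/caudal
#' half, age group (P1-6, P7-13, P14+) and the area-by-quarter group used
#' when pooling flatmaps.
#'
#' @param injections data.frame with columns `rc` and `age_days`; an `area`
#'   column is used for the combined group label when present.
#' @return the data.frame with columns `rc_quarter` (1 rostral .. 4 caudal),
#'   `rc_half`, `age_group` and `group` added.
#' @export
assign_subgroups <- function(injections) {
  rc <- injections$rc
  if (any(rc < 0 | rc > 1))
    stop("rc outside [0, 1]", call. = FALSE)
  q <- pmin(floor(rc * 4), 3) + 1L
  injections$rc_quarter <- as.integer(q)
  injections$rc_half <- ifelse(rc < 0.5, "rostral", "caudal")
  injections$age_group <- cut(injections$age_days, c(-Inf, 6.5, 13.5, Inf),
                              labels = c("P1-6", "P7-13", "P14+"))
  area <- if ("area" %in% names(injections)) injections$area else "all"
  injections$group <- paste(area, injections$rc_quarter, sep = "_Q")
  injections
}

## short stable hash of the configuration for provenance blocks
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full quantification pipeline
#'
#' Orchestrates the stages in order: flatten the injections onto the source
#' surface, build the average flatmap from the measurements, map the labeling
#' observations onto it, normalize, compute the center-of-mass table, and fit
#' the six topography regressions (three assembled fields x dorsoventral and
#' transverse coordinates). Experiments without labeled axons and animals
#' older than `age_max` are excluded (and counted in the log); a failing
#' stage aborts with the stage name.
#'
#' @param inputs either a [gen_study()] object or a list with
#'   `measurements`, `injections`, `observations` data.frames and `borders`
#'   (named [border_polyline()] list), e.g. from [read_study()].
#' @param alpha significance criterion for interaction retention.
#' @param age_max oldest age (days) entering the regressions.
#' @param span border-smoothing span (`NULL` to skip smoothing).
#' @param smax flatmap row count, or `"auto"`.
#' @return list with `injections` (normalized coordinates), `spec`, `maps`
#'   (normalized label maps), `com` (center-of-mass table joined with
#'   injection coordinates), `regressions` and `diagnostics` (named by
#'   `field.axis`), `log` (character), and `config_hash`.
#' @export
run_pipeline <- function(inputs, alpha = 0.05, age_max = 19, span = 0.5,
                         smax = "auto") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }
  if (inherits(inputs, "synthetic_study"))
    inputs <- list(measurements = inputs$measurements,
                   injections = inputs$injections,
                   observations = inputs$observations,
                   borders = inputs$border_polylines)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  inj <- stage("flatten_injections",
               flatten_injections(inputs$borders, inputs$injections,
                                  span = span))
  say("flatten_injections: %d injections normalized", nrow(inj))
  spec <- stage("flatmap_build",
                average_flatmap(inputs$measurements, smax = smax))
  say("flatmap_build: smax=%d, %d subdivisions", spec$smax,
      length(spec$subdivisions))
  maps <- stage("label_map",
                map_observations(inputs$observations, spec,
                                 inputs$measurements))
  ## experiments with no observation rows at all are empty maps
  missing <- setdiff(inj$experiment_id, names(maps))
  for (eid in missing) maps[[eid]] <- empty_label_map(spec, eid)
  n_empty <- sum(vapply(maps, `[[`, logical(1), "empty"))
  say("label_map: %d experiments mapped, %d without labeled axons (excluded)",
      length(maps), n_empty)
  maps <- lapply(maps, normalize_map)
  com <- stage("center_of_mass", com_table(maps))
  com <- merge(com, inj[, c("experiment_id", "rc", "dv", "age_days",
                            if ("area" %in% names(inj)) "area")],
               by = "experiment_id", sort = TRUE)
  names(com)[names(com) == "age_days"] <- "age"
  say("center_of_mass: %d rows; %d excluded as older than P%g",
      nrow(com), sum(com$age > age_max), age_max)
  regressions <- list(); diagnostics <- list()
  for (f in names(COM_FIELDS)) for (axis in c("dv_com", "tr_com")) {
    d <- com[com$field == f, ]
    key <- paste0(f, ".", axis)
    fit <- stage(paste0("regression ", key),
                 fit_topography(d, axis, alpha = alpha, age_max = age_max))
    regressions[[key]] <- fit
    diagnostics[[key]] <- regression_diagnostics(fit)
    say("regression %s: n=%d, terms: %s", key, fit$n,
        paste(fit$terms, collapse = " + "))
  }
  list(injections = inj, spec = spec, maps = maps, com = com,
       regressions = regressions, diagnostics = diagnostics, log = log,
       config_hash = .config_hash(list(alpha = alpha, age_max = age_max,
                                       span = span, smax = smax)))
}
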