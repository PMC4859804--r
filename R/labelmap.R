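## Reference border from which transverse positions are measured, per
## subdivision: axon distances are taken from the proximal border of PrS, the
## distal border of PaS, and the medial border of MEC/LEC. Distal-referenced
## measurements are flipped onto the common proximal/medial -> distal/lateral
## axis before binning.
REFERENCE_BORDER <- c(PrS_sup = "proximal", PrS_deep = "proximal",
                      PaS_deep = "distal", MEC_deep = "medial",
                      LEC_deep = "medial")

is_distal_referenced <- function(subdivision) {
  ref <- REFERENCE_BORDER[subdivision]
  !is.na(ref) & ref == "distal"
}

## fields assembled along the transverse axis for center-of-mass analysis
COM_FIELDS <- list(PrS_LI_III = "PrS_sup",
                   PrS_PaS_deep = c("PrS_deep", "PaS_deep"),
                   EC_deep = c("MEC_deep", "LEC_deep"))

#' Empty label map on a flatmap specification
#'
#' An experiment's label map is a ragged grid: one numeric vector of bin
#' values per dorsoventral row of each subdivision, rows ordered dorsal
#' (row 1) to ventral (row smax), bins ordered proximal/medial to
#' distal/lateral.
#'
#' @param spec a [average_flatmap()] specification.
#' @param experiment_id scalar id.
#' @return an `experiment_label_map` with all bins 0.
#' @export
empty_label_map <- function(spec, experiment_id = NA_character_) {
  stopifnot(inherits(spec, "flatmap_spec"))
  values <- lapply(spec$subdivisions, function(m)
    lapply(m$n_bins, function(nb) numeric(nb)))
  structure(list(experiment_id = experiment_id, spec = spec,
                 values = values, normalized = FALSE, empty = TRUE),
            class = "experiment_label_map")
}

#' @export
print.experiment_label_map <- function(x, ...) {
  tot <- sum(unlist(x$values))
  cat(sprintf("<experiment_label_map> %s: %s, total mass %.3f%s\n",
              x$experiment_id,
              if (x$normalized) "normalized" else "raw", tot,
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

.check_same_spec <- function(maps) {
  ref <- maps[[1]]$spec
  same <- vapply(maps, function(m) isTRUE(all.equal(m$spec, ref)), logical(1))
  if (!all(same))
    stop("maps were built on different flatmap specifications", call. = FALSE)
  ref
}

#' Bin values for one dense-plexus interval
#'
#' The plexus boundary interval, already normalized by the section's
#' transverse extent and oriented on the common axis (0 = proximal/medial),
#' marks every bin whose center falls in `[start, end)` with the density
#' grade (1 = weak to 3 = densest).
#'
#' @param n_bins bins in the target row.
#' @param start,end normalized interval in `[0, 1]`, `start < end`.
#' @param grade integer density grade in 1..3.
#' @return numeric vector of length `n_bins`.
#' @export
map_plexus <- function(n_bins, start, end, grade) {
  if (!(grade %in% 1:3))
    stop("plexus density grade must be 1, 2 or 3", call. = FALSE)
  if (!(start >= 0 && start < end && end <= 1 + 1e-9))
    stop("plexus interval must satisfy 0 <= start < end <= 1", call. = FALSE)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  as.numeric(centers >= start & centers < end) * grade
}

#' Bin counts for single-fiber positions
#'
#' Each labeled axon's normalized transverse position is assigned to the bin
#' containing it (half-open bins, the last bin closed on the right) and bins
#' take the fiber count.
#'
#' @param n_bins bins in the target row.
#' @param positions normalized positions in `[0, 1]`.
#' @return numeric vector of counts, summing to `length(positions)`.
#' @export
map_fibers <- function(n_bins, positions) {
  if (any(positions < 0 | positions > 1))
    stop("fiber position outside [0, section extent]", call. = FALSE)
  idx <- pmin(floor(positions * n_bins) + 1L, n_bins)
  tabulate(idx, nbins = n_bins)
}

#' Map a table of labeling observations onto the flatmap
#'
#' Converts per-section plexus intervals and single-fiber positions (µm from
#' each subdivision's reference border) into per-experiment label maps.
#' Positions are normalized by the section's measured transverse extent,
#' distal-referenced subdivisions (PaS) are flipped to the common axis, each
#' section is assigned to the flatmap row containing its center, overlapping
#' plexus grades take the maximum, and fiber counts accumulate.
#'
#' @param obs data.frame with columns `experiment_id`, `animal_id`,
#'   `section_index`, `subdivision`, `kind` (`"plexus"` or `"fiber"`),
#'   `start_um` (fiber position for kind `"fiber"`), `end_um` (NA for
#'   fibers), `grade` (NA for fibers).
#' @param spec a [average_flatmap()] specification.
#' @param measurements the per-section measurement table (same schema as
#'   [as_animal_records()]), used for section extents and section counts.
#' @return named list of `experiment_label_map`s, one per experiment.
#' @export
map_observations <- function(obs, spec, measurements) {
  need <- c("experiment_id", "animal_id", "section_index", "subdivision",
            "kind", "start_um", "end_um", "grade")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observation table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_sec <- tapply(measurements$section_index, measurements$animal_id,
                  function(x) length(unique(x)))
  ext_key <- paste(measurements$animal_id, measurements$section_index,
                   measurements$subdivision)
  extents <- stats::setNames(measurements$transverse_um, ext_key)
  if (!all(obs$subdivision %in% names(spec$subdivisions))) {
    bad <- setdiff(unique(obs$subdivision), names(spec$subdivisions))
    stop("unknown subdivision(s) in observations: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(obs$kind %in% c("plexus", "fiber")))
    stop("observation kind must be 'plexus' or 'fiber'", call. = FALSE)
  ext <- unname(extents[match(paste(obs$animal_id, obs$section_index,
                                    obs$subdivision), names(extents))])
  if (anyNA(ext) || any(ext <= 0)) {
    r <- which(is.na(ext) | ext <= 0)[1]
    stop("no positive transverse extent for animal ", obs$animal_id[r],
         " section ", obs$section_index[r], " ", obs$subdivision[r],
         call. = FALSE)
  }
  row_of <- row_for_section(obs$section_index,
                            as.numeric(n_sec[as.character(obs$animal_id)]),
                            spec$smax)
  eid_v <- as.character(obs$experiment_id); sub_v <- obs$subdivision
  kind_v <- obs$kind; start_v <- obs$start_um; end_v <- obs$end_um
  grade_v <- obs$grade
  out <- list()
  for (eid in unique(eid_v)) {
    idx <- which(eid_v == eid)
    m <- empty_label_map(spec, experiment_id = eid)
    for (r in idx) {
      sub <- sub_v[r]
      row <- row_of[r]
      nb <- spec$subdivisions[[sub]]$n_bins[row]
      if (nb < 1L) next
      if (kind_v[r] == "plexus") {
        a <- start_v[r] / ext[r]; b <- end_v[r] / ext[r]
        if (is_distal_referenced(sub)) { tmp <- a; a <- 1 - b; b <- 1 - tmp }
        v <- map_plexus(nb, a, b, grade_v[r])
        m$values[[sub]][[row]] <- pmax(m$values[[sub]][[row]], v)
      } else {
        x <- start_v[r] / ext[r]
        if (is_distal_referenced(sub)) x <- 1 - x
        m$values[[sub]][[row]] <- m$values[[sub]][[row]] + map_fibers(nb, x)
      }
    }
    m$empty <- sum(unlist(m$values)) == 0
    out[[eid]] <- m
  }
  out
}

## resample one row's bin values onto a different bin count by linear
## interpolation of values at bin centers against normalized position
.resample_row <- function(values, n_out) {
  n_in <- length(values)
  if (n_out == 0L) return(numeric(0))
  if (n_in == 0L) return(numeric(n_out))
  if (n_in == 1L) return(rep(values, n_out))
  stats::approx((seq_len(n_in) - 0.5) / n_in, values,
                xout = (seq_len(n_out) - 0.5) / n_out, rule = 2)$y
}

#' Fill rows lost to missing or damaged sections
#'
#' A missing row's projection pattern is estimated as the average of the
#' patterns in the sections directly above and below: neighbor rows are
#' matched bin-to-bin by normalized transverse position (the grid is ragged)
#' and averaged; a missing edge row copies its single neighbor.
#'
#' @param map an `experiment_label_map`.
#' @param missing_rows integer row indices that were not observed.
#' @param subdivisions which subdivisions to fill (default all).
#' @return the map with missing rows filled.
#' @export
interpolate_missing <- function(map, missing_rows,
                                subdivisions = names(map$values)) {
  smax <- map$spec$smax
  missing_rows <- sort(unique(as.integer(missing_rows)))
  if (length(missing_rows) == length(seq_len(smax)))
    stop("all rows missing: nothing to interpolate from", call. = FALSE)
  for (sub in subdivisions) {
    nb <- map$spec$subdivisions[[sub]]$n_bins
    for (i in missing_rows) {
      above <- rev(setdiff(seq_len(i - 1L), missing_rows))
      below <- setdiff(seq(i + 1L, length.out = max(0L, smax - i)),
                       missing_rows)
      ia <- if (length(above)) above[1] else NA_integer_
      ib <- if (length(below)) below[1] else NA_integer_
      if (is.na(ia) && is.na(ib))
        stop("isolated block of missing rows has no observed neighbor",
             call. = FALSE)
      vals <- list()
      if (!is.na(ia))
        vals <- c(vals, list(.resample_row(map$values[[sub]][[ia]], nb[i])))
      if (!is.na(ib))
        vals <- c(vals, list(.resample_row(map$values[[sub]][[ib]], nb[i])))
      map$values[[sub]][[i]] <- Reduce(`+`, vals) / length(vals)
    }
  }
  map$empty <- sum(unlist(map$values)) == 0
  map
}

#' Normalize a label map to its maximum-valued bin
#'
#' Dense-plexus grades and single-fiber counts live on different scales; to
#' compare or pool experiments each map is divided by its highest bin value,
#' giving bins in `[0, 1]` with 1 at the densest labeling. A map with no
#' labeling anywhere is flagged empty and left all-zero.
#'
#' @param map an `experiment_label_map`.
#' @return the normalized map (idempotent).
#' @export
normalize_map <- function(map) {
  mx <- max(c(0, unlist(map$values)))
  if (mx == 0) {
    map$empty <- TRUE
  } else {
    map$values <- lapply(map$values, function(rows)
      lapply(rows, function(v) v / mx))
    map$empty <- FALSE
  }
  map$normalized <- TRUE
  map
}

#' Pool normalized label maps across experiments
#'
#' Bins representing the same location are summed across maps and the summed
#' map is renormalized to its highest bin. With `subgroups`, maps are pooled
#' and normalized within each subgroup first and the normalized subgroup maps
#' are then summed and renormalized, so each subgroup has similar impact
#' regardless of its size.
#'
#' @param maps list of normalized `experiment_label_map`s on one spec.
#' @param subgroups optional vector of subgroup labels, one per map.
#' @return a pooled, normalized `experiment_label_map`.
#' @export
pool_maps <- function(maps, subgroups = NULL) {
  stopifnot(length(maps) >= 1L)
  spec <- .check_same_spec(maps)
  if (!is.null(subgroups)) {
    stopifnot(length(subgroups) == length(maps))
    groups <- split(maps, subgroups)
    pooled <- lapply(groups, pool_maps)
    return(pool_maps(unname(pooled)))
  }
  acc <- empty_label_map(spec, experiment_id = "pooled")
  for (m in maps) {
    for (sub in names(acc$values))
      acc$values[[sub]] <- Map(`+`, acc$values[[sub]], m$values[[sub]])
  }
  normalize_map(acc)
}

#' Center of mass of labeling in an assembled field
#'
#' Subdivisions are assembled along the transverse axis per field
#' (`PrS_LI_III` = superficial PrS alone; `PrS_PaS_deep` = deep PrS then deep
#' PaS, proximal to distal; `EC_deep` = deep MEC then deep LEC, medial to
#' lateral). The dorsoventral coordinate of the center of mass is the
#' mass-weighted mean of row centers on a 0 (ventral) to 1 (dorsal) scale;
#' the transverse coordinate is the mass-weighted mean of bin centers
#' normalized by each row's assembled width, 0 (proximal/medial) to 1
#' (distal/lateral).
#'
#' @param map an `experiment_label_map`.
#' @param field one of `"PrS_LI_III"`, `"PrS_PaS_deep"`, `"EC_deep"`.
#' @return list with `experiment_id`, `field`, `dv_com`, `tr_com` and `mass`;
#'   `dv_com`/`tr_com` are `NA` when the field holds no labeling (such
#'   experiments are excluded from regression).
#' @export
center_of_mass <- function(map, field = names(COM_FIELDS)) {
  field <- match.arg(field)
  subs <- COM_FIELDS[[field]]
  subs <- intersect(subs, names(map$values))
  smax <- map$spec$smax
  w_sum <- 0; dv_acc <- 0; tr_acc <- 0
  for (i in seq_len(smax)) {
    row <- unlist(lapply(subs, function(s) map$values[[s]][[i]]))
    width <- length(row)
    if (width == 0L || sum(row) == 0) next
    x_centers <- (seq_len(width) - 0.5) / width
    dv_center <- 1 - (i - 0.5) / smax
    w_sum <- w_sum + sum(row)
    dv_acc <- dv_acc + sum(row) * dv_center
    tr_acc <- tr_acc + sum(row * x_centers)
  }
  if (w_sum == 0)
    return(list(experiment_id = map$experiment_id, field = field,
                dv_com = NA_real_, tr_com = NA_real_, mass = 0))
  list(experiment_id = map$experiment_id, field = field,
       dv_com = dv_acc / w_sum, tr_com = tr_acc / w_sum, mass = w_sum)
}

#' Center-of-mass table for a set of experiments
#'
#' @param maps list of `experiment_label_map`s.
#' @param fields which assembled fields to summarize.
#' @return data.frame with one row per experiment x field: `experiment_id`,
#'   `field`, `dv_com`, `tr_com`, `mass`.
#' @export
com_table <- function(maps, fields = names(COM_FIELDS)) {
  rows <- list()
  for (m in maps) for (f in fields) {
    cm <- center_of_mass(m, f)
    rows[[length(rows) + 1L]] <- data.frame(
      experiment_id = cm$experiment_id, field = f,
      dv_com = cm$dv_com, tr_com = cm$tr_com, mass = cm$mass,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Linear color-scale positions clipped at two standard deviations
#'
#' Scatter-plot color scales run linearly between the mean minus and plus two
#' standard deviations of the plotted values; more extreme values are
#' thresholded to the scale's ends.
#'
#' @param values numeric vector (>= 2 values).
#' @return positions in `[0, 1]`; all 0.5 when the values have zero spread.
#' @export
color_scale <- function(values) {
  stopifnot(length(values) >= 2L)
  mu <- mean(values); sd <- stats::sd(values)
  if (sd == 0) return(rep(0.5, length(values)))
  pmin(pmax((values - (mu - 2 * sd)) / (4 * sd), 0), 1)
}
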