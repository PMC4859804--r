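## Subdivisions of the parahippocampal target region that receive the traced
## projections; the within-section (transverse) extent of each is measured per
## histological section.
PHR_SUBDIVISIONS <- c("PrS_sup", "PrS_deep", "PaS_deep", "MEC_deep", "LEC_deep")

## round "to the nearest integer" with .5 away from zero (half-up), the
## convention used when converting transverse extents into bin counts
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' One animal's per-section measurement record
#'
#' @param animal_id scalar id.
#' @param age_days postnatal age in days.
#' @param sections data.frame with columns `section_index` (ordered dorsal to
#'   ventral), `subdivision` and `transverse_um` (>= 0).
#' @param spacing_um distance between consecutive sections of the series (µm);
#'   the default dorsoventral extent is `n_sections * spacing_um`.
#' @param dv_um optional direct measurement of the dorsoventral extent (µm),
#'   overriding the section-count estimate.
#' @return an `animal_record` object.
#' @export
animal_record <- function(animal_id, age_days, sections, spacing_um,
                          dv_um = NULL) {
  stopifnot(all(c("section_index", "subdivision", "transverse_um") %in%
                names(sections)))
  if (any(sections$transverse_um < 0))
    stop("transverse extents must be >= 0", call. = FALSE)
  dup <- duplicated(sections[, c("section_index", "subdivision")])
  if (any(dup))
    stop("duplicate (section_index, subdivision) in animal ", animal_id,
         call. = FALSE)
  n_sec <- length(unique(sections$section_index))
  dv <- if (is.null(dv_um)) n_sec * spacing_um else dv_um
  if (dv <= 0) stop("dorsoventral extent must be positive", call. = FALSE)
  structure(list(animal_id = animal_id, age_days = age_days,
                 sections = sections[order(sections$subdivision,
                                           sections$section_index), ],
                 spacing_um = spacing_um, dv_um = dv, n_sections = n_sec),
            class = "animal_record")
}

#' @export
print.animal_record <- function(x, ...) {
  cat(sprintf("<animal_record> %s, P%g, %d sections, dv extent %g um\n",
              x$animal_id, x$age_days, x$n_sections, x$dv_um))
  invisible(x)
}

#' Split a measurement table into animal records
#'
#' @param meas data.frame with columns `animal_id`, `age_days`,
#'   `section_index`, `subdivision`, `transverse_um`, `series_spacing_um`.
#' @return named list of [animal_record()]s.
#' @export
as_animal_records <- function(meas) {
  need <- c("animal_id", "age_days", "section_index", "subdivision",
            "transverse_um", "series_spacing_um")
  miss <- setdiff(need, names(meas))
  if (length(miss))
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lst <- split(meas, meas$animal_id)
  recs <- lapply(lst, function(d) {
    animal_record(d$animal_id[1], d$age_days[1],
                  d[, c("section_index", "subdivision", "transverse_um")],
                  spacing_um = d$series_spacing_um[1])
  })
  recs[order(names(recs))]
}

#' Size-normalize one animal's measurements
#'
#' Brains of different ages have different sizes, so absolute measurements are
#' converted to normalized values: within each subdivision, every transverse
#' extent is divided by that animal's maximum measured extent of the same
#' subdivision, and the animal's dorsoventral extent is expressed as the ratio
#' of its absolute dorsoventral extent to the same maximum. A subdivision
#' whose extents are all zero carries no shape information and is dropped with
#' a warning.
#'
#' @param rec an [animal_record()].
#' @return list per subdivision: `s_norm` (normalized extents in section
#'   order, in `[0, 1]` with max 1), `dv_norm` (normalized dorsoventral
#'   extent), `n_sections`, plus `age_days` and `animal_id` attributes.
#' @export
normalize_animal <- function(rec) {
  stopifnot(inherits(rec, "animal_record"))
  out <- list()
  for (sub in unique(rec$sections$subdivision)) {
    d <- rec$sections[rec$sections$subdivision == sub, ]
    mx <- max(d$transverse_um)
    if (mx == 0) {
      warning("animal ", rec$animal_id, ": subdivision ", sub,
              " has all-zero extents; excluded", call. = FALSE)
      next
    }
    out[[sub]] <- list(s_norm = d$transverse_um[order(d$section_index)] / mx,
                       dv_norm = rec$dv_um / mx,
                       n_sections = nrow(d))
  }
  attr(out, "animal_id") <- rec$animal_id
  attr(out, "age_days") <- rec$age_days
  out
}

#' Resample a normalized section profile onto flatmap rows
#'
#' Maps an animal's ordered per-section profile (section centers at
#' `(j - 0.5) / n` of the animal's own dorsoventral extent) onto `smax` equal
#' rows by linear interpolation of normalized transverse extent against
#' normalized dorsoventral position, evaluated at row centers
#' `(i - 0.5) / smax`. Row centers beyond the outermost section centers take
#' the nearest section's value (the animal's sections tile its full extent).
#'
#' @param s_norm numeric vector of normalized extents, dorsal to ventral.
#' @param smax number of flatmap rows.
#' @return numeric vector `t_i` of length `smax`.
#' @export
resample_to_rows <- function(s_norm, smax) {
  n <- length(s_norm)
  stopifnot(n >= 1L, smax >= 1L)
  centers_out <- (seq_len(smax) - 0.5) / smax
  if (n == 1L) return(rep(s_norm, smax))
  centers_in <- (seq_len(n) - 0.5) / n
  stats::approx(centers_in, s_norm, xout = centers_out, rule = 2)$y
}

#' Build the age-normalized average flatmap
#'
#' Combines normalized animal records into one average flatmap per
#' subdivision: the dorsoventral axis is binned into `smax` rows (by default
#' the maximum number of sections containing the region in any single
#' series), each animal's profile is resampled onto those rows, row means are
#' taken across animals (`t_bar`), the mean normalized dorsoventral extent
#' across animals is computed (`dv_bar`), each row's relative transverse
#' extent is `T = t_bar / dv_bar`, and the bin count per row is
#' `round(T * smax)` (half-up), yielding rows of square bins.
#'
#' @param records list of [animal_record()]s (or a measurement data.frame,
#'   which is split with [as_animal_records()]).
#' @param smax `"auto"` or an integer number of dorsoventral rows.
#' @return a `flatmap_spec`: list with `smax` and, per subdivision, `t_bar`,
#'   `dv_bar`, `T`, `n_bins` (integer bins per row, dorsal row first) and
#'   `n_animals`.
#' @export
average_flatmap <- function(records, smax = "auto") {
  if (is.data.frame(records)) records <- as_animal_records(records)
  norm <- lapply(records, normalize_animal)
  if (identical(smax, "auto")) {
    smax <- max(vapply(records, function(r) r$n_sections, numeric(1)))
  }
  smax <- as.integer(smax)
  stopifnot(smax >= 1L)
  subs <- unique(unlist(lapply(norm, names)))
  maps <- list()
  for (sub in subs) {
    have <- Filter(function(x) !is.null(x[[sub]]), norm)
    t_mat <- vapply(have, function(x) resample_to_rows(x[[sub]]$s_norm, smax),
                    numeric(smax))
    t_mat <- matrix(t_mat, nrow = smax)
    t_bar <- rowMeans(t_mat)
    dv_bar <- mean(vapply(have, function(x) x[[sub]]$dv_norm, numeric(1)))
    if (dv_bar == 0)
      stop("mean normalized dorsoventral extent is zero for ", sub,
           call. = FALSE)
    T_i <- t_bar / dv_bar
    maps[[sub]] <- list(t_bar = t_bar, dv_bar = dv_bar, T = T_i,
                        n_bins = as.integer(round_half_up(T_i * smax)),
                        n_animals = length(have))
  }
  structure(list(smax = smax, subdivisions = maps), class = "flatmap_spec")
}

#' @export
print.flatmap_spec <- function(x, ...) {
  cat(sprintf("<flatmap_spec> smax=%d rows\n", x$smax))
  for (sub in names(x$subdivisions)) {
    m <- x$subdivisions[[sub]]
    cat(sprintf("  %-9s dv_bar=%.3f, bins/row %d-%d, %d animal(s)\n",
                sub, m$dv_bar, min(m$n_bins), max(m$n_bins), m$n_animals))
  }
  invisible(x)
}

#' Which flatmap row contains a section's center
#'
#' @param section_index 1-based section index (dorsal to ventral).
#' @param n_sections total sections in the animal's series.
#' @param smax number of flatmap rows.
#' @return integer row index in `1..smax`.
#' @export
row_for_section <- function(section_index, n_sections, smax) {
  i <- ceiling((section_index - 0.5) / n_sections * smax)
  pmin(pmax(as.integer(i), 1L), as.integer(smax))
}
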