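#' Triangulate the cortical strip between two border polylines
#'
#' The pial surface of the source area is modelled as the strip spanned by its
#' dorsal and ventral border polylines. Both borders are resampled to a common
#' vertex count at equal arc-length fractions and each quad of corresponding
#' vertices is split into two triangles. The midline — the line positioned
#' equally distant from the dorsal and ventral borders — is taken as the
#' pointwise midpoints of matched arc-length fractions; its cumulative arc
#' length carries the rostrocaudal coordinate.
#'
#' @param dorsal,ventral [border_polyline()]s ordered rostral to caudal.
#' @param n_u number of vertices after resampling (default: the larger of the
#'   two input vertex counts).
#' @param area label for the strip: `"A29"`, `"A30"` or `"combined"`.
#' @return A `surface_model`: list with triangle vertex matrices `A`, `B`, `C`
#'   (each n_tri x 3), the resampled `dorsal`/`ventral` borders, the `midline`
#'   matrix with its `midline_arclen`, per-triangle `areas` (mm^2) and the
#'   `area` label.
#' @export
triangulate_strip <- function(dorsal, ventral, n_u = NULL,
                              area = c("combined", "A29", "A30")) {
  area <- match.arg(area)
  n_u <- if (is.null(n_u)) max(nrow(dorsal), nrow(ventral)) else as.integer(n_u)
  D <- resample_polyline(dorsal, n_u)
  V <- resample_polyline(ventral, n_u)
  scale <- max(polyline_length(D), polyline_length(V))
  if (max(sqrt(rowSums((unclass(D) - unclass(V))^2))) < 1e-9 * max(scale, 1))
    stop("degenerate strip: dorsal and ventral borders coincide",
         call. = FALSE)
  ## quad (D_i, D_{i+1}, V_{i+1}, V_i) split into two triangles
  i0 <- seq_len(n_u - 1L)
  A <- rbind(unclass(D)[i0, , drop = FALSE], unclass(D)[i0, , drop = FALSE])
  B <- rbind(unclass(V)[i0, , drop = FALSE], unclass(V)[i0 + 1L, , drop = FALSE])
  C <- rbind(unclass(V)[i0 + 1L, , drop = FALSE], unclass(D)[i0 + 1L, , drop = FALSE])
  cr <- .cross3(B - A, C - A)
  areas <- 0.5 * sqrt(rowSums(cr^2))
  if (any(areas <= 1e-12 * max(scale, 1)^2))
    stop("degenerate triangle in strip (zero area)", call. = FALSE)
  ## crossing borders flip the orientation of adjacent triangle normals
  nrm <- cr / sqrt(rowSums(cr^2))
  ord <- order(rep(i0, 2L), rep(1:2, each = n_u - 1L))
  nrm <- nrm[ord, , drop = FALSE]
  if (nrow(nrm) > 1L &&
      any(rowSums(nrm[-1L, , drop = FALSE] *
                  nrm[-nrow(nrm), , drop = FALSE]) < 0))
    stop("geometry error: borders cross (triangle orientation flips)",
         call. = FALSE)
  mid <- (unclass(D) + unclass(V)) / 2
  seg <- sqrt(rowSums((mid[-1L, , drop = FALSE] -
                       mid[-nrow(mid), , drop = FALSE])^2))
  structure(list(A = A, B = B, C = C, areas = areas,
                 dorsal = D, ventral = V,
                 midline = mid, midline_arclen = c(0, cumsum(seg)),
                 area = area),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf(
    "<surface_model> area=%s, %d triangles, surface %.3f mm^2, midline %.3f mm\n",
    x$area, length(x$areas), sum(x$areas),
    x$midline_arclen[length(x$midline_arclen)]))
  invisible(x)
}

.cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

## closest point on each triangle (A, B, C row-wise) to point p
## (Ericson, Real-Time Collision Detection, vectorized over triangles)
.closest_on_triangles <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- sweep(-A, 2L, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-B, 2L, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-C, 2L, p, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  out <- A + ab * v + ac * w                     # face region default
  set <- function(out, mask, val) {
    out[mask, ] <- val[mask, , drop = FALSE]; out
  }
  ## edge BC
  t_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  m <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  m[is.na(m)] <- FALSE
  out <- set(out, m, B + (C - B) * t_bc)
  ## edge AC
  t_ac <- d2 / (d2 - d6)
  m <- vb <= 0 & d2 >= 0 & d6 <= 0
  m[is.na(m)] <- FALSE
  out <- set(out, m, A + ac * t_ac)
  ## edge AB
  t_ab <- d1 / (d1 - d3)
  m <- vc <= 0 & d1 >= 0 & d3 <= 0
  m[is.na(m)] <- FALSE
  out <- set(out, m, A + ab * t_ab)
  ## vertices last (highest priority)
  m <- d6 >= 0 & d5 <= d6; m[is.na(m)] <- FALSE
  out <- set(out, m, C)
  m <- d3 >= 0 & d4 <= d3; m[is.na(m)] <- FALSE
  out <- set(out, m, B)
  m <- d1 <= 0 & d2 <= 0; m[is.na(m)] <- FALSE
  out <- set(out, m, A)
  out
}

#' Transpose a 3D point onto the triangulated surface
#'
#' Finds the closest point on the triangulated pial surface to `p` — the foot
#' of the shortest vector between an injection site and the cortical surface.
#' Ties between triangles at exactly equal distance resolve to the lowest
#' triangle index.
#'
#' @param p numeric length-3 point (mm).
#' @param s a [triangulate_strip()] surface model.
#' @return list with `point` (closest surface point), `triangle` (index) and
#'   `dist` (mm).
#' @export
transpose_to_surface <- function(p, s) {
  p <- as.numeric(p)
  cand <- .closest_on_triangles(p, s$A, s$B, s$C)
  d2 <- rowSums(sweep(cand, 2L, p, "-")^2)
  i <- which.min(d2)
  list(point = cand[i, ], triangle = i, dist = sqrt(d2[i]))
}

#' Normalized flatmap coordinates of a transposed injection
#'
#' For a point on the surface, computes the minimum Euclidean distances to the
#' dorsal border (`d_d`) and ventral border (`d_v`), the dorsoventral
#' coordinate `dv = d_v / (d_v + d_d)` (0 = ventral, 1 = dorsal), and — via
#' the foot of the shortest vector to the midline — the cumulative arc
#' distances to the rostral (`d_r`) and caudal (`d_c`) ends, giving the
#' rostrocaudal coordinate `rc = d_r / (d_r + d_c)` (0 = rostral, 1 = caudal).
#'
#' @param tp numeric length-3 surface point.
#' @param s a [triangulate_strip()] surface model.
#' @return list with `rc`, `dv`, `d_d`, `d_v`, `d_r`, `d_c`.
#' @export
normalize_injection <- function(tp, s) {
  tp <- as.numeric(tp)
  d_d <- dist_to_border(tp, s$dorsal)
  d_v <- dist_to_border(tp, s$ventral)
  if (d_d + d_v == 0)
    stop("geometry error: point lies on both borders simultaneously",
         call. = FALSE)
  mid <- .point_to_polyline(tp, s$midline)
  d_r <- mid$arc
  d_c <- mid$total - mid$arc
  list(rc = d_r / (d_r + d_c), dv = d_v / (d_v + d_d),
       d_d = d_d, d_v = d_v, d_r = d_r, d_c = d_c)
}

#' Flatten injection sites onto normalized surface coordinates
#'
#' Runs the full injection-normalization chain: smooth the borders, build the
#' triangulated strip(s), transpose each 3D injection coordinate onto the
#' nearest surface point, and express it as normalized (rc, dv) coordinates.
#' When the three-border form is given (dorsal border of A30, A29/A30
#' boundary, ventral border of A29), two strips are built and each injection
#' is assigned to the area whose strip it is closest to; its coordinates are
#' then normalized within that area's own borders, while rc is measured along
#' the combined strip so it spans the full rostrocaudal extent of the source
#' region.
#'
#' @param borders named list of [border_polyline()]s: either
#'   `dorsal_of_area` + `ventral_of_area`, or `dorsal_A30` +
#'   `A29_A30_boundary` + `ventral_A29`.
#' @param injections data.frame with columns `experiment_id`, `animal_id`,
#'   `age_days`, `x`, `y`, `z` (mm).
#' @param span loess span passed to [smooth_borders()]; `NULL` skips smoothing.
#' @param n_u resampled vertex count per border for triangulation.
#' @return the injection data.frame augmented with columns `tx`, `ty`, `tz`
#'   (transposed point), `surf_dist`, `d_d`, `d_v`, `d_r`, `d_c`, `rc`, `dv`
#'   and `area`.
#' @export
flatten_injections <- function(borders, injections, span = 0.5, n_u = 50L) {
  sm <- function(b) if (is.null(span)) b else smooth_borders(b, span = span)
  two_area <- all(c("dorsal_A30", "A29_A30_boundary", "ventral_A29") %in%
                  names(borders))
  if (two_area) {
    d30 <- sm(borders$dorsal_A30)
    bnd <- sm(borders$A29_A30_boundary)
    v29 <- sm(borders$ventral_A29)
    surfs <- list(A30 = triangulate_strip(d30, bnd, n_u = n_u, area = "A30"),
                  A29 = triangulate_strip(bnd, v29, n_u = n_u, area = "A29"))
    comb <- triangulate_strip(d30, v29, n_u = n_u, area = "combined")
  } else if (all(c("dorsal_of_area", "ventral_of_area") %in% names(borders))) {
    surfs <- list(combined = triangulate_strip(
      sm(borders$dorsal_of_area), sm(borders$ventral_of_area),
      n_u = n_u, area = "combined"))
    comb <- surfs$combined
  } else {
    stop("borders must contain dorsal_of_area/ventral_of_area or ",
         "dorsal_A30/A29_A30_boundary/ventral_A29", call. = FALSE)
  }
  n <- nrow(injections)
  out <- injections
  cols <- c("tx", "ty", "tz", "surf_dist", "d_d", "d_v", "d_r", "d_c",
            "rc", "dv")
  for (cl in cols) out[[cl]] <- NA_real_
  out$area <- NA_character_
  for (k in seq_len(n)) {
    p <- as.numeric(injections[k, c("x", "y", "z")])
    tps <- lapply(surfs, transpose_to_surface, p = p)
    j <- which.min(vapply(tps, `[[`, numeric(1), "dist"))
    tp <- tps[[j]]
    s_area <- surfs[[j]]
    nc <- normalize_injection(tp$point, s_area)
    ## rc along the full source region, not the per-area strip
    rc <- normalize_injection(tp$point, comb)$rc
    out[k, c("tx", "ty", "tz")] <- tp$point
    out$surf_dist[k] <- tp$dist
    out$d_d[k] <- nc$d_d; out$d_v[k] <- nc$d_v
    out$d_r[k] <- nc$d_r; out$d_c[k] <- nc$d_c
    out$rc[k] <- rc
    out$dv[k] <- nc$dv
    out$area[k] <- if (two_area) names(surfs)[j] else s_area$area
  }
  out
}
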