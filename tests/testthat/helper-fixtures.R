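# shared in-code fixtures: tiny geometries, hand-sized flatmap specs and
# label maps used across the test files

# planar rectangular strip in the z = 0 plane: dorsal border at y = width,
# ventral at y = 0, running rostral (x = 0) to caudal (x = length)
planar_strip <- function(length = 10, width = 4, n = 11) {
  x <- seq(0, length, length.out = n)
  list(
    dorsal = border_polyline(cbind(x, width, 0), role = "dorsal_of_area"),
    ventral = border_polyline(cbind(x, 0, 0), role = "ventral_of_area"))
}

planar_surface <- function(length = 10, width = 4, n = 11, n_u = NULL) {
  b <- planar_strip(length, width, n)
  triangulate_strip(b$dorsal, b$ventral, n_u = n_u)
}

# minimal flatmap spec built directly: one subdivision, constant bins per row
make_spec <- function(smax, n_bins, subdivision = "PrS_sup") {
  nb <- rep_len(as.integer(n_bins), smax)
  subs <- list()
  subs[[subdivision]] <- list(t_bar = rep(1, smax), dv_bar = 1,
                              T = rep(1, smax), n_bins = nb, n_animals = 1L)
  structure(list(smax = as.integer(smax), subdivisions = subs),
            class = "flatmap_spec")
}

# spec with several subdivisions sharing one row structure
make_multi_spec <- function(smax, n_bins,
                            subdivisions = c("PrS_sup", "PrS_deep",
                                             "PaS_deep", "MEC_deep",
                                             "LEC_deep")) {
  subs <- lapply(subdivisions, function(s)
    list(t_bar = rep(1, smax), dv_bar = 1, T = rep(1, smax),
         n_bins = rep_len(as.integer(n_bins), smax), n_animals = 1L))
  names(subs) <- subdivisions
  structure(list(smax = as.integer(smax), subdivisions = subs),
            class = "flatmap_spec")
}

# label map with values set from a dense matrix (rows x bins)
map_from_matrix <- function(spec, M, subdivision = names(spec$subdivisions)[1],
                            experiment_id = "e1") {
  m <- empty_label_map(spec, experiment_id)
  for (i in seq_len(spec$smax)) {
    nb <- spec$subdivisions[[subdivision]]$n_bins[i]
    if (nb > 0L) m$values[[subdivision]][[i]] <- as.numeric(M[i, seq_len(nb)])
  }
  m$empty <- sum(unlist(m$values)) == 0
  m
}

# one-animal measurement record with a given per-section profile
simple_record <- function(id, s_um, dv_um, age = 10,
                          subdivision = "PrS_sup", spacing = 300) {
  animal_record(id, age,
                data.frame(section_index = seq_along(s_um),
                           subdivision = subdivision, transverse_um = s_um),
                spacing_um = spacing, dv_um = dv_um)
}

# brute-force closest point on a parametric planar surface by dense sampling
dense_surface_oracle <- function(p, length, width, n_grid = 100) {
  u <- seq(0, 1, length.out = n_grid)
  v <- seq(0, 1, length.out = n_grid)
  g <- expand.grid(u = u, v = v)
  pts <- cbind(g$u * length, g$v * width, 0)
  d2 <- rowSums(sweep(pts, 2, p, "-")^2)
  i <- which.min(d2)
  list(point = pts[i, ], dist = sqrt(d2[i]))
}
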