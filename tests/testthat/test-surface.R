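test_that("local-regression smoothing reproduces noiseless lines and rejects short input", {
  x <- seq(0, 1, length.out = 20)
  line <- border_polyline(cbind(x, 2 * x, -x), role = "dorsal_of_area")
  sm <- smooth_borders(line, span = 0.5)
  expect_lt(max(abs(unclass(sm) - unclass(line))), 1e-9)
  expect_error(smooth_borders(border_polyline(cbind(0:2, 0, 0)), span = 0.5),
               "at least 4 points")
})

test_that("smoothing noisy straight borders reduces the maximum residual to the line", {
  n_better <- 0L
  for (s in 1:100) {
    set.seed(s)
    x <- seq(0, 10, length.out = 30)
    noise <- matrix(rnorm(90, 0, 0.05), ncol = 3)
    raw <- cbind(x, 0, 0) + noise
    sm <- smooth_borders(border_polyline(raw), span = 0.5)
    resid_raw <- max(sqrt(raw[, 2]^2 + raw[, 3]^2))
    resid_sm <- max(sqrt(unclass(sm)[, 2]^2 + unclass(sm)[, 3]^2))
    if (resid_sm < resid_raw) n_better <- n_better + 1L
  }
  expect_gte(n_better, 95L)
})

test_that("strip triangulation tiles rectangles and trapezoids with the exact area", {
  s <- planar_surface(length = 10, width = 4, n = 11)
  expect_equal(length(s$areas), 2 * (11 - 1))
  expect_equal(sum(s$areas), 40, tolerance = 1e-9)
  # trapezoid: dorsal longer than ventral (parallel sides 12 and 8, height 3)
  d <- border_polyline(cbind(seq(-1, 11, length.out = 13), 3, 0),
                       role = "dorsal_of_area")
  v <- border_polyline(cbind(seq(1, 9, length.out = 13), 0, 0),
                       role = "ventral_of_area")
  tz <- triangulate_strip(d, v)
  expect_equal(sum(tz$areas), (12 + 8) / 2 * 3, tolerance = 1e-9)
})

test_that("degenerate and crossing border pairs are geometry errors", {
  x <- seq(0, 10, length.out = 11)
  b <- border_polyline(cbind(x, 0, 0), role = "dorsal_of_area")
  expect_error(triangulate_strip(b, b), "degenerate")
  d <- border_polyline(cbind(x, seq(2, -2, length.out = 11), 0),
                       role = "dorsal_of_area")
  v <- border_polyline(cbind(x, seq(-2, 2, length.out = 11), 0),
                       role = "ventral_of_area")
  expect_error(triangulate_strip(d, v), "cross|degenerate")
})

test_that("surface transposition is the closest-point projection", {
  s <- planar_surface()
  on_face <- c(3.3, 1.7, 0)
  tp <- transpose_to_surface(on_face, s)
  expect_equal(tp$point, on_face, tolerance = 1e-12)
  expect_equal(tp$dist, 0, tolerance = 1e-12)
  # orthogonal projection from above the footprint
  tp2 <- transpose_to_surface(c(6.1, 2.5, 3), s)
  expect_equal(tp2$point, c(6.1, 2.5, 0), tolerance = 1e-9)
  expect_equal(tp2$dist, 3, tolerance = 1e-9)
})

test_that("points outside the footprint match a dense-sampling oracle", {
  s <- planar_surface(length = 10, width = 4)
  set.seed(42)
  for (k in 1:20) {
    p <- c(runif(1, -3, 13), runif(1, -3, 7), runif(1, -2, 2))
    tp <- transpose_to_surface(p, s)
    oracle <- dense_surface_oracle(p, 10, 4, n_grid = 100)
    expect_lt(abs(tp$dist - oracle$dist), 0.08)   # oracle grid resolution
    expect_lte(tp$dist, oracle$dist + 1e-12)      # true min never beats oracle
  }
})

test_that("normalized coordinates match planar analytic geometry", {
  s <- planar_surface(length = 10, width = 4)
  # on the ventral border: dv = 0
  expect_equal(normalize_injection(c(5, 0, 0), s)$dv, 0, tolerance = 1e-12)
  # equidistant from both borders at the rostral end
  nc <- normalize_injection(c(0, 2, 0), s)
  expect_equal(nc$rc, 0, tolerance = 1e-12)
  expect_equal(nc$dv, 0.5, tolerance = 1e-12)
  # interior point: rostral offset 2.5 of 10, 1.0 above the ventral border
  nc <- normalize_injection(c(2.5, 1.0, 0), s)
  expect_equal(nc$rc, 0.25, tolerance = 1e-12)
  expect_equal(nc$dv, 0.25, tolerance = 1e-12)
  expect_equal(nc$d_v, 1.0, tolerance = 1e-12)
  expect_equal(nc$d_d, 3.0, tolerance = 1e-12)
})

test_that("rc and dv stay in [0,1] and rc grows monotonically along the midline", {
  s <- planar_surface()
  set.seed(7)
  pts <- cbind(runif(50, 0, 10), runif(50, 0, 4), 0)
  vals <- t(apply(pts, 1, function(p) {
    nc <- normalize_injection(p, s); c(nc$rc, nc$dv)
  }))
  expect_true(all(vals >= 0 & vals <= 1))
  rc_mid <- sapply(seq(0.1, 9.9, length.out = 30), function(x)
    normalize_injection(c(x, 2, 0), s)$rc)
  expect_true(all(diff(rc_mid) >= 0))
})

test_that("normalized coordinates are invariant under rigid motion", {
  b <- planar_strip(length = 10, width = 4)
  p <- c(3.1, 1.2, 0)
  s0 <- triangulate_strip(b$dorsal, b$ventral)
  ref <- normalize_injection(p, s0)
  theta <- 0.83; phi <- -0.41
  Rz <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0,
                 0, 0, 1), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(phi), -sin(phi), 0, sin(phi), cos(phi)),
               3, byrow = TRUE)
  R <- Rz %*% Rx; shift <- c(5, -3, 2)
  mov <- function(m) sweep(unclass(m) %*% t(R), 2, shift, "+")
  s1 <- triangulate_strip(border_polyline(mov(b$dorsal), "dorsal_of_area"),
                          border_polyline(mov(b$ventral), "ventral_of_area"))
  got <- normalize_injection(as.numeric(R %*% p + shift), s1)
  expect_equal(got$rc, ref$rc, tolerance = 1e-9)
  expect_equal(got$dv, ref$dv, tolerance = 1e-9)
})

test_that("border distances agree with a dense-sampling oracle", {
  b <- planar_strip(length = 10, width = 4)
  s <- triangulate_strip(b$dorsal, b$ventral)
  dense_d <- resample_polyline(b$dorsal, 10000L)
  dense_v <- resample_polyline(b$ventral, 10000L)
  set.seed(11)
  for (k in 1:10) {
    p <- c(runif(1, 0, 10), runif(1, 0, 4), 0)
    nc <- normalize_injection(p, s)
    oracle_d <- min(sqrt(rowSums(sweep(unclass(dense_d), 2, p, "-")^2)))
    oracle_v <- min(sqrt(rowSums(sweep(unclass(dense_v), 2, p, "-")^2)))
    expect_lt(abs(nc$d_d - oracle_d), 2e-3)
    expect_lt(abs(nc$d_v - oracle_v), 2e-3)
  }
})

test_that("a point on both borders at once is a geometry error", {
  # hand-built strip whose borders pinch together at the caudal end
  d <- border_polyline(cbind(0:10, seq(2, 0, length.out = 11), 0),
                       role = "dorsal_of_area")
  v <- border_polyline(cbind(0:10, seq(-2, 0, length.out = 11), 0),
                       role = "ventral_of_area")
  mid <- (unclass(d) + unclass(v)) / 2
  s <- list(dorsal = d, ventral = v, midline = mid)
  expect_error(normalize_injection(c(10, 0, 0), s), "both borders")
})

test_that("flatten_injections assigns areas by nearest strip in the three-border form", {
  x <- seq(0, 10, length.out = 21)
  borders <- list(
    dorsal_A30 = border_polyline(cbind(x, 4, 0), role = "dorsal_A30"),
    A29_A30_boundary = border_polyline(cbind(x, 2, 0),
                                       role = "A29_A30_boundary"),
    ventral_A29 = border_polyline(cbind(x, 0, 0), role = "ventral_A29"))
  inj <- data.frame(experiment_id = c("e_dorsal", "e_ventral"),
                    animal_id = c("a1", "a2"), age_days = c(5, 5),
                    x = c(5, 5), y = c(3.5, 0.5), z = c(1, 1))
  out <- flatten_injections(borders, inj, span = NULL)
  expect_equal(out$area, c("A30", "A29"))
  # dv is normalized within the assigned area's own borders
  expect_equal(out$dv[1], 1.5 / 2, tolerance = 1e-9)  # 1.5 above boundary of 2
  expect_equal(out$dv[2], 0.5 / 2, tolerance = 1e-9)
  expect_equal(out$rc, c(0.5, 0.5), tolerance = 1e-9)
})
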