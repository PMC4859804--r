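# brute-force normalized convolution on a masked matrix, written directly
# from the definition as an independent check of the smoother
brute_smooth <- function(M, size = 5L, sigma = 1.5) {
  half <- (size - 1L) %/% 2L
  k1 <- dnorm(-half:half, sd = sigma)
  K <- outer(k1, k1); K <- K / sum(K)
  out <- M
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    if (is.na(M[i, j])) next
    num <- 0; den <- 0
    for (a in -half:half) for (b in -half:half) {
      ii <- i + a; jj <- j + b
      if (ii < 1 || ii > nrow(M) || jj < 1 || jj > ncol(M)) next
      if (is.na(M[ii, jj])) next
      w <- K[a + half + 1, b + half + 1]
      num <- num + w * M[ii, jj]; den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

test_that("Gaussian smoothing preserves constants and reproduces the kernel on impulses", {
  spec <- make_spec(9, 9)
  const <- map_from_matrix(spec, matrix(0.4, 9, 9))
  expect_equal(unname(unlist(smooth_flatmap(const)$values)), rep(0.4, 81))
  # interior impulse: the 5x5 patch equals the normalized Gaussian kernel
  M <- matrix(0, 9, 9); M[5, 5] <- 1
  sm <- map_to_dense(smooth_flatmap(map_from_matrix(spec, M)), "PrS_sup")
  k1 <- dnorm(-2:2, sd = 1.5)
  K <- outer(k1, k1); K <- K / sum(K)
  expect_equal(sm[3:7, 3:7], K, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
})

test_that("smoothing at region corners matches the renormalized truncated kernel", {
  spec <- make_spec(9, 9)
  M <- matrix(0, 9, 9); M[1, 1] <- 1
  got <- map_to_dense(smooth_flatmap(map_from_matrix(spec, M)), "PrS_sup")
  expect_equal(got, brute_smooth(M), tolerance = 1e-12)
  # ragged region: no bleed across out-of-region bins, constants preserved
  spec2 <- make_spec(6, 1)
  spec2$subdivisions$PrS_sup$n_bins <- c(2L, 4L, 6L, 6L, 4L, 2L)
  m2 <- empty_label_map(spec2, "e")
  m2$values$PrS_sup <- lapply(c(2, 4, 6, 6, 4, 2), function(n) rep(0.7, n))
  sm2 <- smooth_flatmap(m2)
  expect_equal(unname(unlist(sm2$values)), rep(0.7, 24))
})

test_that("flatmap correlations form a valid matrix with unit diagonal", {
  spec <- make_spec(4, 5)
  set.seed(3)
  M <- matrix(runif(20), 4, 5)
  m1 <- map_from_matrix(spec, M, , "e1")
  m2 <- map_from_matrix(spec, 1 - M, , "e2")
  R <- flatmap_correlations(list(m1, m2))
  expect_equal(diag(R), c(e1 = 1, e2 = 1))
  expect_equal(R["e1", "e2"], -1)
  z <- map_from_matrix(spec, matrix(1, 4, 5), , "flat")
  expect_error(flatmap_correlations(list(m1, z)), "flat")
})

test_that("independent random maps are near-uncorrelated (null simulation)", {
  spec <- make_spec(50, 20)   # 1000 bins
  big <- 0L
  for (s in 1:100) {
    set.seed(s)
    m1 <- map_from_matrix(spec, matrix(runif(1000), 50, 20), , "a")
    m2 <- map_from_matrix(spec, matrix(runif(1000), 50, 20), , "b")
    r <- flatmap_correlations(list(m1, m2))["a", "b"]
    if (abs(r) >= 0.15) big <- big + 1L
  }
  expect_lte(big, 5L)
})

test_that("k-means on the correlation matrix recovers clear group structure", {
  spec <- make_spec(6, 6)
  set.seed(2)
  A <- matrix(runif(36), 6, 6); B <- matrix(runif(36), 6, 6)
  maps <- c(lapply(1:5, function(i)
    map_from_matrix(spec, A + matrix(rnorm(36, 0, 0.01), 6), ,
                    paste0("a", i))),
    lapply(1:5, function(i)
      map_from_matrix(spec, B + matrix(rnorm(36, 0, 0.01), 6), ,
                      paste0("b", i))))
  R <- flatmap_correlations(maps)
  cl <- cluster_experiments(R, k_range = 2:5, seed = 1)
  expect_equal(cl$chosen_k, 2L)
  expect_lt(cl$ratio[["2"]], 0.05)
  lab <- cl$labels
  expect_equal(length(unique(lab[1:5])), 1L)
  expect_equal(length(unique(lab[6:10])), 1L)
  expect_true(lab[1] != lab[6])
  expect_error(cluster_experiments(R, k_range = 2:10), "below the number")
})

test_that("identical maps give a degenerate (flagged) clustering", {
  spec <- make_spec(4, 4)
  m <- map_from_matrix(spec, matrix(runif(16), 4, 4))
  R <- matrix(1, 5, 5)  # all pairwise correlations 1
  cl <- cluster_experiments(R, k_range = 2:3, seed = 1)
  expect_true(cl$degenerate)
  expect_true(all(is.na(cl$ratio)))
})

test_that("three noisy archetype groups are recovered across seeds", {
  spec <- make_spec(6, 6)
  set.seed(99)
  arch <- lapply(1:3, function(i) matrix(runif(36), 6, 6))
  hit <- 0L
  for (s in 1:100) {
    set.seed(s)
    maps <- list(); truth <- integer(0)
    for (g in 1:3) for (i in 1:10) {
      maps[[length(maps) + 1L]] <-
        map_from_matrix(spec, arch[[g]] + matrix(rnorm(36, 0, 0.05), 6), ,
                        paste0("m", g, "_", i))
      truth <- c(truth, g)
    }
    cl <- cluster_experiments(flatmap_correlations(maps), k_range = 3,
                              n_restarts = 10, seed = s)
    # agreement up to label permutation
    tab <- table(cl$labels, truth)
    agree <- sum(apply(tab, 2, max)) / length(truth)
    if (agree > 0.9) hit <- hit + 1L
  }
  expect_gte(hit, 95L)
})

test_that("ordinary least squares matches the normal-equations oracle", {
  # 12-row hand-made table
  d <- data.frame(
    rc  = c(0.1, 0.3, 0.5, 0.7, 0.9, 0.2, 0.4, 0.6, 0.8, 0.15, 0.55, 0.95),
    dv  = c(0.2, 0.8, 0.4, 0.6, 0.1, 0.9, 0.3, 0.7, 0.5, 0.25, 0.85, 0.45),
    age = c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19, 2, 8))
  set.seed(4)
  d$y <- 0.3 - 0.2 * d$rc + 0.1 * d$dv + 0.01 * d$age + rnorm(12, 0, 0.05)
  fit <- fit_topography(d, "y", alpha = 1)   # full interaction model kept
  X <- cbind(1, d$rc, d$dv, d$age, d$rc * d$dv, d$rc * d$age, d$dv * d$age)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(fit$table$estimate), as.numeric(beta), tolerance = 1e-8)
  # closed-form confidence intervals
  res <- d$y - X %*% beta
  s2 <- sum(res^2) / (12 - 7)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  tq <- qt(0.975, 12 - 7)
  expect_equal(unname(fit$table$ci_lo), as.numeric(beta - tq * se),
               tolerance = 1e-8)
  expect_equal(unname(fit$table$ci_hi), as.numeric(beta + tq * se),
               tolerance = 1e-8)
  expect_equal(unname(fit$table$df), rep(5, 7))
})

test_that("backward elimination spans the full and main-effects models at the alpha extremes", {
  set.seed(8)
  n <- 60
  d <- data.frame(rc = runif(n), dv = runif(n), age = sample(1:19, n, TRUE))
  d$y <- 0.5 - 0.3 * d$rc + rnorm(n, 0, 0.05)
  full <- fit_topography(d, "y", alpha = 1)
  expect_setequal(full$terms,
                  c("rc", "dv", "age", "rc:dv", "rc:age", "dv:age"))
  mains <- fit_topography(d, "y", alpha = 0)
  expect_setequal(mains$terms, c("rc", "dv", "age"))
  expect_equal(nrow(mains$trace), 3L)   # one interaction dropped per step
  # noiseless generative recovery: beta_rc -> -0.3
  d2 <- d
  d2$y <- 0.5 - 0.3 * d2$rc + rnorm(n, 0, 1e-9)
  fit2 <- fit_topography(d2, "y")
  expect_setequal(fit2$terms, c("rc", "dv", "age"))
  expect_equal(fit2$table$estimate[fit2$table$term == "rc"], -0.3,
               tolerance = 1e-5)
})

test_that("a pure interaction survives elimination", {
  set.seed(10)
  n <- 200
  d <- data.frame(rc = runif(n), dv = runif(n), age = sample(1:19, n, TRUE))
  d$y <- d$rc * d$dv + rnorm(n, 0, 0.01)
  fit <- fit_topography(d, "y")
  expect_true("rc:dv" %in% fit$terms)
  expect_lt(fit$table$p[fit$table$term == "rc:dv"], 0.05)
})

test_that("standardized and unstandardized coefficients share t and p", {
  set.seed(12)
  n <- 50
  d <- data.frame(rc = runif(n), dv = runif(n), age = sample(1:19, n, TRUE))
  d$y <- 0.2 + 0.4 * d$dv - 0.02 * d$age + rnorm(n, 0, 0.1)
  fit <- fit_topography(d, "y", alpha = 0)
  # standardized beta = t * sd-ratio consistency: recompute directly
  for (term in c("rc", "dv", "age")) {
    row <- fit$table[fit$table$term == term, ]
    expect_equal(row$std_beta,
                 row$estimate * sd(fit$data[[term]]) / sd(fit$data$y),
                 tolerance = 1e-12)
  }
  # scaling the outcome leaves t and p unchanged
  d2 <- d; d2$y <- d2$y * 7
  fit2 <- fit_topography(d2, "y", alpha = 0)
  expect_equal(fit2$table$t, fit$table$t, tolerance = 1e-9)
  expect_equal(fit2$table$p, fit$table$p, tolerance = 1e-9)
})

test_that("age and CoM filters and the sample-size precondition apply", {
  set.seed(13)
  n <- 30
  d <- data.frame(rc = runif(n), dv = runif(n),
                  age = c(sample(1:19, 20, TRUE), rep(27, 10)))
  d$y <- 0.5 - 0.2 * d$rc + rnorm(n, 0, 0.05)
  d$y[1:3] <- NA   # experiments without labeled axons
  fit <- fit_topography(d, "y", age_max = 19)
  expect_equal(fit$n, 17L)
  expect_equal(fit$n_excluded, 13L)
  expect_error(fit_topography(d[1:12, ], "y"), "at least 10")
})

test_that("variance inflation factors come from auxiliary regressions", {
  # orthogonal predictors: all VIF exactly 1
  d <- expand.grid(rc = c(0, 1), dv = c(0, 1), age = c(1, 19))
  d <- rbind(d, d)
  set.seed(14)
  d$y <- rnorm(nrow(d))
  fit <- fit_topography(d, "y", alpha = 0)
  diag <- regression_diagnostics(fit)
  expect_equal(unname(diag$vif), rep(1, 3), tolerance = 1e-12)
  expect_true(diag$collinearity_ok)
  # correlated predictors: VIF approx 1 / (1 - r^2)
  set.seed(15)
  n <- 500
  rc <- runif(n)
  dv <- 0.6 * scale(rc)[, 1] * sd(rc) + sqrt(1 - 0.36) * rnorm(n, 0, sd(rc))
  d2 <- data.frame(rc = rc, dv = dv + mean(rc), age = sample(1:19, n, TRUE))
  d2$y <- rnorm(n)
  fit2 <- fit_topography(d2, "y", alpha = 0)
  diag2 <- regression_diagnostics(fit2)
  r <- cor(d2$rc, d2$dv)
  expect_equal(unname(diag2$vif[["rc"]]), 1 / (1 - r^2), tolerance = 0.1)
  skip_if_not_installed("car")
  expect_equal(unname(diag2$vif), unname(car::vif(fit2$fit)),
               tolerance = 1e-8)
})

test_that("a duplicated predictor is flagged as aliased or infinite-VIF", {
  set.seed(16)
  n <- 40
  d <- data.frame(rc = runif(n), age = sample(1:19, n, TRUE))
  d$dv <- d$rc   # exact duplicate
  d$y <- rnorm(n)
  expect_error(fit_topography(d, "y", alpha = 1), "alias|rank")
})

test_that("dichotomized-age regression recovers a group difference and validates groups", {
  set.seed(17)
  n <- 100
  d <- data.frame(rc = runif(n), dv = runif(n),
                  age = sample(1:14, n, TRUE))
  delta <- 0.3
  d$y <- 0.2 + delta * (d$age >= 7) + rnorm(n, 0, 1e-6)
  fit <- fit_age_dichotomized(d, "y", cut = 7)
  expect_equal(fit$table$estimate[fit$table$term == "age_group"], delta,
               tolerance = 1e-4)
  d_one <- d; d_one$age <- 3
  expect_error(fit_age_dichotomized(d_one, "y"), "one side")
  # identical groups: indicator indistinguishable from zero (null sim)
  sig <- 0L
  for (s in 1:100) {
    set.seed(s)
    dn <- data.frame(rc = runif(n), dv = runif(n),
                     age = sample(1:14, n, TRUE))
    dn$y <- 0.5 + rnorm(n, 0, 0.1)
    f <- fit_age_dichotomized(dn, "y", alpha = 0)
    if (f$table$p[f$table$term == "age_group"] <= 0.05) sig <- sig + 1L
  }
  expect_gte(100L - sig, 90L)
})
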