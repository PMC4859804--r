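#' Dense rectangular embedding of one subdivision's ragged grid
#'
#' Rows of a flatmap have different bin counts; for image-style operations
#' the grid is embedded in an `smax x max(n_bins)` matrix, left-aligned at
#' the proximal/medial edge, with `NA` outside the region.
#'
#' @param map an `experiment_label_map`.
#' @param subdivision subdivision name.
#' @return numeric matrix with `NA` outside the region.
#' @export
map_to_dense <- function(map, subdivision) {
  nb <- map$spec$subdivisions[[subdivision]]$n_bins
  width <- max(nb, 1L)
  M <- matrix(NA_real_, nrow = map$spec$smax, ncol = width)
  for (i in seq_len(map$spec$smax))
    if (nb[i] > 0L) M[i, seq_len(nb[i])] <- map$values[[subdivision]][[i]]
  M
}

## masked Gaussian filtering of a dense matrix: normalized convolution, i.e.
## the kernel is renormalized over the in-region support at every target bin,
## so constants are preserved and no mass bleeds in from outside the region
.smooth_masked <- function(M, size, sigma) {
  mask <- !is.na(M)
  M0 <- ifelse(mask, M, 0)
  half <- (size - 1L) %/% 2L
  off <- -half:half
  k1 <- stats::dnorm(off, sd = sigma)
  K <- outer(k1, k1); K <- K / sum(K)
  nr <- nrow(M); nc <- ncol(M)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (a in seq_along(off)) for (b in seq_along(off)) {
    di <- off[a]; dj <- off[b]
    si <- seq_len(nr) - di; sj <- seq_len(nc) - dj
    ok_i <- si >= 1 & si <= nr; ok_j <- sj >= 1 & sj <= nc
    if (!any(ok_i) || !any(ok_j)) next
    w <- K[a, b]
    num[ok_i, ok_j] <- num[ok_i, ok_j] +
      w * M0[si[ok_i], sj[ok_j], drop = FALSE]
    den[ok_i, ok_j] <- den[ok_i, ok_j] +
      w * mask[si[ok_i], sj[ok_j], drop = FALSE]
  }
  out <- matrix(NA_real_, nr, nc)
  out[mask] <- num[mask] / den[mask]
  out
}

#' Gaussian-smooth a label map
#'
#' Before clustering, each flatmap is smoothed with a 5 x 5 bin Gaussian
#' filter of standard deviation 1.5 bins, applied on the dense embedding of
#' each subdivision's ragged grid. At region boundaries the kernel is
#' renormalized over the bins that exist, so constant maps stay constant and
#' nothing bleeds in from outside the region.
#'
#' @param map an `experiment_label_map`.
#' @param size odd kernel size in bins.
#' @param sigma kernel standard deviation in bins.
#' @return the smoothed map.
#' @export
smooth_flatmap <- function(map, size = 5L, sigma = 1.5) {
  stopifnot(size %% 2L == 1L, sigma > 0)
  for (sub in names(map$values)) {
    nb <- map$spec$subdivisions[[sub]]$n_bins
    if (all(nb == 0L)) next
    S <- .smooth_masked(map_to_dense(map, sub), size, sigma)
    for (i in seq_len(map$spec$smax))
      if (nb[i] > 0L) map$values[[sub]][[i]] <- S[i, seq_len(nb[i])]
  }
  map
}

#' Pairwise Pearson correlations between flatmaps
#'
#' Each map is vectorized over its in-region bins (all subdivisions
#' concatenated) and every pair of experiments is correlated.
#'
#' @param maps list of >= 2 `experiment_label_map`s on one spec.
#' @return symmetric correlation matrix with unit diagonal, dimnames taken
#'   from the experiment ids.
#' @export
flatmap_correlations <- function(maps) {
  stopifnot(length(maps) >= 2L)
  .check_same_spec(maps)
  vecs <- vapply(maps, function(m) unlist(m$values, use.names = FALSE),
                 numeric(length(unlist(maps[[1]]$values))))
  ids <- vapply(maps, function(m) as.character(m$experiment_id), character(1))
  sds <- apply(vecs, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance flatmap(s): correlation undefined for ",
         paste(ids[sds == 0], collapse = ", "), call. = FALSE)
  R <- stats::cor(vecs)
  dimnames(R) <- list(ids, ids)
  diag(R) <- 1
  R
}

#' Cluster experiments from their flatmap correlation matrix
#'
#' Runs k-means (squared-Euclidean distance, multiple restarts, fixed seed)
#' on the rows of the pairwise correlation matrix for each candidate number
#' of clusters, and reports the within- to between-cluster variance ratio
#' (SSW/SSB). The number of clusters is fixed at the point where adding
#' another cluster no longer yields a substantial decrease of the ratio
#' (default: a drop of at least 0.1 in SSW/SSB); the threshold is exposed so
#' users can override the choice, as the elbow is ultimately a judgement
#' call.
#'
#' @param corr correlation matrix from [flatmap_correlations()].
#' @param k_range candidate cluster counts.
#' @param n_restarts k-means restarts per k.
#' @param seed RNG seed for the restarts.
#' @param threshold minimum decrease of the SSW/SSB ratio regarded
#'   substantial.
#' @return a `cluster_result`: list with `chosen_k`, `labels` (for the chosen
#'   k), `ratio` (SSW/SSB per k), `k_range`, `labels_by_k`, `degenerate`
#'   flag, and the input matrix.
#' @export
cluster_experiments <- function(corr, k_range = 2:8, n_restarts = 50L,
                                seed = NULL, threshold = 0.1) {
  n <- nrow(corr)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range >= n))
    stop("number of clusters must be below the number of experiments",
         call. = FALSE)
  if (any(k_range < 1L)) stop("k must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ratios <- numeric(length(k_range))
  labels_by_k <- vector("list", length(k_range))
  degenerate <- FALSE
  n_distinct <- nrow(unique(corr))
  for (j in seq_along(k_range)) {
    if (k_range[j] > n_distinct) {
      degenerate <- TRUE
      ratios[j] <- NA_real_
      labels_by_k[[j]] <- rep(1L, n)
      next
    }
    km <- stats::kmeans(corr, centers = k_range[j], nstart = n_restarts,
                        iter.max = 100L)
    if (km$betweenss <= 1e-12 * max(km$totss, 1)) {
      degenerate <- TRUE
      ratios[j] <- NA_real_
    } else {
      ratios[j] <- km$tot.withinss / km$betweenss
    }
    labels_by_k[[j]] <- km$cluster
  }
  chosen <- k_range[length(k_range)]
  if (length(k_range) > 1L && !degenerate) {
    for (j in 2:length(k_range)) {
      if (ratios[j - 1L] - ratios[j] < threshold) {
        chosen <- k_range[j - 1L]
        break
      }
    }
  }
  structure(list(chosen_k = chosen,
                 labels = labels_by_k[[match(chosen, k_range)]],
                 ratio = stats::setNames(ratios, k_range),
                 k_range = k_range, labels_by_k = labels_by_k,
                 degenerate = degenerate, corr = corr),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> chosen k=%d%s\n", x$chosen_k,
              if (x$degenerate) " (degenerate: no between-cluster variance)"
              else ""))
  cat("  SSW/SSB by k:",
      paste(sprintf("%s=%.3g", names(x$ratio), x$ratio), collapse = ", "),
      "\n")
  invisible(x)
}
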