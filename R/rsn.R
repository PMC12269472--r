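#' Gaussian surface smoothing of per-vertex time series
#'
#' Replaces every time sample by a Gaussian-weighted neighbourhood average
#' over inter-vertex distances with \eqn{\sigma = FWHM / 2.3548}. The weight
#' matrix is symmetrised to (near-)doubly-stochastic form by Sinkhorn
#' balancing so that each vertex's weights sum to one and the global mean of
#' every time sample is preserved.
#'
#' @param mesh A `cortical_mesh`.
#' @param series Vertices x samples matrix.
#' @param fwhm_mm Full width at half maximum of the kernel in mm (default 7).
#' @return Smoothed matrix of the same shape.
#' @export
smooth_series <- function(mesh, series, fwhm_mm = 7) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  if (nrow(series) != mesh$n_vertices) {
    stop("series vertex count does not match the mesh")
  }
  W <- smoothing_weights(mesh, fwhm_mm)
  W %*% series
}

#' @rdname smooth_series
#' @export
smoothing_weights <- function(mesh, fwhm_mm = 7) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- unname(mesh_distances(mesh))
  W <- exp(-d^2 / (2 * sigma^2))
  W[W < 1e-12] <- 0
  # Sinkhorn balancing: rows sum to exactly 1, columns to 1 within tolerance,
  # so row-stochastic smoothing also preserves the global mean.
  for (it in 1:200) {
    W <- W / rowSums(W)
    cs <- colSums(W)
    if (max(abs(cs - 1)) < 1e-12) break
    W <- sweep(W, 2L, cs, "/")
  }
  W / rowSums(W)
}

#' Select an evenly distributed vertex subset
#'
#' Deterministic farthest-point sampling from a fixed start vertex (vertex 1):
#' each step adds the vertex with the largest distance to the current subset,
#' yielding a spatially even reduction of the mesh as used before the
#' correlation/SVD step.
#'
#' @param mesh A `cortical_mesh`.
#' @param k Subset size, between 2 and `n_vertices`.
#' @return An object of class `reduction_plan` with `subset_indices`
#'   (1-based, in selection order), `method`, and `k`.
#' @export
select_even_subset <- function(mesh, k) {
  n <- mesh$n_vertices
  if (k < 2L || k > n) stop("k must be between 2 and n_vertices")
  d <- mesh_distances(mesh)
  idx <- .farthest_point_indices(d, k, start = 1L)
  structure(list(subset_indices = idx, method = "farthest-point", k = k),
            class = "reduction_plan")
}

.farthest_point_indices <- function(d, k, start = 1L) {
  n <- nrow(d)
  if (k >= n) return(seq_len(n))
  idx <- integer(k)
  idx[1L] <- start
  mind <- d[start, ]
  for (i in 2:k) {
    nxt <- which.max(mind)
    idx[i] <- nxt
    mind <- pmin(mind, d[nxt, ])
  }
  idx
}

#' Extract resting-state networks by correlation + SVD
#'
#' Implements the group-level network extraction: each subject's per-vertex
#' megPAC series is z-scored and the series are concatenated along time; the
#' Pearson correlation matrix over the subset vertices of the reduction plan
#' is decomposed by SVD; the leading `n_modes` spatial modes are carried back
#' to full resolution by correlating every vertex's concatenated series with
#' each mode's time course; finally each map is rectified and scaled to
#' \[0,1\] with maximum exactly 1 (the "coupling strength").
#'
#' @param series_list List of vertices x samples matrices, one per subject
#'   (all on the same mesh).
#' @param plan A `reduction_plan` from [select_even_subset()], or `NULL` for
#'   all vertices.
#' @param n_modes Number of spatial modes to retain (default 10).
#' @return An object of class `rsn_set` with `modes` (n_modes x n_vertices
#'   coupling-strength maps in \[0,1\]), `singular_values` (all, descending),
#'   `subset_vectors` (k x n_modes orthonormal), and `plan`.
#' @export
extract_rsns <- function(series_list, plan = NULL, n_modes = 10L) {
  stopifnot(length(series_list) >= 1L)
  nv <- nrow(series_list[[1L]])
  zs <- lapply(series_list, function(m) {
    mu <- rowMeans(m)
    s <- apply(m, 1L, stats::sd)
    s[s == 0] <- Inf   # zero-variance vertex contributes zeros
    (m - mu) / s
  })
  X <- do.call(cbind, zs)            # nv x T concatenated
  sub <- if (is.null(plan)) seq_len(nv) else plan$subset_indices
  if (n_modes > length(sub)) {
    stop("n_modes exceeds the subset size")
  }
  if (ncol(X) < length(sub)) {
    warning("fewer time samples than subset vertices: correlation matrix is rank deficient")
  }
  Y <- X[sub, , drop = FALSE]
  C <- suppressWarnings(stats::cor(t(Y)))
  C[!is.finite(C)] <- 0              # zero-variance vertices
  eig <- eigen(C, symmetric = TRUE)
  U <- eig$vectors[, seq_len(n_modes), drop = FALSE]
  # mode time courses on the subset; back-project to full resolution
  tc <- crossprod(Y, U)              # T x n_modes
  maps <- matrix(0, n_modes, nv)
  Xc <- X - rowMeans(X)
  xs <- sqrt(rowSums(Xc^2))
  xs[xs == 0] <- Inf
  tcc <- sweep(tc, 2L, colMeans(tc))
  tcs <- sqrt(colSums(tcc^2))
  tcs[tcs == 0] <- Inf
  for (m in seq_len(n_modes)) {
    maps[m, ] <- abs((Xc %*% tcc[, m]) / (xs * tcs[m]))
  }
  mx <- apply(maps, 1L, max)
  mx[mx == 0] <- 1
  maps <- maps / mx
  structure(list(
    modes = maps,
    singular_values = eig$values,
    subset_vectors = U,
    n_modes = n_modes,
    plan = plan
  ), class = "rsn_set")
}

#' @export
print.rsn_set <- function(x, ...) {
  cat(sprintf("rsn_set: %d modes over %d vertices; leading singular values: %s\n",
              x$n_modes, ncol(x$modes),
              paste(signif(utils::head(x$singular_values, 3), 3), collapse = ", ")))
  invisible(x)
}
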