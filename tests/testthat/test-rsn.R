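test_that("smoothing preserves constants and the global mean, and shrinks to identity", {
  mesh <- ico1_mesh()
  set.seed(2)
  x <- matrix(rnorm(mesh$n_vertices * 5), mesh$n_vertices, 5)
  sm <- smooth_series(mesh, x, fwhm_mm = 40)
  expect_equal(colMeans(sm), colMeans(x), tolerance = 1e-8)
  const <- matrix(0.7, mesh$n_vertices, 3)
  expect_equal(smooth_series(mesh, const, 40), const, tolerance = 1e-10)
  # FWHM far below the minimum vertex spacing: identity
  expect_equal(smooth_series(mesh, x, fwhm_mm = 1), x, tolerance = 1e-10)
  expect_error(smooth_series(mesh, x, fwhm_mm = 0), "positive")
  expect_error(smooth_series(mesh, x[-1, , drop = FALSE], 7), "match")
})

test_that("an impulse spreads with the Gaussian kernel profile", {
  mesh <- build_mesh(list(type = "grid", nx = 9, ny = 9, spacing_mm = 3))
  W <- smoothing_weights(mesh, fwhm_mm = 7)
  centre <- 41L  # middle of the 9x9 grid
  d <- unname(mesh_distances(mesh)[centre, ])
  sigma <- 7 / (2 * sqrt(2 * log(2)))
  kernel <- exp(-d^2 / (2 * sigma^2))
  got <- W[centre, ]
  # profile proportional to the kernel over the vertices that matter
  keep <- kernel > 1e-6
  expect_equal(got[keep] / sum(got[keep]), kernel[keep] / sum(kernel[keep]),
               tolerance = 0.05)
})

test_that("farthest-point subsets are deterministic, spread out, and bounded", {
  mesh <- build_mesh(list(type = "icosphere", subdiv = 2, radius_mm = 50))
  expect_error(select_even_subset(mesh, 1), "between")
  expect_error(select_even_subset(mesh, mesh$n_vertices + 1), "between")
  expect_identical(select_even_subset(mesh, mesh$n_vertices)$subset_indices,
                   seq_len(mesh$n_vertices))
  p1 <- select_even_subset(mesh, 40)
  p2 <- select_even_subset(mesh, 40)
  expect_identical(p1$subset_indices, p2$subset_indices)

  d <- mesh_distances(mesh)
  p <- select_even_subset(mesh, 2)
  expect_gte(d[p$subset_indices[1], p$subset_indices[2]], 0.95 * max(d))

  # spread: max nearest-subset distance <= 2x the ideal uniform spacing
  sub <- p1$subset_indices
  cover <- apply(d[, sub, drop = FALSE], 1, min)
  ideal <- sqrt(4 * pi * 50^2 / 40)
  expect_lte(max(cover), 2 * ideal)
})

test_that("a rank-one group gives one constant full-strength map", {
  set.seed(5)
  base <- rnorm(400)
  series <- matrix(rep(base, each = 12), 12, 400)
  rs <- extract_rsns(list(series), NULL, n_modes = 10)
  expect_equal(rs$modes[1, ], rep(1, 12), tolerance = 1e-8)
  expect_gt(rs$singular_values[1] / sum(abs(rs$singular_values)), 0.99)
})

test_that("two independent blocks separate into the leading two modes", {
  # blocks of distinct extent, so the two block singular values do not
  # collide (under exact degeneracy the eigenvectors are free to mix)
  set.seed(7)
  env1 <- rnorm(600)
  env2 <- rnorm(600)
  mk <- function() {
    rbind(
      matrix(rep(env1, each = 12), 12) + 0.01 * matrix(rnorm(7200), 12),
      matrix(rep(env2, each = 8), 8) + 0.01 * matrix(rnorm(4800), 8)
    )
  }
  rs <- extract_rsns(list(mk(), mk()), NULL, n_modes = 10)
  block1 <- c(rep(1, 12), rep(0, 8))
  m1 <- match_to_template(rs, block1)
  m2 <- match_to_template(rs, 1 - block1)
  expect_setequal(c(m1$mode, m2$mode), c(1L, 2L))
  expect_equal(m1$phi, 1)
  expect_equal(m2$phi, 1)
})

test_that("maps are normalized, subset modes orthogonal, and sign-invariant", {
  set.seed(8)
  series <- lapply(1:3, function(i) matrix(rnorm(15 * 300), 15, 300))
  plan <- structure(list(subset_indices = 1:15, method = "farthest-point",
                         k = 15), class = "reduction_plan")
  rs <- extract_rsns(series, plan, n_modes = 10)
  expect_true(all(rs$modes >= 0))
  expect_equal(unname(apply(rs$modes, 1, max)), rep(1, 10))
  expect_true(all(diff(rs$singular_values) <= 1e-10))
  gram <- crossprod(rs$subset_vectors)
  expect_equal(gram, diag(10), tolerance = 1e-8)
  # flipping one vertex's series in every subject leaves the maps unchanged
  flipped <- lapply(series, function(m) { m[2, ] <- -m[2, ]; m })
  rs2 <- extract_rsns(flipped, plan, n_modes = 10)
  expect_equal(rs2$modes, rs$modes, tolerance = 1e-8)
})

test_that("zero-variance vertices yield zero coupling, and rank warnings fire", {
  set.seed(9)
  m <- matrix(rnorm(8 * 6), 8, 6)
  m[3, ] <- 5
  expect_warning(rs <- extract_rsns(list(m), NULL, n_modes = 5), "rank")
  expect_equal(rs$modes[1, 3], 0)
  expect_error(extract_rsns(list(m), NULL, n_modes = 9), "exceeds")
})

test_that("maps are robust to halving the even-subset size", {
  set.seed(10)
  mesh <- ico1_mesh()
  nv <- mesh$n_vertices
  env1 <- rnorm(500)
  env2 <- rnorm(500)
  members1 <- 1:12
  members2 <- 25:32
  mk <- function() {
    m <- 0.15 * matrix(rnorm(nv * 500), nv, 500)
    m[members1, ] <- m[members1, ] + rep(env1, each = length(members1))
    m[members2, ] <- m[members2, ] + rep(env2, each = length(members2))
    m
  }
  series <- list(mk(), mk())
  full <- extract_rsns(series, select_even_subset(mesh, nv), n_modes = 10)
  half <- extract_rsns(series, select_even_subset(mesh, nv %/% 2), n_modes = 10)
  for (tmpl in list(as.numeric(seq_len(nv) %in% members1),
                    as.numeric(seq_len(nv) %in% members2))) {
    mf <- match_to_template(full, tmpl)
    mh <- match_to_template(half, tmpl)
    agree <- phi_coefficient(binarize_map(mf$map), binarize_map(mh$map))
    expect_gte(agree, 0.7)
  }
})
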