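test_that("binarization thresholds at 40% of the map maximum, boundary inclusive", {
  b <- binarize_map(c(1.0, 0.5, 0.39), 0.4)
  expect_identical(b$members, c(TRUE, TRUE, FALSE))
  expect_identical(binarize_map(c(1, 0.4, 0.3999), 0.4)$members,
                   c(TRUE, TRUE, FALSE))
  expect_true(all(binarize_map(rep(0.7, 5), 0.4)$members))
  b0 <- binarize_map(c(0, 0.2, 0.5), 0)
  expect_identical(b0$members, c(TRUE, TRUE, TRUE))  # >= 0 * max
  expect_error(binarize_map(rep(0, 4)), "all-zero")
})

test_that("the phi coefficient matches the 2x2 formula and the Pearson identity", {
  a <- c(rep(TRUE, 4), rep(FALSE, 6))
  expect_equal(phi_coefficient(a, a), 1)
  expect_equal(phi_coefficient(a, !a), -1)
  # n11=3, n10=1, n01=1, n00=5 -> 14/24
  x <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  y <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  expect_equal(phi_coefficient(x, y), 14 / 24)
  expect_equal(phi_coefficient(y, x), 14 / 24)

  set.seed(3)
  for (i in 1:200) {
    u <- runif(50) > runif(1, 0.2, 0.8)
    v <- runif(50) > runif(1, 0.2, 0.8)
    if (length(unique(u)) < 2 || length(unique(v)) < 2) next
    expect_lt(abs(phi_coefficient(u, v) - cor(as.numeric(u), as.numeric(v))),
              1e-10)
  }
  expect_warning(z <- phi_coefficient(rep(TRUE, 5), c(TRUE, rep(FALSE, 4))),
                 "degenerate")
  expect_identical(z, 0)
  expect_error(phi_coefficient(c(TRUE, FALSE), rep(TRUE, 3)), "vertex counts")
})

test_that("welch_t reproduces stats::t.test and the inflated-variance formula", {
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    ref <- t.test(x, y)
    got <- welch_t(x, y)
    expect_lt(abs(got$t - unname(ref$statistic)), 1e-10)
    expect_lt(abs(got$df - unname(ref$parameter)), 1e-10)
    expect_lt(abs(got$p - ref$p.value), 1e-10)
  }
  # inflation by (N-1) per group: direct formula
  x <- rnorm(10); y <- rnorm(12)
  got <- welch_t(x, y, inflate_x = 9, inflate_y = 11)
  vx <- 81 * var(x) / 10; vy <- 121 * var(y) / 12
  expect_equal(got$t, (mean(x) - mean(y)) / sqrt(vx + vy), tolerance = 1e-12)
  expect_equal(got$df, (vx + vy)^2 / (vx^2 / 9 + vy^2 / 11), tolerance = 1e-12)
})

test_that("template matching picks the phi-argmax mode and flags degenerate matches", {
  set.seed(21)
  modes <- matrix(runif(10 * 30, 0, 0.3), 10, 30)
  modes[3, 1:8] <- 1
  modes <- modes / apply(modes, 1, max)
  rs <- structure(list(modes = modes, n_modes = 10L,
                       singular_values = 10:1), class = "rsn_set")
  template <- c(rep(1, 8), rep(0, 22))
  m <- match_to_template(rs, template)
  expect_equal(m$mode, 3L)
  expect_equal(m$phi, 1)
  # a template equal to mode 3 itself matches with phi 1
  m2 <- match_to_template(rs, modes[3, ])
  expect_equal(m2$mode, 3L)
  # all-constant modes give degenerate tables for every mode
  rs_bad <- structure(list(modes = matrix(1, 2, 30), n_modes = 2L),
                      class = "rsn_set")
  m3 <- suppressWarnings(match_to_template(rs_bad, template))
  expect_false(m3$valid)
})

test_that("vertex ANOVA reproduces the balanced closed-form oracle when uncorrected", {
  set.seed(31)
  nv <- 3
  n_per <- 6L
  vals <- lapply(megpac_conditions(), function(cc) {
    matrix(rnorm(n_per * nv, mean = 0.5, sd = 0.1), n_per, nv)
  })
  names(vals) <- megpac_conditions()
  fm <- fake_matched(vals)
  res <- vertex_anova(fm$matched, fm$templates, jackknife_correction = FALSE)
  an <- res$networks$net$anova
  for (v in 1:nv) {
    y <- unlist(lapply(megpac_conditions(), function(cc) vals[[cc]][, v]))
    conds <- rep(megpac_conditions(), each = n_per)
    med <- ifelse(grepl("ON$", conds), "ON", "OFF")
    sess <- ifelse(grepl("^first", conds), "first", "second")
    oracle <- balanced_twoway_oracle(y, med, sess)
    expect_equal(an$F_medication[v], oracle$F_a, tolerance = 1e-8)
    expect_equal(an$F_session[v], oracle$F_b, tolerance = 1e-8)
    expect_equal(an$F_interaction[v], oracle$F_ab, tolerance = 1e-8)
  }
})

test_that("jackknife correction divides F by (N-1)^2 and deflates post-hoc t", {
  set.seed(32)
  vals <- lapply(megpac_conditions(), function(cc) {
    matrix(rnorm(18 * 2, 0.5, 0.05), 18, 2)
  })
  names(vals) <- megpac_conditions()
  fm <- fake_matched(vals)
  raw <- vertex_anova(fm$matched, fm$templates, jackknife_correction = FALSE)
  adj <- vertex_anova(fm$matched, fm$templates, jackknife_correction = TRUE)
  expect_equal(adj$networks$net$anova$F_session,
               raw$networks$net$anova$F_session / 17^2, tolerance = 1e-10)
  expect_equal(adj$networks$net$posthoc$t,
               raw$networks$net$posthoc$t / 17, tolerance = 1e-10)
})

test_that("FDR-significant sets are nested across levels", {
  set.seed(33)
  vals <- lapply(megpac_conditions(), function(cc) {
    m <- matrix(rnorm(10 * 6, 0.5, 0.1), 10, 6)
    if (grepl("second", cc)) m[, 1:2] <- m[, 1:2] + 0.15
    m
  })
  names(vals) <- megpac_conditions()
  fm <- fake_matched(vals)
  r1 <- vertex_anova(fm$matched, fm$templates, jackknife_correction = FALSE,
                     q = 0.01)
  r5 <- vertex_anova(fm$matched, fm$templates, jackknife_correction = FALSE,
                     q = 0.05)
  s1 <- r1$networks$net$posthoc
  s5 <- r5$networks$net$posthoc
  expect_true(all(s5$sig[s1$sig]))
})

test_that("identical subjects give identical jackknife runs and no findings", {
  set.seed(34)
  base <- matrix(rnorm(12 * 80), 12, 80)
  processed <- setNames(
    lapply(1:4, function(i) list(megpac = base)),
    sprintf("s%02d", 1:4)
  )
  ens <- run_jackknife(processed, NULL, n_modes = 3)
  expect_equal(ens$n_runs, 4L)
  maps <- lapply(ens$runs, function(r) r$rsns$modes)
  for (i in 2:4) expect_equal(maps[[i]], maps[[1]], tolerance = 1e-10)
})

test_that("overlap tests report per-run phi with Welch pairwise comparisons", {
  set.seed(35)
  nv <- 30
  template <- c(rep(1, 10), rep(0, 20))
  mk_runs <- function(n, shift = 0) {
    lapply(1:n, function(r) {
      # a small random spatial jitter per run gives the phi values spread
      s <- shift + sample(0:2, 1)
      map <- template * runif(nv, 0.7, 1) + runif(nv, 0, 0.2)
      if (s > 0) map <- c(map[-(1:s)], map[1:s])
      list(map = map / max(map), phi = 1, mode = 1L,
           left_out = sprintf("s%02d", r))
    })
  }
  matched <- list(
    `first-OFF` = list(net = mk_runs(18)),
    `first-ON` = list(net = mk_runs(18)),
    `second-OFF` = list(net = mk_runs(17, shift = 4)),
    `second-ON` = list(net = mk_runs(19))
  )
  ov <- hc_overlap(matched, list(net = template), jackknife_correction = FALSE)
  expect_equal(nrow(ov$tests), 6L)
  expect_equal(sum(ov$phi$condition == "second-OFF"), 17L)
  sm <- ov$summary
  shifted_mean <- sm$mean[sm$condition == "second-OFF"]
  expect_true(all(shifted_mean < sm$mean[sm$condition != "second-OFF"]))
  sig <- ov$tests[ov$tests$p_bonf < 0.05, ]
  expect_true(all(grepl("second-OFF", paste(sig$condition_1, sig$condition_2))))
  # df of an uncorrected pair equals the Welch formula on the phi vectors
  x <- ov$phi$phi[ov$phi$condition == "first-OFF"]
  y <- ov$phi$phi[ov$phi$condition == "first-ON"]
  expect_equal(ov$tests$df[1], unname(t.test(x, y)$parameter),
               tolerance = 1e-10)
})

test_that("identical maps across conditions yield phi 1 everywhere and no differences", {
  template <- c(rep(1, 6), rep(0, 14))
  run <- list(map = template, phi = 1, mode = 1L, left_out = "s01")
  matched <- lapply(setNames(megpac_conditions(), megpac_conditions()),
                    function(cc) list(net = rep(list(run), 5)))
  ov <- hc_overlap(matched, list(net = template))
  expect_true(all(ov$phi$phi == 1))
  expect_true(all(ov$tests$p_bonf == 1))
})
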