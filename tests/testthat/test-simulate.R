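test_that("the same seed reproduces a recording bit for bit", {
  cfg <- tiny_sim(seed = 4)
  a <- simulate_recording(cfg, "s01", "first-ON", seed = 99)
  b <- simulate_recording(cfg, "s01", "first-ON", seed = 99)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth, b$truth)
  c <- simulate_recording(cfg, "s01", "first-ON", seed = 100)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("group generation reproduces the study cohort sizes with differing subject sets", {
  st <- reduced_study_config(seed = 2)
  grp <- generate_group(st$sim)
  sizes <- vapply(grp$cohorts, length, 1L)
  expect_equal(unname(sizes), c(18L, 18L, 17L, 19L))
  # excluded subjects vary across conditions, so paired tests are impossible
  expect_false(all(grp$cohorts[["first-OFF"]] %in% grp$cohorts[["second-OFF"]]) &&
               all(grp$cohorts[["second-OFF"]] %in% grp$cohorts[["first-OFF"]]))
  expect_length(grp$recordings, sum(sizes))
})

test_that("invalid simulation settings are rejected", {
  expect_error(sim_config(mesh_spec = list(type = "icosphere", subdiv = 0),
                          networks = list(list(name = "n", vertices = 1:3,
                                               f_phase = 10, f_amp = 140)),
                          fs = 250, duration_s = 30),
               "aliasing")
  expect_error(sim_config(mesh_spec = list(type = "icosphere", subdiv = 0),
                          networks = list(list(name = "n", vertices = 1:3,
                                               f_phase = 2, f_amp = 100)),
                          fs = 600, duration_s = 10),
               "100 cycles")
  expect_error(sim_config(mesh_spec = list(type = "icosphere", subdiv = 0),
                          networks = list(list(name = "a", vertices = 1:3,
                                               f_phase = 5, f_amp = 90),
                                          list(name = "b", vertices = 3:5,
                                               f_phase = 8, f_amp = 110)),
                          fs = 600, duration_s = 30),
               "disjoint")
})

test_that("vertex spectra peak at the planted phase frequency and amplitude band", {
  cfg <- tiny_sim(seed = 9, f_phase = 6, f_amp = 100, noise_sd = 0.1)
  rec <- simulate_recording(cfg, "s01", "first-OFF", seed = 31)$recording
  x <- rec$data[1, ]
  n <- length(x)
  p <- Mod(fft(x))^2
  freqs <- (0:(n - 1)) * rec$fs / n
  half <- freqs <= rec$fs / 2
  band_power <- function(f1, f2) sum(p[half & freqs >= f1 & freqs <= f2])
  # slow line dominates its vicinity
  expect_gt(band_power(5.5, 6.5), 10 * band_power(10, 20))
  # amplitude carrier plus sidebands clearly above a neighbouring silent band
  expect_gt(band_power(90, 110), 5 * band_power(50, 70))
})

test_that("planted coupling strength maps monotonically into measured PAC", {
  kappas <- c(0, 0.3, 0.6, 0.9)
  mean_pac <- sapply(kappas, function(k) {
    vals <- sapply(1:10, function(s) {
      cfg <- tiny_sim(seed = s, kappa = k, fs = 400, duration_s = 25,
                      f_phase = 8, f_amp = 110)
      rec <- simulate_recording(cfg, "s01", "first-OFF", seed = 500 + s)$recording
      estimate_pac(rec$data[1, ], 8, 110, 400)
    })
    mean(vals)
  })
  expect_true(all(diff(mean_pac) > 0))
  expect_lt(mean_pac[1], 0.05)
})

test_that("a null effect map is constant and effect multipliers hit the right cells", {
  st <- reduced_study_config(seed = 3, effect = TRUE)
  out <- simulate_recording(st$sim, "s01", "second-ON", seed = 77)
  expect_equal(sort(unique(out$truth$condition_multiplier)), c(1, 1.5))
  expect_true(all(which(out$truth$condition_multiplier == 1.5) %in%
                  st$effect_vertices))
  out_first <- simulate_recording(st$sim, "s01", "first-ON", seed = 77)
  expect_equal(out_first$truth$condition_multiplier,
               rep(1, st$sim$mesh$n_vertices))
  # background vertices carry no coupling
  expect_true(all(out$truth$kappa_eff[out$truth$network_label == 0] == 0))
})
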