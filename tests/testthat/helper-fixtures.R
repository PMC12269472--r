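# Shared fixtures, built in code. Heavier objects are cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

ico1_mesh <- function() fixture("ico1", function() {
  build_mesh(list(type = "icosphere", subdiv = 1, radius_mm = 50))
})

# A coupled test signal: slow oscillation plus phase-gated fast carrier.
coupled_signal <- function(f_phase = 6, f_amp = 100, fs = 600,
                           duration = 30, kappa = 1, noise_sd = 0,
                           envelope = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (0:(round(duration * fs) - 1)) / fs
  phi <- 2 * pi * f_phase * t
  m <- if (is.null(envelope)) 1 else envelope(t)
  x <- sin(phi) + kappa * m * (1 + cos(phi)) / 2 * sin(2 * pi * f_amp * t)
  if (noise_sd > 0) x <- x + rnorm(length(t), sd = noise_sd)
  x
}

# One tiny single-network simulation (12-vertex icosphere).
tiny_sim <- function(seed = 1, f_phase = 6, f_amp = 100, kappa = 0.9,
                     noise_sd = 0.3, fs = 600, duration_s = 30) {
  sim_config(
    mesh_spec = list(type = "icosphere", subdiv = 0),
    networks = list(list(name = "net", vertices = 1:3,
                         f_phase = f_phase, f_amp = f_amp)),
    kappa = kappa, noise_sd = noise_sd, fs = fs, duration_s = duration_s,
    seed = seed
  )
}

# Independent two-way balanced ANOVA oracle (cell-mean formulas).
balanced_twoway_oracle <- function(y, a, b) {
  stopifnot(length(unique(table(a, b))) == 1)  # balanced
  n <- length(y)
  r <- length(unique(a)); c <- length(unique(b))
  nc <- n / (r * c)
  grand <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  ss_a <- nc * c * sum((ma - grand)^2)
  ss_b <- nc * r * sum((mb - grand)^2)
  ss_ab <- nc * sum((sweep(sweep(mab, 1, ma - grand), 2, mb - grand) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_a - ss_b - ss_ab
  df_err <- n - r * c
  list(
    F_a = (ss_a / (r - 1)) / (ss_err / df_err),
    F_b = (ss_b / (c - 1)) / (ss_err / df_err),
    F_ab = (ss_ab / ((r - 1) * (c - 1))) / (ss_err / df_err)
  )
}

# Build a matched/templates pair carrying prescribed per-vertex values so the
# group-stats machinery can be driven with known numbers. `values` is a list
# values[[condition]] = runs x vertices matrix.
fake_matched <- function(values, network = "net") {
  conds <- megpac_conditions()
  matched <- list()
  templates <- list()
  for (cc in conds) {
    runs <- lapply(seq_len(nrow(values[[cc]])), function(r) {
      list(map = values[[cc]][r, ], phi = 1, mode = 1L,
           left_out = sprintf("s%02d", r))
    })
    matched[[cc]] <- stats::setNames(list(runs), network)
    templates[[cc]] <- stats::setNames(list(rep(1, ncol(values[[cc]]))),
                                       network)
  }
  list(matched = matched, templates = templates)
}
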