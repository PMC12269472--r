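#' Simulation configuration for synthetic source-space recordings
#'
#' Defines the synthetic study: a four-condition design (`first-OFF`,
#' `first-ON`, `second-OFF`, `second-ON`) with unequal usable cohort sizes
#' (defaults 18/18/17/19 drawn from a common pool of 20 subjects), a set of
#' planted networks carrying cross-frequency coupling (low-frequency phase in
#' \[2,30\] Hz gating high-gamma amplitude in \[80,150\] Hz), and optional
#' condition-specific coupling-strength effects in subregions.
#'
#' The per-vertex signal model is
#' \deqn{x(t) = \sin(2\pi f_\phi t + \theta_v) +
#'   \kappa_{eff}\, m(t)\, g(\phi(t)) \sin(2\pi f_a t) + \epsilon(t)}
#' with \eqn{g(\phi) = (1+\cos\phi)/2} gating the fast amplitude by the slow
#' phase, \eqn{m(t)} a slow non-negative envelope (low-pass filtered noise,
#' default cutoff 0.5 Hz) shared by all vertices of a network, \eqn{\theta_v}
#' a random per-vertex phase offset, and \eqn{\epsilon} white noise.
#' \eqn{\kappa_{eff}} is the network's coupling strength `kappa` times any
#' condition multiplier from `effect_regions`. Background vertices carry the
#' slow oscillation and noise only (`kappa = 0`).
#'
#' @param mesh_spec Mesh specification passed to [build_mesh()].
#' @param networks List of planted networks, each
#'   `list(name=, vertices=, f_phase=, f_amp=, kappa=)` with `vertices`
#'   1-based mesh indices, `f_phase` in \[2,30\] Hz, `f_amp` in \[80,150\] Hz.
#'   `NULL` picks three spatially compact disjoint networks via
#'   [default_networks()] with phase frequencies 5/8/12 Hz and amplitude
#'   frequencies 90/110/130 Hz.
#' @param n_subjects Usable cohort size per condition, in the order
#'   first-OFF, first-ON, second-OFF, second-ON.
#' @param kappa Default coupling strength in \[0,1\] for networks that do not
#'   set their own.
#' @param effect_regions List of planted condition effects, each
#'   `list(vertices=, conditions=, multiplier=)`; the multiplier scales kappa
#'   for those vertices in those conditions (default multiplier 1.5).
#' @param envelope_cutoff_hz Low-pass cutoff of the shared network envelope.
#' @param noise_sd Standard deviation of the additive white noise.
#' @param fs Sampling rate in Hz; must exceed twice the highest amplitude
#'   frequency with margin.
#' @param duration_s Recording duration per subject and condition in seconds.
#' @param seed Integer master seed; all randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mesh_spec = list(type = "icosphere", subdiv = 2, radius_mm = 50),
                       networks = NULL,
                       n_subjects = c(`first-OFF` = 18L, `first-ON` = 18L,
                                      `second-OFF` = 17L, `second-ON` = 19L),
                       kappa = 0.9,
                       effect_regions = list(),
                       envelope_cutoff_hz = 0.5,
                       noise_sd = 0.3,
                       fs = 600,
                       duration_s = 120,
                       seed = 1L) {
  mesh <- build_mesh(mesh_spec)
  if (is.null(networks)) {
    networks <- default_networks(mesh)
  }
  for (i in seq_along(networks)) {
    nw <- networks[[i]]
    if (is.null(nw$kappa)) networks[[i]]$kappa <- kappa
    if (is.null(nw$name)) networks[[i]]$name <- paste0("net", i)
    stopifnot(nw$f_phase >= 2, nw$f_phase <= 30,
              nw$f_amp >= 80, nw$f_amp <= 150)
  }
  all_net_v <- unlist(lapply(networks, `[[`, "vertices"))
  if (anyDuplicated(all_net_v)) stop("network vertex sets must be disjoint")
  if (fs <= 2 * max(vapply(networks, `[[`, 0, "f_amp"))) {
    stop("sampling rate too low for the planted amplitude frequencies (aliasing)")
  }
  min_fphi <- min(vapply(networks, `[[`, 0, "f_phase"))
  if (duration_s * min_fphi < 100) {
    stop("duration too short: need at least 100 cycles of the slowest phase frequency")
  }
  n_subjects <- as.integer(n_subjects)
  if (is.null(names(n_subjects)) || !all(nzchar(names(n_subjects)))) {
    names(n_subjects) <- megpac_conditions()
  }
  structure(list(
    mesh_spec = mesh_spec, mesh = mesh, networks = networks,
    n_subjects = n_subjects, kappa = kappa,
    effect_regions = effect_regions,
    envelope_cutoff_hz = envelope_cutoff_hz, noise_sd = noise_sd,
    fs = fs, duration_s = duration_s, seed = as.integer(seed)
  ), class = "sim_config")
}

#' The four recording conditions
#'
#' Medication ON/OFF crossed with recording session (before electrode
#' implantation vs about one year later).
#' @return Character vector of condition labels.
#' @export
megpac_conditions <- function() {
  c("first-OFF", "first-ON", "second-OFF", "second-ON")
}

#' Pick spatially compact disjoint default networks on a mesh
#'
#' Seeds `n_networks` well-separated vertices by farthest-point sampling and
#' grows each network from its seed's nearest neighbours. Network sizes are
#' deliberately heterogeneous (ratios 1.5 / 1.0 / 0.6 around `size`), as real
#' resting-state networks differ in spatial extent; distinct extents also
#' separate the singular values of the group correlation matrix so the
#' spatial modes do not mix under near-degeneracy.
#'
#' @param mesh A `cortical_mesh`.
#' @param n_networks Number of networks (default 3, named SMN / visual /
#'   frontal after the three networks analysed downstream).
#' @param size Base vertices per network; default one sixth of the mesh.
#' @return A list of network definitions as used by [sim_config()].
#' @export
default_networks <- function(mesh, n_networks = 3L,
                             size = max(3L, ceiling(mesh$n_vertices / 6))) {
  d <- mesh_distances(mesh)
  seeds <- .farthest_point_indices(d, n_networks, start = 1L)
  names_default <- c("SMN", "visual", "frontal")
  f_phase <- c(5, 8, 12)
  f_amp <- c(90, 110, 130)
  ratios <- rep_len(c(1.5, 1, 0.6), n_networks)
  taken <- integer(0)
  nets <- vector("list", n_networks)
  for (i in seq_len(n_networks)) {
    ord <- order(d[seeds[i], ])
    ord <- setdiff(ord, taken)
    verts <- sort(ord[seq_len(max(3L, round(size * ratios[i])))])
    taken <- c(taken, verts)
    nets[[i]] <- list(
      name = if (i <= 3L) names_default[i] else paste0("net", i),
      vertices = verts,
      f_phase = f_phase[((i - 1L) %% 3L) + 1L],
      f_amp = f_amp[((i - 1L) %% 3L) + 1L]
    )
  }
  nets
}

# Deterministic sub-seed per (subject, condition); kept below 2^31.
.recording_seed <- function(seed, subject_idx, condition_idx) {
  as.integer((as.numeric(seed) * 100003 + subject_idx * 1009 +
                condition_idx * 101) %% 2147483629)
}

# Slow non-negative envelope shared by one network: low-pass filtered white
# noise (frequency-domain brick wall), unit-sd standardized, m = max(0, 1+0.4z).
.slow_envelope <- function(n, fs, cutoff_hz) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  freqs <- .fft_freqs(n, fs)
  Z[abs(freqs) > cutoff_hz] <- 0
  z <- Re(stats::fft(Z, inverse = TRUE)) / n
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  pmax(0, 1 + 0.4 * z)
}

.fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

#' Simulate one subject-by-condition source recording
#'
#' @param config A [sim_config()].
#' @param subject_id Subject label (e.g. `"s03"`).
#' @param condition One of [megpac_conditions()].
#' @param seed Integer seed for this recording; [generate_group()] derives one
#'   deterministically per (subject, condition).
#' @return A list with elements `recording` (class `source_recording`:
#'   `data` vertices x samples, `fs`, `subject_id`, `condition`) and `truth`
#'   (class `ground_truth`: per-vertex `network_label` (0 = background),
#'   `f_phase`, `f_amp`, and `kappa_eff` actually applied).
#' @export
simulate_recording <- function(config, subject_id, condition, seed) {
  stopifnot(inherits(config, "sim_config"),
            condition %in% megpac_conditions())
  mesh <- config$mesh
  nv <- mesh$n_vertices
  n <- round(config$duration_s * config$fs)
  t <- (0:(n - 1)) / config$fs
  set.seed(as.integer(seed))

  network_label <- integer(nv)
  f_phase <- stats::runif(nv, 2, 30)   # background slow frequency per vertex
  f_amp <- rep(NA_real_, nv)
  kappa_eff <- numeric(nv)
  theta <- stats::runif(nv, 0, 2 * pi)

  mult <- rep(1, nv)
  for (er in config$effect_regions) {
    if (condition %in% er$conditions) {
      m <- if (is.null(er$multiplier)) 1.5 else er$multiplier
      mult[er$vertices] <- mult[er$vertices] * m
    }
  }

  data <- matrix(0, nv, n)
  for (k in seq_along(config$networks)) {
    nw <- config$networks[[k]]
    env <- .slow_envelope(n, config$fs, config$envelope_cutoff_hz)
    for (v in nw$vertices) {
      network_label[v] <- k
      f_phase[v] <- nw$f_phase
      f_amp[v] <- nw$f_amp
      base_kappa <- if (is.null(nw$vertex_kappa)) nw$kappa else nw$vertex_kappa[match(v, nw$vertices)]
      kappa_eff[v] <- min(1, base_kappa * mult[v])
      phi <- 2 * pi * nw$f_phase * t + theta[v]
      g <- (1 + cos(phi)) / 2
      data[v, ] <- sin(phi) +
        kappa_eff[v] * env * g * sin(2 * pi * nw$f_amp * t)
    }
  }
  bg <- which(network_label == 0L)
  for (v in bg) {
    data[v, ] <- sin(2 * pi * f_phase[v] * t + theta[v])
  }
  if (config$noise_sd > 0) {
    data <- data + matrix(stats::rnorm(nv * n, sd = config$noise_sd), nv, n)
  }

  recording <- structure(list(
    subject_id = subject_id, condition = condition,
    data = data, fs = config$fs
  ), class = "source_recording")
  truth <- structure(list(
    network_label = network_label,
    network_names = vapply(config$networks, `[[`, "", "name"),
    f_phase = f_phase, f_amp = f_amp, kappa_eff = kappa_eff,
    condition_multiplier = mult
  ), class = "ground_truth")
  list(recording = recording, truth = truth)
}

#' Generate the full four-condition synthetic group
#'
#' Emulates the study design: a pool of subjects (size `max(n_subjects) + 1`,
#' i.e. 20 at the defaults) from which each condition loses a distinct random
#' subset to reach its usable cohort size, so the per-condition subject sets
#' differ and paired tests are not possible.
#'
#' @param config A [sim_config()].
#' @return A list with `recordings` (list of `source_recording`), `truths`
#'   (ground truth per recording), `mesh`, `config`, and `cohorts` (subject
#'   ids per condition).
#' @export
generate_group <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  conds <- megpac_conditions()
  pool_n <- max(config$n_subjects) + 1L
  pool <- sprintf("s%02d", seq_len(pool_n))
  set.seed(config$seed)
  cohorts <- list()
  for (ci in seq_along(conds)) {
    drop_n <- pool_n - config$n_subjects[ci]
    dropped <- sample(pool_n, drop_n)
    cohorts[[conds[ci]]] <- pool[setdiff(seq_len(pool_n), dropped)]
  }
  recordings <- list()
  truths <- list()
  for (ci in seq_along(conds)) {
    for (sid in cohorts[[conds[ci]]]) {
      si <- match(sid, pool)
      rs <- .recording_seed(config$seed, si, ci)
      out <- simulate_recording(config, sid, conds[ci], seed = rs)
      key <- paste(sid, conds[ci], sep = "_")
      recordings[[key]] <- out$recording
      truths[[key]] <- out$truth
    }
  }
  list(recordings = recordings, truths = truths,
       mesh = config$mesh, config = config, cohorts = cohorts)
}

#' Ground-truth binary network maps
#'
#' @param truth A `ground_truth` (any recording's; labels are shared).
#' @return A list of 0/1 vertex vectors, one per planted network.
#' @export
true_network_maps <- function(truth) {
  ks <- seq_along(truth$network_names)
  maps <- lapply(ks, function(k) as.numeric(truth$network_label == k))
  names(maps) <- truth$network_names
  maps
}

#' Desk-scale study configuration
#'
#' A reduced version of the default study that preserves its structure --
#' four conditions with cohort sizes 18/18/17/19, three planted networks at
#' 5/8/12 Hz phase and 90/110/130 Hz amplitude frequencies -- on a 42-vertex
#' icosphere with 20 s recordings at 400 Hz and a correspondingly reduced
#' search grid (phase 3-14 Hz in 1 Hz steps; amplitude cells at the three
#' planted carrier frequencies, since amplitude-frequency resolution is not
#' under study at this scale). Used by the examples and the package's
#' simulation studies so the
#' whole pipeline runs in minutes on one core.
#'
#' With `effect = TRUE`, a four-vertex subregion of the SMN is planted with a
#' 1.5x coupling multiplier in the second-session conditions. The subregion's
#' baseline coupling is set below the network's (0.55 vs 0.9) so that even
#' after the boost its coupling stays below the network peak: the maps are
#' normalized by their maximum, so an effect that moved the peak itself would
#' show up over the whole network rather than in the planted subregion.
#'
#' @param seed Master simulation seed.
#' @param effect Plant the second-session coupling effect (default FALSE).
#' @param n_subjects Cohort sizes (default 18/18/17/19).
#' @return List with `sim` (a [sim_config()]), `pipe` (a
#'   [pipeline_config()]), and `effect_vertices` (integer vector, empty when
#'   `effect = FALSE`).
#' @export
reduced_study_config <- function(seed = 1L, effect = FALSE,
                                 n_subjects = c(18L, 18L, 17L, 19L)) {
  mesh <- build_mesh(list(type = "icosphere", subdiv = 1, radius_mm = 50))
  nets <- default_networks(mesh)
  effect_vertices <- integer(0)
  effect_regions <- list()
  if (effect) {
    v1 <- nets[[1]]$vertices
    centroid <- colMeans(mesh$vertex_coords[v1, , drop = FALSE])
    d <- sqrt(colSums((t(mesh$vertex_coords[v1, ]) - centroid)^2))
    effect_vertices <- sort(v1[order(-d)][1:4])
    nets[[1]]$vertex_kappa <- ifelse(v1 %in% effect_vertices, 0.55, 0.9)
    effect_regions <- list(list(vertices = effect_vertices,
                                conditions = c("second-OFF", "second-ON"),
                                multiplier = 1.5))
  }
  sim <- sim_config(
    mesh_spec = list(type = "icosphere", subdiv = 1, radius_mm = 50),
    networks = nets, n_subjects = n_subjects, kappa = 0.9,
    effect_regions = effect_regions,
    envelope_cutoff_hz = 0.5, noise_sd = 0.3,
    fs = 400, duration_s = 20, seed = seed
  )
  pipe <- pipeline_config(
    grid = pac_grid(phase_freqs = 3:14, amp_freqs = c(90, 110, 130)),
    seed = seed
  )
  list(sim = sim, pipe = pipe, effect_vertices = effect_vertices)
}
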