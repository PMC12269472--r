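#' Pipeline configuration
#'
#' Bundles the analysis constants: the PAC search grid, 7 mm smoothing FWHM,
#' 10 spatial modes, the 40% relative threshold, the 10 Hz megPAC rate, the
#' even-subset size, the sign convention at extrema, and the jackknife
#' variance correction switch.
#'
#' @param grid A [pac_grid()].
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 7).
#' @param n_modes Number of spatial modes (default 10).
#' @param rel_threshold Relative binarization threshold (default 0.4).
#' @param megpac_rate megPAC output rate in Hz (default 10).
#' @param subset_k Even-subset size; `NULL` means `min(n_vertices, 1000)`.
#' @param signed_extrema Sign convention at extrema: `TRUE` samples the
#'   high-gamma amplitude with + at maxima and - at minima, `FALSE` (the
#'   default) keeps the raw amplitude. With per-vertex oscillatory phases the
#'   signed series carries a zero-mean carrier at an arbitrary phase offset,
#'   which suppresses within-network correlations; the unsigned series keeps
#'   the shared slow envelope and is the default here.
#' @param jackknife_correction Jackknife variance correction switch
#'   (default TRUE).
#' @param seed Seed recorded in the manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid = pac_grid(), fwhm_mm = 7, n_modes = 10L,
                            rel_threshold = 0.4, megpac_rate = 10,
                            subset_k = NULL, signed_extrema = FALSE,
                            jackknife_correction = TRUE, seed = 1L) {
  structure(list(
    grid = grid, fwhm_mm = fwhm_mm, n_modes = as.integer(n_modes),
    rel_threshold = rel_threshold, megpac_rate = megpac_rate,
    subset_k = subset_k, signed_extrema = signed_extrema,
    jackknife_correction = jackknife_correction, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Process one source recording into smoothed megPAC series and a PAC map
#'
#' Runs the subject-level chain: per-vertex maximum-PAC search over the grid,
#' megPAC synthesis at each vertex's maximum-coupling pair, resampling to the
#' megPAC rate, and Gaussian surface smoothing.
#'
#' @param recording A `source_recording`.
#' @param mesh The analysis `cortical_mesh`.
#' @param cfg A [pipeline_config()].
#' @param smoother Optional precomputed [smoothing_weights()] matrix.
#' @return List with `megpac` (smoothed vertices x samples matrix at
#'   `megpac_rate`), `pacmap`, `subject_id`, `condition`.
#' @export
process_recording <- function(recording, mesh, cfg = pipeline_config(),
                              smoother = NULL) {
  stopifnot(inherits(recording, "source_recording"))
  if (nrow(recording$data) != mesh$n_vertices) {
    stop("recording vertex count does not match the mesh")
  }
  pm <- pac_map(recording$data, recording$fs, cfg$grid)
  mp <- megpac_matrix(recording$data, pm, recording$fs,
                      rate = cfg$megpac_rate, signed = cfg$signed_extrema)
  if (is.null(smoother)) smoother <- smoothing_weights(mesh, cfg$fwhm_mm)
  list(megpac = smoother %*% mp, pacmap = pm,
       subject_id = recording$subject_id, condition = recording$condition)
}

#' Run the full analysis pipeline on a synthetic group
#'
#' Executes the whole chain on the output of [generate_group()]: subject-level
#' megPAC processing, per-condition full-cohort template networks (named by
#' matching the extracted modes to reference maps), jackknife leave-one-out
#' ensembles with template matching, vertex-wise two-factor ANOVA with FDR,
#' overlap tests against external templates, and the low-frequency-component
#' three-factor ANOVA. Deterministic for a fixed simulation seed.
#'
#' @param group Output of [generate_group()].
#' @param cfg A [pipeline_config()].
#' @param reference_maps Named list of per-vertex maps used to identify and
#'   name the analysed networks among the 10 modes; defaults to the
#'   simulation's ground-truth network maps.
#' @param hc_templates Named list of external (healthy-control) template
#'   maps for the overlap analysis; defaults to `reference_maps`.
#' @param out_dir Optional directory for CSV/JSON stage outputs and the run
#'   manifest.
#' @param stages Character vector of statistics stages to run, any of
#'   `"vertex_anova"`, `"hc_overlap"`, `"lowfreq"`.
#' @return A list with `templates`, `ensembles`, `matched`, `vertex_stats`,
#'   `overlap`, `lowfreq`, `processed`, `plan`, `cfg`, and `manifest`.
#' @export
run_pipeline <- function(group, cfg = pipeline_config(),
                         reference_maps = NULL, hc_templates = NULL,
                         out_dir = NULL,
                         stages = c("vertex_anova", "hc_overlap", "lowfreq")) {
  t0 <- proc.time()[["elapsed"]]
  mesh <- group$mesh
  conds <- megpac_conditions()
  if (is.null(reference_maps)) {
    reference_maps <- true_network_maps(group$truths[[1L]])
  }
  if (is.null(hc_templates)) hc_templates <- reference_maps
  nets <- names(reference_maps)
  k <- if (is.null(cfg$subset_k)) min(mesh$n_vertices, 1000L) else cfg$subset_k
  plan <- if (k >= mesh$n_vertices) NULL else select_even_subset(mesh, k)
  smoother <- smoothing_weights(mesh, cfg$fwhm_mm)
  timings <- c()

  processed <- list()
  pacmaps <- list()
  for (cc in conds) {
    processed[[cc]] <- list()
    pacmaps[[cc]] <- list()
    for (sid in group$cohorts[[cc]]) {
      key <- paste(sid, cc, sep = "_")
      pr <- process_recording(group$recordings[[key]], mesh, cfg, smoother)
      processed[[cc]][[sid]] <- pr
      pacmaps[[cc]][[sid]] <- pr$pacmap
    }
  }
  timings["subject_processing"] <- proc.time()[["elapsed"]] - t0

  # per-condition full-cohort RSNs; name networks via the reference maps
  templates <- list()
  full_rsns <- list()
  for (cc in conds) {
    rs <- extract_rsns(lapply(processed[[cc]], `[[`, "megpac"), plan,
                       cfg$n_modes)
    full_rsns[[cc]] <- rs
    templates[[cc]] <- list()
    for (nk in nets) {
      m <- match_to_template(rs, reference_maps[[nk]], cfg$rel_threshold)
      if (!m$valid) stop("no valid template match for network ", nk,
                         " in condition ", cc)
      templates[[cc]][[nk]] <- m$map
    }
  }

  ensembles <- list()
  matched <- list()
  for (cc in conds) {
    ens <- run_jackknife(processed[[cc]], plan, cfg$n_modes)
    ensembles[[cc]] <- ens
    matched[[cc]] <- list()
    for (nk in nets) {
      matched[[cc]][[nk]] <- lapply(ens$runs, function(run) {
        m <- match_to_template(run$rsns, templates[[cc]][[nk]],
                               cfg$rel_threshold)
        m$left_out <- run$left_out
        m
      })
    }
  }
  timings["rsn_jackknife"] <- proc.time()[["elapsed"]] - t0 - sum(timings)

  vs <- NULL
  if ("vertex_anova" %in% stages) {
    vs <- vertex_anova(matched, templates, cfg$rel_threshold,
                       cfg$jackknife_correction)
  }
  ov <- NULL
  if ("hc_overlap" %in% stages) {
    ov <- hc_overlap(matched, hc_templates, cfg$rel_threshold,
                     cfg$jackknife_correction)
  }
  lf <- NULL
  if ("lowfreq" %in% stages) {
    lf <- lowfreq_anova(pacmaps, matched, ensembles, cfg$rel_threshold,
                        cfg$jackknife_correction)
  }
  timings["statistics"] <- proc.time()[["elapsed"]] - t0 - sum(timings)

  manifest <- list(
    package_version = as.character(utils::packageVersion("megpacr")),
    seed = group$config$seed,
    n_vertices = mesh$n_vertices,
    cohort_sizes = vapply(group$cohorts, length, 1L),
    config = list(
      fwhm_mm = cfg$fwhm_mm, n_modes = cfg$n_modes,
      rel_threshold = cfg$rel_threshold, megpac_rate = cfg$megpac_rate,
      subset_k = k, signed_extrema = cfg$signed_extrema,
      jackknife_correction = cfg$jackknife_correction,
      phase_freqs = cfg$grid$phase_freqs, amp_freqs = cfg$grid$amp_freqs
    ),
    timings_s = as.list(round(timings, 2))
  )

  result <- list(templates = templates, full_rsns = full_rsns,
                 ensembles = ensembles, matched = matched,
                 vertex_stats = vs, overlap = ov, lowfreq = lf,
                 processed = processed, pacmaps = pacmaps,
                 plan = plan, cfg = cfg, manifest = manifest)
  if (!is.null(out_dir)) export_results(result, out_dir)
  result
}

#' Export pipeline results as CSV tables and a JSON manifest
#'
#' @param result Output of [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
export_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (cc in names(result$templates)) {
    for (nk in names(result$templates[[cc]])) {
      df <- data.frame(vertex_id = seq_along(result$templates[[cc]][[nk]]) - 1L,
                       value = result$templates[[cc]][[nk]])
      utils::write.csv(df, file.path(out_dir,
        sprintf("template_%s_%s.csv", gsub("[^A-Za-z0-9]", "", cc), nk)),
        row.names = FALSE)
    }
  }
  if (!is.null(result$vertex_stats)) {
    ph <- do.call(rbind, lapply(result$vertex_stats$networks, `[[`, "posthoc"))
    utils::write.csv(ph, file.path(out_dir, "vertex_posthoc.csv"),
                     row.names = FALSE)
    an <- do.call(rbind, lapply(names(result$vertex_stats$networks), function(k) {
      cbind(network = k, result$vertex_stats$networks[[k]]$anova)
    }))
    utils::write.csv(an, file.path(out_dir, "vertex_anova.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$overlap)) {
    utils::write.csv(result$overlap$phi, file.path(out_dir, "overlap_phi.csv"),
                     row.names = FALSE)
    utils::write.csv(result$overlap$tests,
                     file.path(out_dir, "overlap_tests.csv"), row.names = FALSE)
  }
  if (!is.null(result$lowfreq)) {
    utils::write.csv(result$lowfreq$medians,
                     file.path(out_dir, "lowfreq_medians.csv"), row.names = FALSE)
    utils::write.csv(result$lowfreq$anova,
                     file.path(out_dir, "lowfreq_anova.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}
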