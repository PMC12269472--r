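#' Write / read a group of source recordings in a directory container
#'
#' Recordings are stored hierarchically: one subdirectory per
#' subject-by-condition group, each holding an `attrs.json` attribute file
#' (`subject_id`, `condition`, `fs`, `n_vertices`, `n_samples`) and the data
#' matrix as little-endian float64 (`data.bin`, row-major by vertex). The
#' round trip is exact.
#'
#' @param recordings List of `source_recording` objects.
#' @param path Container directory (created if missing).
#' @return `write_recordings` returns `path` invisibly; `read_recordings`
#'   returns a named list of `source_recording`s.
#' @export
write_recordings <- function(recordings, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (rec in recordings) {
    gname <- paste(rec$subject_id, rec$condition, sep = "_")
    gdir <- file.path(path, gname)
    dir.create(gdir, showWarnings = FALSE)
    jsonlite::write_json(list(
      subject_id = rec$subject_id, condition = rec$condition,
      fs = rec$fs, n_vertices = nrow(rec$data), n_samples = ncol(rec$data),
      vertex_indexing = "0-based"
    ), file.path(gdir, "attrs.json"), auto_unbox = TRUE, digits = NA)
    con <- file(file.path(gdir, "data.bin"), "wb")
    writeBin(as.numeric(t(rec$data)), con, size = 8L, endian = "little")
    close(con)
  }
  invisible(path)
}

#' @rdname write_recordings
#' @param mesh Optional `cortical_mesh`; if given, each recording's vertex
#'   count is validated against it.
#' @export
read_recordings <- function(path, mesh = NULL) {
  groups <- list.dirs(path, recursive = FALSE)
  if (!length(groups)) stop("no recording groups found under ", path)
  out <- list()
  for (gdir in groups) {
    afile <- file.path(gdir, "attrs.json")
    if (!file.exists(afile)) {
      stop("group ", basename(gdir), ": missing attrs.json")
    }
    at <- jsonlite::read_json(afile, simplifyVector = TRUE)
    for (req in c("subject_id", "condition", "fs", "n_vertices", "n_samples")) {
      if (is.null(at[[req]])) {
        stop("group ", basename(gdir), ": missing attribute '", req, "'")
      }
    }
    con <- file(file.path(gdir, "data.bin"), "rb")
    vals <- readBin(con, "numeric", at$n_vertices * at$n_samples,
                    size = 8L, endian = "little")
    close(con)
    data <- matrix(vals, at$n_vertices, at$n_samples, byrow = TRUE)
    if (!all(is.finite(data))) {
      stop("group ", basename(gdir), ": non-finite values in data")
    }
    if (!is.null(mesh) && at$n_vertices != mesh$n_vertices) {
      stop("group ", basename(gdir), ": vertex count ", at$n_vertices,
           " does not match mesh (", mesh$n_vertices, ")")
    }
    out[[basename(gdir)]] <- structure(list(
      subject_id = at$subject_id, condition = at$condition,
      data = data, fs = as.numeric(at$fs)
    ), class = "source_recording")
  }
  out
}

#' Export a PAC map as a per-vertex CSV table
#'
#' Columns: `vertex_id` (0-based), `f_phase`, `f_amp`, `pac`.
#'
#' @param pacmap A `pac_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pac_map <- function(pacmap, path) {
  df <- data.frame(vertex_id = pacmap$vertex - 1L, f_phase = pacmap$f_phase,
                   f_amp = pacmap$f_amp, pac = pacmap$pac)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export RSN maps as per-vertex CSV overlay tables
#'
#' Writes one `vertex_id` (0-based) / `value` table per mode, consumable by
#' standard surface viewers.
#'
#' @param rsns An `rsn_set`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_rsn_maps <- function(rsns, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in seq_len(rsns$n_modes)) {
    df <- data.frame(vertex_id = seq_len(ncol(rsns$modes)) - 1L,
                     value = rsns$modes[m, ])
    utils::write.csv(df, file.path(dir, sprintf("mode_%02d.csv", m)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unset keys fall back to the analysis defaults (10 Hz megPAC rate, 7 mm
#' FWHM, 10 modes, 40% threshold, phase grid 2-30 Hz, amplitude grid
#' 80-150 Hz).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  grid_args <- list()
  if (!is.null(y$phase_freqs)) grid_args$phase_freqs <- y$phase_freqs
  if (!is.null(y$amp_freqs)) grid_args$amp_freqs <- y$amp_freqs
  grid <- do.call(pac_grid, grid_args)
  defaults <- pipeline_config(grid = grid)
  for (key in c("fwhm_mm", "n_modes", "rel_threshold", "megpac_rate",
                "subset_k", "signed_extrema", "jackknife_correction", "seed")) {
    if (!is.null(y[[key]])) defaults[[key]] <- y[[key]]
  }
  defaults
}
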