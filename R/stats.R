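#' Binarize a coupling-strength map at a fraction of its maximum
#'
#' @param map Non-negative per-vertex map.
#' @param rel_threshold Fraction of the map maximum (default 0.4); a vertex is
#'   included iff its value is >= `rel_threshold * max(map)` (boundary
#'   inclusive).
#' @return An object of class `binary_map`: list with `members` (logical
#'   vector) and `threshold_used`.
#' @export
binarize_map <- function(map, rel_threshold = 0.4) {
  mx <- max(map)
  if (mx <= 0) stop("cannot binarize an all-zero map")
  structure(list(
    members = map >= rel_threshold * mx,
    threshold_used = rel_threshold
  ), class = "binary_map")
}

#' Phi coefficient between two binary maps
#'
#' The phi coefficient of the 2x2 vertex-membership table,
#' \deqn{\phi = \frac{n_{11} n_{00} - n_{10} n_{01}}
#'   {\sqrt{(n_{11}+n_{10})(n_{01}+n_{00})(n_{11}+n_{01})(n_{10}+n_{00})}}}
#' which equals the Pearson correlation of the two 0/1 vectors. A degenerate
#' table (any zero marginal) returns 0 with a warning so that jackknife
#' aggregation never silently drops runs.
#'
#' @param a,b `binary_map`s (or logical/0-1 vectors) on the same mesh.
#' @return Value in \[-1,1\].
#' @export
phi_coefficient <- function(a, b) {
  av <- if (inherits(a, "binary_map")) a$members else as.logical(a)
  bv <- if (inherits(b, "binary_map")) b$members else as.logical(b)
  if (length(av) != length(bv)) stop("maps have different vertex counts")
  n11 <- sum(av & bv)
  n10 <- sum(av & !bv)
  n01 <- sum(!av & bv)
  n00 <- sum(!av & !bv)
  den2 <- (n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00)
  if (den2 == 0) {
    warning("degenerate 2x2 table in phi coefficient; returning 0")
    return(0)
  }
  (n11 * n00 - n10 * n01) / sqrt(den2)
}

#' Welch two-sample t-test with jackknife variance inflation
#'
#' The unequal-variance t-test with optional per-group variance inflation
#' factors. Leave-one-out jackknife run values under-disperse relative to
#' between-subject variability by a factor (N-1)^2, so tests on jackknife
#' ensembles multiply each group's standard error by its `inflate` = N-1;
#' `inflate = 1` recovers the ordinary Welch test.
#'
#' @param x,y Numeric samples.
#' @param inflate_x,inflate_y Standard-error inflation factors.
#' @return List with `t`, `df`, `p` (two-tailed), `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y, inflate_x = 1, inflate_y = 1) {
  nx <- length(x); ny <- length(y)
  vx <- inflate_x^2 * stats::var(x) / nx
  vy <- inflate_y^2 * stats::var(y) / ny
  se2 <- vx + vy
  if (se2 == 0) {
    d <- mean(x) - mean(y)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = nx + ny - 2, p = if (d == 0) 1 else 0,
                mean_x = mean(x), mean_y = mean(y)))
  }
  tval <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       mean_x = mean(x), mean_y = mean(y))
}

#' Match an RSN set to a template map
#'
#' Binarizes the template and every mode map at `rel_threshold` of their
#' maxima and returns the mode with the highest phi coefficient (ties broken
#' toward the lowest mode index). If every mode yields a degenerate table the
#' match is flagged invalid.
#'
#' @param rsns An `rsn_set`.
#' @param template Per-vertex template map (continuous or 0/1).
#' @param rel_threshold Binarization threshold (default 0.4).
#' @return List with `mode` (index), `phi`, `map` (the matched continuous
#'   map), and `valid`.
#' @export
match_to_template <- function(rsns, template, rel_threshold = 0.4) {
  tb <- binarize_map(template, rel_threshold)
  phis <- numeric(rsns$n_modes)
  degenerate <- logical(rsns$n_modes)
  for (m in seq_len(rsns$n_modes)) {
    mb <- binarize_map(rsns$modes[m, ], rel_threshold)
    phis[m] <- withCallingHandlers(
      phi_coefficient(mb, tb),
      warning = function(w) {
        degenerate[m] <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
  }
  if (all(degenerate)) {
    return(list(mode = NA_integer_, phi = NA_real_, map = NULL, valid = FALSE))
  }
  best <- which.max(phis)   # first maximum = lowest mode index on ties
  list(mode = best, phi = phis[best], map = rsns$modes[best, ], valid = TRUE)
}

#' Jackknife leave-one-out RSN ensemble for one condition
#'
#' Re-runs the network extraction once per subject, omitting that subject's
#' (already computed) megPAC series; with N subjects this yields N RSN sets.
#' The per-subject megPAC processing is unaffected by which other subjects
#' are present, so it is computed once and reused across runs.
#'
#' @param processed List of per-subject processed recordings (elements with a
#'   `megpac` matrix), as produced by [process_recording()]; names are
#'   subject ids.
#' @param plan A `reduction_plan` (or `NULL` for all vertices).
#' @param n_modes Number of modes per run.
#' @return An object of class `jackknife_ensemble`: list with `runs` (each
#'   `list(left_out=, rsns=)`) and `n_runs`.
#' @export
run_jackknife <- function(processed, plan = NULL, n_modes = 10L) {
  n <- length(processed)
  if (n < 2L) stop("jackknife needs at least 2 subjects")
  sids <- names(processed)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- processed[-i]
    runs[[i]] <- list(
      left_out = sids[i],
      rsns = extract_rsns(lapply(keep, `[[`, "megpac"), plan, n_modes)
    )
  }
  structure(list(runs = runs, n_runs = n), class = "jackknife_ensemble")
}

# contrasts of interest: OFF vs ON within each session, first vs second
# within each medication state
.posthoc_contrasts <- function() {
  list(
    `first: OFF vs ON`   = c("first-OFF", "first-ON"),
    `second: OFF vs ON`  = c("second-OFF", "second-ON"),
    `OFF: first vs second` = c("first-OFF", "second-OFF"),
    `ON: first vs second`  = c("first-ON", "second-ON")
  )
}

.cond_factors <- function(cond) {
  list(
    medication = ifelse(grepl("ON$", cond), "ON", "OFF"),
    session = ifelse(grepl("^first", cond), "first", "second")
  )
}

#' Vertex-wise two-factor ANOVA with FDR-controlled post-hoc tests
#'
#' For each analysed network, vertices reaching 40% of the maximum coupling
#' strength in at least one condition's template enter a per-vertex two-way
#' ANOVA (factors medication ON/OFF and recording session first/second,
#' unbalanced Type II sums of squares) on the jackknife coupling strengths,
#' followed by two-tailed unequal-variance (Welch) post-hoc tests on the four
#' contrasts of interest. Post-hoc p-values are corrected by
#' Benjamini-Hochberg FDR in a single family across vertices, networks and
#' contrasts. With `jackknife_correction = TRUE`, standard errors are
#' inflated by (N-1) per group (F divided by (N-1)^2, with N-1 averaged over
#' the four cohorts) to undo the under-dispersion of leave-one-out runs.
#'
#' @param matched Nested list `matched[[condition]][[network]]`, each a list
#'   of runs with elements `map` (matched jackknife map) and `phi`.
#' @param templates Nested list `templates[[condition]][[network]]` of
#'   condition-level template maps (used for vertex inclusion).
#' @param rel_threshold Inclusion/binarization threshold (default 0.4).
#' @param jackknife_correction Apply the (N-1) variance correction.
#' @param q FDR level (default 0.05).
#' @return A list per network with `included` (logical vertex mask), `anova`
#'   (per-vertex F and p per effect) and `posthoc` (long data.frame with t,
#'   df, p, p_fdr, sig per vertex x contrast).
#' @export
vertex_anova <- function(matched, templates, rel_threshold = 0.4,
                         jackknife_correction = TRUE, q = 0.05) {
  conds <- megpac_conditions()
  if (!all(conds %in% names(matched))) stop("all four conditions are required")
  nets <- names(matched[[1L]])
  nv <- length(templates[[1L]][[1L]])
  ns <- vapply(conds, function(cc) length(matched[[cc]][[1L]]), 1L)
  infl <- if (jackknife_correction) ns - 1 else rep(1, 4)
  names(infl) <- conds
  f_corr <- if (jackknife_correction) (mean(ns) - 1)^2 else 1

  out <- list()
  all_p <- list()
  for (k in nets) {
    inc <- rep(FALSE, nv)
    for (cc in conds) {
      inc <- inc | binarize_map(templates[[cc]][[k]], rel_threshold)$members
    }
    vals <- lapply(conds, function(cc) {
      do.call(rbind, lapply(matched[[cc]][[k]], `[[`, "map"))
    })
    names(vals) <- conds
    vidx <- which(inc)
    an <- data.frame(vertex = vidx,
                     F_medication = NA_real_, p_medication = NA_real_,
                     F_session = NA_real_, p_session = NA_real_,
                     F_interaction = NA_real_, p_interaction = NA_real_)
    ph <- list()
    for (j in seq_along(vidx)) {
      v <- vidx[j]
      y <- unlist(lapply(conds, function(cc) vals[[cc]][, v]))
      cond_rep <- rep(conds, times = ns)
      fac <- .cond_factors(cond_rep)
      if (stats::sd(y) == 0) next  # zero variance everywhere: skip
      fit <- stats::lm(y ~ med * sess,
                       data = data.frame(y = y, med = factor(fac$medication),
                                         sess = factor(fac$session)))
      a2 <- car::Anova(fit, type = 2)
      Fv <- a2[c("med", "sess", "med:sess"), "F value"] / f_corr
      dfs <- a2[c("med", "sess", "med:sess"), "Df"]
      dfr <- a2["Residuals", "Df"]
      pv <- stats::pf(Fv, dfs, dfr, lower.tail = FALSE)
      an[j, 2:7] <- c(Fv[1], pv[1], Fv[2], pv[2], Fv[3], pv[3])
      for (cn in names(.posthoc_contrasts())) {
        pair <- .posthoc_contrasts()[[cn]]
        wt <- welch_t(vals[[pair[1]]][, v], vals[[pair[2]]][, v],
                      inflate_x = infl[pair[1]], inflate_y = infl[pair[2]])
        ph[[length(ph) + 1L]] <- data.frame(
          network = k, vertex = v, contrast = cn,
          t = wt$t, df = wt$df, p = wt$p,
          diff = wt$mean_x - wt$mean_y
        )
      }
    }
    ph <- if (length(ph)) do.call(rbind, ph) else
      data.frame(network = character(0), vertex = integer(0),
                 contrast = character(0), t = numeric(0), df = numeric(0),
                 p = numeric(0), diff = numeric(0))
    out[[k]] <- list(included = inc, anova = an, posthoc = ph)
    all_p[[k]] <- ph$p
  }
  # one BH family across vertices x networks x contrasts
  pvec <- unlist(all_p, use.names = FALSE)
  padj <- stats::p.adjust(pvec, method = "BH")
  off <- 0L
  for (k in nets) {
    npk <- nrow(out[[k]]$posthoc)
    if (npk > 0L) {
      out[[k]]$posthoc$p_fdr <- padj[off + seq_len(npk)]
      out[[k]]$posthoc$sig <- out[[k]]$posthoc$p_fdr < q
      off <- off + npk
    } else {
      out[[k]]$posthoc$p_fdr <- numeric(0)
      out[[k]]$posthoc$sig <- logical(0)
    }
  }
  structure(list(networks = out, q = q,
                 jackknife_correction = jackknife_correction),
            class = "vertex_stats")
}

#' Overlap of jackknife networks with external (healthy-control) templates
#'
#' Computes the phi coefficient (after thresholding both maps at 40% of
#' their maxima) between each jackknife run's matched map and an external
#' template per network, then compares the four conditions pairwise with
#' two-tailed Welch t-tests, Bonferroni-corrected over the 6 condition pairs
#' x number of networks.
#'
#' @param matched As in [vertex_anova()].
#' @param hc_templates Named list of per-vertex template maps, one per
#'   network.
#' @param rel_threshold Threshold (default 0.4).
#' @param jackknife_correction Apply the (N-1) standard-error inflation.
#' @return List with `phi` (long data.frame: network, condition, run, phi),
#'   `summary` (mean and sd per network x condition) and `tests` (pairwise t,
#'   df, p, p_bonf).
#' @export
hc_overlap <- function(matched, hc_templates, rel_threshold = 0.4,
                       jackknife_correction = TRUE) {
  conds <- megpac_conditions()
  nets <- names(hc_templates)
  ns <- vapply(conds, function(cc) length(matched[[cc]][[1L]]), 1L)
  infl <- if (jackknife_correction) ns - 1 else rep(1, 4)
  names(infl) <- conds
  rows <- list()
  for (k in nets) {
    tb <- binarize_map(hc_templates[[k]], rel_threshold)
    for (cc in conds) {
      runs <- matched[[cc]][[k]]
      for (r in seq_along(runs)) {
        mb <- binarize_map(runs[[r]]$map, rel_threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          network = k, condition = cc, run = r,
          phi = phi_coefficient(mb, tb)
        )
      }
    }
  }
  phi_df <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(nets, function(k) {
    do.call(rbind, lapply(conds, function(cc) {
      x <- phi_df$phi[phi_df$network == k & phi_df$condition == cc]
      data.frame(network = k, condition = cc, n = length(x),
                 mean = mean(x), sd = stats::sd(x))
    }))
  }))
  pairs <- utils::combn(conds, 2L)
  tests <- list()
  for (k in nets) {
    for (j in seq_len(ncol(pairs))) {
      c1 <- pairs[1, j]; c2 <- pairs[2, j]
      x <- phi_df$phi[phi_df$network == k & phi_df$condition == c1]
      y <- phi_df$phi[phi_df$network == k & phi_df$condition == c2]
      wt <- welch_t(x, y, inflate_x = infl[c1], inflate_y = infl[c2])
      tests[[length(tests) + 1L]] <- data.frame(
        network = k, condition_1 = c1, condition_2 = c2,
        t = wt$t, df = wt$df, p = wt$p
      )
    }
  }
  tests <- do.call(rbind, tests)
  tests$p_bonf <- pmin(1, tests$p * nrow(tests))
  list(phi = phi_df, summary = summ, tests = tests)
}

#' Three-factor ANOVA of the maximum-coupling low-frequency component
#'
#' For every jackknife run, the group-level per-vertex phase frequency is the
#' median of the included subjects' maximum-coupling phase frequencies; the
#' run's value for a network is the median of that map over the network's
#' 40%-thresholded matched map. A three-way ANOVA (network x medication x
#' session, all interactions, Type II) is fitted to these medians, with
#' partial eta squared \eqn{SS_{effect}/(SS_{effect}+SS_{error})} per effect
#' and Bonferroni-corrected pairwise post-hoc tests for significant effects.
#'
#' @param pacmaps_by_cond Nested list `pacmaps[[condition]][[subject]]`, each
#'   a `pac_map` data.frame.
#' @param matched As in [vertex_anova()] (runs aligned with the jackknife
#'   ensembles; each run's `left_out` subject is excluded from the median).
#' @param ensembles Nested list `ensembles[[condition]]` of
#'   `jackknife_ensemble`s (provides the left-out subject per run).
#' @param rel_threshold Threshold (default 0.4).
#' @param jackknife_correction Divide F by (mean N - 1)^2.
#' @return List with `medians` (long data.frame), `anova` (effect, F, df, p,
#'   partial eta squared) and `posthoc`.
#' @export
lowfreq_anova <- function(pacmaps_by_cond, matched, ensembles,
                          rel_threshold = 0.4, jackknife_correction = TRUE) {
  conds <- megpac_conditions()
  nets <- names(matched[[1L]])
  rows <- list()
  for (cc in conds) {
    sids <- names(pacmaps_by_cond[[cc]])
    fmat <- do.call(cbind, lapply(pacmaps_by_cond[[cc]],
                                  function(pm) pm$f_phase))  # nv x nsubj
    for (r in seq_along(ensembles[[cc]]$runs)) {
      left <- ensembles[[cc]]$runs[[r]]$left_out
      keep <- fmat[, sids != left, drop = FALSE]
      fmap <- apply(keep, 1L, stats::median)
      for (k in nets) {
        run <- matched[[cc]][[k]][[r]]
        mask <- if (max(run$map) <= 0) rep(FALSE, length(run$map))
                else binarize_map(run$map, rel_threshold)$members
        if (!any(mask)) {
          warning(sprintf("run %d condition %s: empty mask for network %s; excluded", r, cc, k))
          next
        }
        fac <- .cond_factors(cc)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cc, network = k, run = r,
          medication = fac$medication, session = fac$session,
          median_f_phase = stats::median(fmap[mask])
        )
      }
    }
  }
  med <- do.call(rbind, rows)
  ns <- vapply(conds, function(cc) ensembles[[cc]]$n_runs, 1L)
  f_corr <- if (jackknife_correction) (mean(ns) - 1)^2 else 1
  fit <- stats::lm(median_f_phase ~ network * medication * session, data = med)
  if (stats::var(med$median_f_phase) < 1e-18) {
    # no variance anywhere: every effect is exactly null
    eff <- attr(stats::terms(fit), "term.labels")
    tab <- data.frame(effect = eff, df = NA_real_,
                      df_res = stats::df.residual(fit),
                      F = 0, eta2_partial = 0, p = 1)
  } else {
    a2 <- car::Anova(fit, type = 2)
    eff <- rownames(a2)
    eff <- eff[eff != "Residuals"]
    ss_res <- a2["Residuals", "Sum Sq"]
    df_res <- a2["Residuals", "Df"]
    tab <- data.frame(
      effect = eff,
      df = a2[eff, "Df"],
      df_res = df_res,
      F = a2[eff, "F value"] / f_corr,
      eta2_partial = a2[eff, "Sum Sq"] / (a2[eff, "Sum Sq"] + ss_res)
    )
    tab$p <- stats::pf(tab$F, tab$df, df_res, lower.tail = FALSE)
  }

  infl <- if (jackknife_correction) stats::setNames(ns - 1, conds) else
    stats::setNames(rep(1, 4), conds)
  posthoc <- list()
  for (e in tab$effect[tab$p < 0.05 & !grepl(":", tab$effect)]) {
    lev <- unique(med[[e]])
    prs <- utils::combn(lev, 2L)
    for (j in seq_len(ncol(prs))) {
      x <- med$median_f_phase[med[[e]] == prs[1, j]]
      y <- med$median_f_phase[med[[e]] == prs[2, j]]
      # inflation: average over the conditions contributing to each side
      ix <- mean(infl[unique(med$condition[med[[e]] == prs[1, j]])])
      iy <- mean(infl[unique(med$condition[med[[e]] == prs[2, j]])])
      wt <- welch_t(x, y, inflate_x = ix, inflate_y = iy)
      posthoc[[length(posthoc) + 1L]] <- data.frame(
        effect = e, level_1 = prs[1, j], level_2 = prs[2, j],
        t = wt$t, df = wt$df, p = wt$p
      )
    }
  }
  posthoc <- if (length(posthoc)) do.call(rbind, posthoc) else
    data.frame(effect = character(0), level_1 = character(0),
               level_2 = character(0), t = numeric(0), df = numeric(0),
               p = numeric(0))
  if (nrow(posthoc)) posthoc$p_bonf <- pmin(1, posthoc$p * nrow(posthoc))
  list(medians = med, anova = tab, posthoc = posthoc)
}
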