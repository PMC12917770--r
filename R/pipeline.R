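#' End-to-end pipeline configuration
#'
#' Bundles every stage's parameters: the synthetic cohort (or a directory
#' of recording files), motion detection, the quality thresholds, CV
#' pruning, the sweep grid, the task-relevant channel list and the
#' statistics options.
#'
#' @param design a [cohort_design()] (ignored when \code{input_dir} is
#'   given).
#' @param sim a [sim_config()]; its \code{seed} is the master seed.
#' @param motion a [motion_config()].
#' @param qt a [qt_config()] (window length, band, q_threshold).
#' @param cv a [cv_config()].
#' @param grid a [sweep_grid()].
#' @param trc_set task-relevant channel indices.
#' @param exclusion_frac participant-exclusion fraction (default 0.6).
#' @param n_boot bootstrap resamples for the effect estimates
#'   (default 200).
#' @param m Bonferroni family size for the method contrasts (default 3).
#' @param input_dir optional directory of \code{.nirs.json} recordings to
#'   analyse instead of simulating (metadata must carry id, age_months,
#'   cohort, task).
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(design = cohort_design(n_per_cell = 1),
                            sim = sim_config(seed = 1),
                            motion = motion_config(), qt = qt_config(),
                            cv = cv_config(), grid = sweep_grid(),
                            trc_set = c(8:10, 25:27),
                            exclusion_frac = 0.6, n_boot = 200, m = 3,
                            input_dir = NULL) {
  structure(list(design = design, sim = sim, motion = motion, qt = qt,
                 cv = cv, grid = grid, trc_set = trc_set,
                 exclusion_frac = exclusion_frac, n_boot = n_boot, m = m,
                 input_dir = input_dir),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(rapply(unclass(config), function(x) {
    if (is.function(x)) "<function>" else x
  }, how = "replace"), auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the whole analysis pipeline
#'
#' Simulate (or load) the cohort, exclude dead channels, detect motion,
#' derive clean windows, score windowed quality, prune with every method,
#' sweep the threshold grids, select the retention-matched parameters,
#' fit the method contrasts and the full fixed-effects model with
#' bootstrap intervals, and persist every intermediate as CSV/JSON plus a
#' run manifest. With \code{resume = TRUE}, stages whose outputs already
#' exist in \code{output_dir} are loaded instead of recomputed.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for the output bundle (created if
#'   needed).
#' @param resume reuse existing stage outputs (default FALSE).
#' @return Invisibly, a list with the main artifacts (participants,
#'   sweep, matches, contrasts, effects, manifest).
#' @export
run_pipeline <- function(config, output_dir, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(output_dir, f)

  # stage 1: cohort
  cohort <- NULL
  if (resume && file.exists(pth("participants.csv")) &&
      file.exists(pth("sweep.csv"))) {
    participants <- utils::read.csv(pth("participants.csv"))
  } else if (!is.null(config$input_dir)) {
    cohort <- .stage("load", .load_cohort(config$input_dir))
    participants <- cohort$participants
    utils::write.csv(participants, pth("participants.csv"),
                     row.names = FALSE)
  } else {
    cohort <- .stage("simulate", generate_cohort(config$design, config$sim))
    participants <- cohort$participants
    utils::write.csv(participants, pth("participants.csv"),
                     row.names = FALSE)
    gt <- do.call(rbind, lapply(seq_along(cohort$recordings), function(p) {
      tr <- cohort$recordings[[p]]$truth
      data.frame(id = participants$id[p],
                 cardiac_frequency = tr$cardiac_frequency,
                 n_motion_events = nrow(tr$motion_events),
                 n_cse = length(tr$cse_channels),
                 mean_coupling = mean(tr$coupling))
    }))
    utils::write.csv(gt, pth("ground_truth.csv"), row.names = FALSE)
  }

  # stage 2: sweep (motion, quality and pruning are computed inside)
  if (resume && file.exists(pth("sweep.csv"))) {
    sweep <- utils::read.csv(pth("sweep.csv"))
  } else {
    sweep <- .stage("sweep",
      run_sweep(cohort, config$grid, config$qt, config$motion, config$cv,
                config$trc_set, config$exclusion_frac))
    utils::write.csv(sweep, pth("sweep.csv"), row.names = FALSE)
  }

  # stage 3: retention matching
  matches <- .stage("match", list(
    qt = match_to_cv(sweep, "qt"),
    sci_only = match_to_cv(sweep, "sci_only")))
  jsonlite::write_json(
    list(qt = matches$qt$selected, sci_only = matches$sci_only$selected,
         cv_mean_cr = matches$qt$cv_mean_cr,
         cv_n_excluded = matches$qt$cv_n_excluded),
    pth("match.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")

  # stage 4: method contrasts at the matched parameters
  mrows <- .stage("contrast_rows", .method_rows(sweep, matches))
  utils::write.csv(mrows, pth("method_rows.csv"), row.names = FALSE)
  contrasts <- NULL
  if (length(unique(mrows$id[!is.na(mrows$outcome)])) >= 2L) {
    contrasts <- .stage("method_model", fit_method_model(mrows, config$m))
    utils::write.csv(as.data.frame(contrasts), pth("method_contrasts.csv"),
                     row.names = FALSE)
  }

  # stage 5: full model + bootstrap on the qt sweep rows
  effects <- NULL
  qt_rows <- sweep[sweep$method == "qt", , drop = FALSE]
  if (length(unique(qt_rows$id)) >= 4L &&
      sum(!is.na(qt_rows$trc_snr)) >= 50L) {
    mlm <- .stage("full_model", fit_full_model(qt_rows, "trc_snr"))
    effects <- .stage("bootstrap",
      bootstrap_fixed_effects(mlm, n_boot = max(100, config$n_boot),
                              seed = if (is.null(config$sim$seed)) 1
                                     else config$sim$seed))
    utils::write.csv(as.data.frame(effects), pth("effects_trc_snr.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nirsprune")),
    config_hash = .config_hash(config),
    master_seed = config$sim$seed,
    n_participants = nrow(participants),
    n_sweep_rows = nrow(sweep),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)

  invisible(list(participants = participants, sweep = sweep,
                 matches = matches, contrasts = contrasts,
                 effects = effects, manifest = manifest,
                 output_dir = output_dir))
}

.load_cohort <- function(input_dir) {
  files <- sort(list.files(input_dir, pattern = "\\.nirs\\.json$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no .nirs.json recordings in ", input_dir)
  recs <- lapply(files, function(f) list(recording = read_recording(f)))
  participants <- do.call(rbind, Map(function(r, f) {
    md <- r$recording$metadata
    data.frame(id = md$id %||% basename(f),
               age_months = md$age_months %||% NA,
               cohort = md$cohort %||% NA, task = md$task %||% NA)
  }, recs, files))
  rownames(participants) <- NULL
  list(participants = participants, recordings = recs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one row per participant x method at the retention-matched parameters
.method_rows <- function(sweep, matches) {
  cv <- sweep[sweep$method == "cv", , drop = FALSE]
  pick <- function(method) {
    sel <- matches[[method]]$selected
    s <- sweep[sweep$method == method &
                 sweep$sci_thr == sel$sci_thr &
                 sweep$psp_thr == sel$psp_thr, , drop = FALSE]
    s
  }
  qt <- pick("qt")
  so <- pick("sci_only")
  rbind(
    data.frame(id = cv$id, method = "cv", outcome = cv$trc_snr),
    data.frame(id = so$id, method = "sci_only", outcome = so$trc_snr),
    data.frame(id = qt$id, method = "qt", outcome = qt$trc_snr))
}

#' Summarize a completed pipeline run
#'
#' Assembles a plain-text report from a pipeline output bundle: channels
#' retained and TRC SNR by method, the retention-matched parameters,
#' method contrasts, fitted effects with bootstrap intervals, and a flag
#' on grid selections below the recommended infant minima (SCI 0.6,
#' PSP 0.04). Regeneration is idempotent. Missing artifacts are listed
#' explicitly.
#'
#' @param output_dir a [run_pipeline()] output directory.
#' @param write write \code{report.txt} into the bundle (default TRUE).
#' @return Character vector of report lines, invisibly.
#' @export
summarize_run <- function(output_dir, write = TRUE) {
  need <- c("participants.csv", "sweep.csv", "match.json", "manifest.json")
  have <- file.exists(file.path(output_dir, need))
  if (!all(have))
    stop("incomplete output bundle; missing: ",
         paste(need[!have], collapse = ", "))
  participants <- utils::read.csv(file.path(output_dir, "participants.csv"))
  sweep <- utils::read.csv(file.path(output_dir, "sweep.csv"))
  match <- jsonlite::read_json(file.path(output_dir, "match.json"),
                               simplifyVector = TRUE)

  lines <- c(
    "== nirsprune pipeline report ==",
    sprintf("participants: %d", nrow(participants)),
    "",
    "-- mean channels retained / TRC SNR by method --")
  for (mth in c("cv", "sci_only", "qt")) {
    s <- sweep[sweep$method == mth, , drop = FALSE]
    if (nrow(s) == 0L) next
    lines <- c(lines, sprintf(
      "%-9s mean CR %.2f   mean TRC SNR %.2f dB   (%d rows)",
      mth, mean(s$cr), mean(s$trc_snr, na.rm = TRUE), nrow(s)))
  }
  fmt_sel <- function(sel, lab) {
    flag <- if (sel$sci_thr < 0.6 || sel$psp_thr < 0.04)
      "  [below recommended infant minima SCI 0.6 / PSP 0.04]" else ""
    sprintf("%s: sci_threshold %.3g, psp_threshold %.3g (mean CR %.2f)%s",
            lab, sel$sci_thr, sel$psp_thr, sel$mean_cr, flag)
  }
  lines <- c(lines, "", "-- retention-matched parameters (vs CV) --",
             fmt_sel(match$qt, "full QT"),
             fmt_sel(match$sci_only, "SCI only"))
  cfile <- file.path(output_dir, "method_contrasts.csv")
  if (file.exists(cfile)) {
    ct <- utils::read.csv(cfile)
    lines <- c(lines, "", "-- method contrasts (TRC SNR, dB) --",
               sprintf("%-22s %+.3f (SE %.3f, p_bonf %.3g)",
                       ct$term, ct$estimate, ct$se, ct$p_bonferroni))
  }
  efile <- file.path(output_dir, "effects_trc_snr.csv")
  if (file.exists(efile)) {
    ef <- utils::read.csv(efile)
    lines <- c(lines, "", "-- standardized fixed effects on TRC SNR --",
               sprintf("%-16s %+.4f [%+.4f, %+.4f] SE %.4f",
                       ef$term, ef$estimate, ef$ci_lo, ef$ci_hi, ef$se))
  }
  if (write) writeLines(lines, file.path(output_dir, "report.txt"))
  invisible(lines)
}
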