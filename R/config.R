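#' Run configuration
#'
#' A run configuration bundles everything [run_pipeline()] needs: timing
#' (`tr`), the resting-state settings (`fd_threshold`, `band`, `n_keep`),
#' the HRF parameters, the group presets, the master `seed` and the stages
#' to execute. [read_run_config()] loads a YAML file; [run_config()] builds
#' the validated object in code. Unknown keys are rejected and the
#' configuration is serialized into every output directory so results are
#' reproducible from the embedded config alone.
#'
#' @param tr Repetition time in seconds.
#' @param fd_threshold Censoring threshold in mm.
#' @param band Passband in Hz (length 2; high edge below Nyquist).
#' @param n_keep Harmonized timepoint count.
#' @param hrf Named list with `delta`, `tau`, `exponent`.
#' @param presets Named list; each element holds [group_preset()] arguments
#'   (at least `n_subjects`, `r_mean`, `r_sd`).
#' @param seed Master seed.
#' @param stages Character subset of `c("rsfc", "glm", "stats")`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(tr = 2.6, fd_threshold = 0.5, band = c(0.01, 0.08),
                       n_keep = 250L, hrf = list(delta = 2.25, tau = 1.25, exponent = 2),
                       presets = NULL, seed = 1L,
                       stages = c("rsfc", "stats")) {
  if (is.null(presets)) {
    presets <- list(
      meditator = list(n_subjects = 13, r_mean = -0.55, r_sd = 0.18),
      inlab = list(n_subjects = 21, r_mean = -0.41, r_sd = 0.21),
      hcp = list(n_subjects = 168, r_mean = -0.39, r_sd = 0.19,
                 n_runs = 4, n_timepoints = 346)
    )
  }
  cfg <- list(tr = tr, fd_threshold = fd_threshold, band = band,
              n_keep = as.integer(n_keep), hrf = hrf, presets = presets,
              seed = as.integer(seed), stages = stages)
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname run_config
#' @param cfg Raw configuration list.
#' @export
validate_run_config <- function(cfg) {
  known <- c("tr", "fd_threshold", "band", "n_keep", "hrf", "presets",
             "seed", "stages")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  defaults <- list(tr = 2.6, fd_threshold = 0.5, band = c(0.01, 0.08),
                   n_keep = 250L,
                   hrf = list(delta = 2.25, tau = 1.25, exponent = 2),
                   presets = NULL, seed = 1L, stages = c("rsfc", "stats"))
  for (k in setdiff(names(defaults), names(cfg))) cfg[[k]] <- defaults[[k]]
  if (cfg$tr <= 0) .stopf("tr must be positive")
  cfg$band <- as.numeric(unlist(cfg$band))
  if (length(cfg$band) != 2L || cfg$band[1] <= 0 || cfg$band[1] >= cfg$band[2]) {
    .stopf("band must be c(low, high) with 0 < low < high")
  }
  nyq <- 1 / (2 * cfg$tr)
  if (cfg$band[2] >= nyq) {
    .stopf("band high edge %g Hz is at or above the Nyquist frequency %g Hz",
           cfg$band[2], nyq)
  }
  if (cfg$fd_threshold <= 0) .stopf("fd_threshold must be positive")
  if (cfg$n_keep < 2L) .stopf("n_keep must be >= 2")
  bad_stage <- setdiff(cfg$stages, c("rsfc", "glm", "stats"))
  if (length(bad_stage)) .stopf("unknown stage(s): %s", paste(bad_stage, collapse = ", "))
  if (is.null(cfg$presets) || !length(cfg$presets) || is.null(names(cfg$presets))) {
    .stopf("config needs a named 'presets' list")
  }
  cfg$n_keep <- as.integer(cfg$n_keep)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

.config_presets <- function(cfg) {
  lapply(names(cfg$presets), function(nm) {
    args <- cfg$presets[[nm]]
    args$name <- nm
    if (is.null(args$tr)) args$tr <- cfg$tr
    do.call(group_preset, args)
  })
}

#' Execute the configured pipeline end to end
#'
#' Simulates every preset's cohort and runs the configured stages:
#' `"rsfc"` produces the connectivity long table (`connectivity.tsv`);
#' `"glm"` generates a small MOT session per subject, fits the
#' attend-vs-passive GLM and writes the ROI percent-signal-change table
#' (`roi_psc.tsv`); `"stats"` compares all preset pairs on the
#' connectivity table (`stats_ttests.tsv`) and, when the GLM stage ran,
#' adds the group x hemisphere mixed ANOVA on the DAN-DMN difference
#' (`stats_anova.tsv`). A manifest, the serialized configuration and a
#' stage log are written alongside; any stage failure aborts with the stage
#' and subject named.
#'
#' @param cfg A [run_config()] (or path to a YAML file).
#' @param out_dir Output directory (created; must be empty unless
#'   `overwrite`).
#' @param atlas Atlas lookup.
#' @param glm_runs Number of MOT runs per subject in the GLM stage.
#' @param overwrite Overwrite an existing non-empty directory.
#' @return Invisibly, a list of the produced tables.
#' @export
run_pipeline <- function(cfg, out_dir, atlas = synthetic_atlas(),
                         glm_runs = 2L, overwrite = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    .stopf("output directory %s exists and is not empty (use overwrite = TRUE)", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_line <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  presets <- .config_presets(cfg)
  results <- list()
  current <- list(stage = "setup", subject = NA_character_)
  on_fail <- function(e) {
    .stopf("pipeline failed in stage '%s' (subject %s): %s",
           current$stage, current$subject, conditionMessage(e))
  }

  tryCatch({
    if ("rsfc" %in% cfg$stages) {
      current$stage <- "rsfc"
      log_line("stage rsfc: %d preset(s)", length(presets))
      conn <- do.call(rbind, lapply(presets, function(p) {
        subjects <- simulate_cohort(p, cfg$seed, atlas)
        do.call(rbind, lapply(names(subjects), function(id) {
          current$subject <<- id
          s <- subjects[[id]]
          rec <- rsfc_subject(s$ts, s$motion, s$confounds, atlas,
                              fd_threshold = cfg$fd_threshold,
                              band = cfg$band, n_keep = cfg$n_keep)
          cbind(data.frame(subject = id, group = p$name,
                           stringsAsFactors = FALSE), rec)
        }))
      }))
      write_report_table(conn, file.path(out_dir, "connectivity.tsv"))
      results$connectivity <- conn
      log_line("stage rsfc: wrote %d connectivity rows", nrow(conn))
    }

    if ("glm" %in% cfg$stages) {
      current$stage <- "glm"
      hrf <- do.call(hrf_params, cfg$hrf)
      psc <- do.call(rbind, lapply(presets, function(p) {
        design <- generate_mot_design(glm_runs, seed = cfg$seed)
        seeds <- .child_seeds(cfg$seed + 1L, p$n_subjects)
        do.call(rbind, lapply(seq_len(p$n_subjects), function(i) {
          id <- sprintf("%s_s%03d", p$name, i)
          current$subject <<- id
          subj <- generate_task_subject(design, p, seeds[i], atlas)
          fits <- lapply(seq_len(design$n_runs), function(run) {
            idx <- .run_bounds(subj$ts$run_lengths)[run, ]
            ev <- design_to_events(design, run)
            X <- build_design_matrix(
              ev, motion = subj$motion$params[idx["start"]:idx["end"], ],
              n_tr = design$n_trs_per_run, tr = design$tr, hrf = hrf)
            fit_glm(subj$ts$data[, idx["start"]:idx["end"]], X,
                    contrasts = list(attend_vs_passive = c(attend = 1, passive = -1)))
          })
          # average contrast and baseline over runs before the ROI summary
          avg <- fits[[1L]]
          if (length(fits) > 1L) {
            avg$contrast <- Reduce(`+`, lapply(fits, `[[`, "contrast")) / length(fits)
            avg$betas <- Reduce(`+`, lapply(fits, `[[`, "betas")) / length(fits)
          }
          roi_percent_signal_change(avg, atlas, "attend_vs_passive",
                                    subject = id, group = p$name)
        }))
      }))
      write_report_table(psc, file.path(out_dir, "roi_psc.tsv"))
      results$roi_psc <- psc
      log_line("stage glm: wrote %d ROI rows", nrow(psc))
    }

    if ("stats" %in% cfg$stages) {
      current$stage <- "stats"
      current$subject <- NA_character_
      if (!is.null(results$connectivity)) {
        nms <- vapply(presets, function(p) p$name, "")
        pairs <- utils::combn(nms, 2L, simplify = FALSE)
        tt <- do.call(rbind, lapply(pairs, function(pr) {
          res <- compare_groups(results$connectivity, pr[1], pr[2], value_col = "r")
          data.frame(group_a = pr[1], group_b = pr[2],
                     mean_a = res$mean_a, mean_b = res$mean_b,
                     sd_a = res$sd_a, sd_b = res$sd_b,
                     n_a = res$n_a, n_b = res$n_b,
                     t = res$t, dof = res$dof, p = res$p,
                     cohens_d = res$cohens_d, stringsAsFactors = FALSE)
        }))
        write_report_table(tt, file.path(out_dir, "stats_ttests.tsv"))
        results$ttests <- tt
        log_line("stage stats: wrote %d t-test rows", nrow(tt))
      }
      if (!is.null(results$roi_psc) &&
          length(unique(results$roi_psc$group)) == 2L) {
        dan <- results$roi_psc[results$roi_psc$network == "DAN", ]
        dmn <- results$roi_psc[results$roi_psc$network == "DMN", ]
        diff_tab <- merge(dan, dmn, by = c("subject", "group", "hemisphere"),
                          suffixes = c("_dan", "_dmn"))
        diff_tab$percent_signal_change <-
          diff_tab$percent_signal_change_dan - diff_tab$percent_signal_change_dmn
        av <- mixed_anova(diff_tab)
        write_report_table(as.data.frame(av), file.path(out_dir, "stats_anova.tsv"))
        results$anova <- av
        log_line("stage stats: wrote ANOVA table")
      }
    }
  }, error = on_fail)

  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  cfg_string <- paste(names(unlist(cfg)), unlist(cfg), sep = "=", collapse = ";")
  cfg_bytes <- utf8ToInt(cfg_string)
  manifest <- data.frame(
    package = "attnet",
    version = as.character(utils::packageVersion("attnet")),
    seed = cfg$seed,
    config_hash = sprintf("%08x", sum(cfg_bytes * seq_along(cfg_bytes)) %% 0xFFFFFFF),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(results)
}
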