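#' Simulate a cohort in memory
#'
#' Draws per-subject seeds from the master seed and generates one
#' resting-state subject per row of the preset. Used by [rsfc_cohort()] and
#' by [generate_cohort()], which additionally writes the dataset to disk.
#'
#' @param preset A [group_preset()].
#' @param master_seed Integer master seed.
#' @param atlas Atlas lookup.
#' @param n_subjects Optional override of the preset's sample size (e.g.
#'   for reduced-scale runs).
#' @return List of subjects as returned by [generate_rest_subject()], with
#'   names `<preset>_s<index>`.
#' @export
simulate_cohort <- function(preset, master_seed, atlas = synthetic_atlas(),
                            n_subjects = NULL) {
  n <- if (is.null(n_subjects)) preset$n_subjects else as.integer(n_subjects)
  seeds <- .child_seeds(master_seed, n)
  subjects <- lapply(seq_len(n), function(i) {
    generate_rest_subject(preset, seeds[i], atlas)
  })
  names(subjects) <- sprintf("%s_s%03d", preset$name, seq_len(n))
  attr(subjects, "seeds") <- seeds
  attr(subjects, "group") <- preset$name
  subjects
}

#' Run the resting-state pipeline over a whole cohort
#'
#' Generates the cohort from its preset and runs [rsfc_subject()] on every
#' subject, returning the connectivity long table that feeds the group
#' statistics: one row per subject and hemisphere.
#'
#' @inheritParams simulate_cohort
#' @param ... Passed to [rsfc_subject()] (thresholds, band, `n_keep`, ...).
#' @return Data.frame with `subject`, `group`, `hemisphere`, `r`,
#'   `n_timepoints`, `true_r`.
#' @export
rsfc_cohort <- function(preset, master_seed, atlas = synthetic_atlas(),
                        n_subjects = NULL, ...) {
  subjects <- simulate_cohort(preset, master_seed, atlas, n_subjects)
  rows <- lapply(names(subjects), function(id) {
    s <- subjects[[id]]
    rec <- rsfc_subject(s$ts, s$motion, s$confounds, atlas, ...)
    rec$subject <- id
    rec$group <- preset$name
    rec$true_r <- s$true_r[rec$hemisphere]
    rec
  })
  out <- do.call(rbind, rows)
  out[, c("subject", "group", "hemisphere", "r", "n_timepoints", "true_r")]
}

#' Write a synthetic multi-group dataset to disk
#'
#' Generates every preset's cohort and writes per-subject files plus a
#' manifest. Per subject: the parcel-by-timepoint matrix
#' (`<id>_bold.tsv`), a JSON sidecar with TR and run lengths
#' (`<id>_bold.json`), the motion table (`<id>_motion.tsv`) and the
#' confound table (`<id>_confounds.tsv`). The manifest
#' (`manifest.tsv`) lists subject, group, seed and true r per hemisphere
#' and is byte-identical across reruns with the same inputs.
#'
#' @param presets List of [group_preset()] objects with distinct names.
#' @param master_seed Integer master seed.
#' @param out_dir Output directory.
#' @param atlas Atlas lookup (also written to `atlas.tsv`).
#' @param overwrite Overwrite an existing non-empty directory.
#' @return Invisibly, the manifest data.frame.
#' @export
generate_cohort <- function(presets, master_seed, out_dir,
                            atlas = synthetic_atlas(), overwrite = FALSE) {
  if (inherits(presets, "group_preset")) presets <- list(presets)
  nms <- vapply(presets, function(p) p$name, "")
  if (anyDuplicated(nms)) .stopf("preset names must be distinct")
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    .stopf("output directory %s exists and is not empty (use overwrite = TRUE)", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list()
  for (p in presets) {
    subjects <- simulate_cohort(p, master_seed, atlas)
    seeds <- attr(subjects, "seeds")
    for (i in seq_along(subjects)) {
      id <- names(subjects)[i]
      s <- subjects[[i]]
      utils::write.table(format(s$ts$data, digits = 8, trim = TRUE),
                         file.path(out_dir, paste0(id, "_bold.tsv")),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      jsonlite::write_json(
        list(tr = s$ts$tr, run_lengths = s$ts$run_lengths),
        file.path(out_dir, paste0(id, "_bold.json")), auto_unbox = TRUE
      )
      utils::write.table(format(s$motion$params, digits = 8, trim = TRUE),
                         file.path(out_dir, paste0(id, "_motion.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(format(s$confounds, digits = 8, trim = TRUE),
                         file.path(out_dir, paste0(id, "_confounds.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject = id, group = p$name, seed = seeds[i],
        true_r_L = s$true_r[["L"]], true_r_R = s$true_r[["R"]],
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, manifest)
  manifest$true_r_L <- signif(manifest$true_r_L, 6)
  manifest$true_r_R <- signif(manifest$true_r_R, 6)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_atlas(atlas, file.path(out_dir, "atlas.tsv"))
  invisible(manifest)
}

#' Read one subject written by [generate_cohort()]
#'
#' @param out_dir Dataset directory.
#' @param subject Subject id as listed in the manifest.
#' @return List with `ts`, `motion`, `confounds`.
#' @export
read_cohort_subject <- function(out_dir, subject) {
  side <- jsonlite::read_json(file.path(out_dir, paste0(subject, "_bold.json")),
                              simplifyVector = TRUE)
  bold <- as.matrix(utils::read.delim(
    file.path(out_dir, paste0(subject, "_bold.tsv")), header = FALSE))
  motion <- as.matrix(utils::read.delim(
    file.path(out_dir, paste0(subject, "_motion.tsv"))))
  conf <- as.matrix(utils::read.delim(
    file.path(out_dir, paste0(subject, "_confounds.tsv"))))
  rl <- as.integer(side$run_lengths)
  list(
    ts = parcel_ts(bold, side$tr, rl),
    motion = motion_trace(motion, side$tr, rl),
    confounds = conf
  )
}
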