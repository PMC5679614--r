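#' Pipeline configuration
#'
#' Assembles and validates the configuration for
#' \code{\link{run_pipeline}}. Precedence is caller argument over config
#' defaults; the object round-trips losslessly through JSON.
#'
#' @param input_dir Directory holding the study inputs (per-subject images
#'   under \code{subjects/}, \code{labels.nii} + \code{labels.tsv},
#'   \code{scaling.tsv}, \code{cohort.tsv}).
#' @param output_dir Directory for all outputs.
#' @param simulate \code{NULL}, or a list of arguments for
#'   \code{\link{make_end_to_end_fixture}} (e.g. \code{list(seed = 1)}):
#'   when present the input directory is generated first.
#' @param fit A \code{\link{fit_options}} object.
#' @param region_set Regions summarized and tested.
#' @param battery List with elements \code{scores} (optional subset),
#'   \code{covariates} and \code{ms_only}.
#' @param alpha Significance level for FDR-adjusted p-values, in (0, 1).
#' @param seed Base seed recorded in the manifest.
#' @param resume Skip stages whose inputs and configuration are unchanged
#'   since the last run (checksum-based).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(input_dir, output_dir, simulate = NULL,
                            fit = fit_options(),
                            region_set = limbic_regions(),
                            battery = list(scores = NULL,
                                           covariates = c("age", "gender",
                                                          "lesion_load",
                                                          "treatment"),
                                           ms_only = TRUE),
                            alpha = 0.05, seed = 1L, resume = TRUE) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!inherits(fit, "fit_options")) stop("fit must be a fit_options object")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 simulate = simulate, fit = fit, region_set = region_set,
                 battery = battery, alpha = alpha, seed = as.integer(seed),
                 resume = resume),
            class = "pipeline_config")
}

read_manifest <- function(path) {
  if (file.exists(path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else list(stages = list())
}

stage_done <- function(manifest, name, hash) {
  st <- manifest$stages[[name]]
  !is.null(st) && identical(st$hash, hash) && isTRUE(st$status == "ok")
}

#' Run the full analysis pipeline
#'
#' Executes the stages simulate (optional), fit, summarize, stats and
#' report in order. Each stage records a hash of its configuration and
#' input checksums in the run manifest; with \code{resume = TRUE} a stage
#' whose hash is unchanged and whose outputs exist is skipped. A subject
#' with missing or unreadable images is reported in the manifest warnings
#' and does not block the remaining subjects.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return The run manifest (invisibly also written to
#'   \code{output_dir/manifest.json}): tool version, per-stage status,
#'   timing, hashes, warnings and output checksums.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (config$resume) read_manifest(manifest_path)
              else list(stages = list())
  manifest$tool_version <- as.character(utils::packageVersion("r2tstar"))
  manifest$config_hash <- hash_object(config[setdiff(names(config),
                                                     c("resume"))])
  manifest$warnings <- character(0)
  t_all <- proc.time()[3]

  run_stage <- function(name, hash, outputs, fun) {
    hash <- hash_object(list(hash, manifest$tool_version))
    if (config$resume && stage_done(manifest, name, hash) &&
        all(file.exists(outputs))) {
      message("[", name, "] up to date, skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[3]
    fun()
    manifest$stages[[name]] <<- list(
      hash = hash, status = "ok",
      seconds = round(proc.time()[3] - t0, 2),
      outputs = as.list(hash_files(outputs)))
    message("[", name, "] done in ",
            round(proc.time()[3] - t0, 1), " s")
  }

  # --- simulate ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sim_hash <- hash_object(list("simulate", sim_args))
    run_stage("simulate", sim_hash, file.path(config$input_dir, "cohort.tsv"),
              function() {
                do.call(make_end_to_end_fixture,
                        c(list(dir = config$input_dir), sim_args))
              })
  }

  in_dir <- config$input_dir
  cohort_path <- file.path(in_dir, "cohort.tsv")
  if (!file.exists(cohort_path))
    stop("input cohort table not found: ", cohort_path)
  cohort <- read_tsv(cohort_path)
  scaling <- read_tsv(file.path(in_dir, "scaling.tsv"))
  label_map <- read_label_map(file.path(in_dir, "labels.nii"),
                              file.path(in_dir, "labels.tsv"))
  subjects <- cohort$subject_id

  # --- fit --------------------------------------------------------------
  qmap_dir <- file.path(out_dir, "qmaps")
  dir.create(qmap_dir, showWarnings = FALSE)
  input_files <- unlist(lapply(subjects, function(s)
    file.path(in_dir, "subjects", paste0(s, c("_mag.nii", "_phase.nii",
                                              ".json", "_nav.tsv")))))
  fit_hash <- hash_object(list("fit", config$fit, hash_files(input_files)))
  fit_outputs <- file.path(qmap_dir, paste0(subjects, "_r2t_star.nii"))
  run_stage("fit", fit_hash, fit_outputs, function() {
    for (s in subjects) {
      prefix <- file.path(in_dir, "subjects", s)
      if (!file.exists(paste0(prefix, "_mag.nii"))) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0("subject incomplete, skipped: ", s))
        next
      }
      img <- read_multi_echo(prefix)
      nav_path <- paste0(prefix, "_nav.tsv")
      if (file.exists(nav_path) && !is.null(img$phase))
        img <- navigator_correct(img, read_tsv(nav_path)$phase)
      field <- if (!is.null(img$phase)) estimate_field(img) else NULL
      qm <- fit_volume(img, field, config$fit)
      write_qmaps(qm, file.path(qmap_dir, s))
    }
  })

  # --- summarize --------------------------------------------------------
  summary_path <- file.path(out_dir, "summaries.tsv")
  sum_hash <- hash_object(list("summarize", config$region_set,
                               hash_files(fit_outputs)))
  run_stage("summarize", sum_hash, summary_path, function() {
    rows <- list()
    for (s in subjects) {
      r2t_path <- file.path(qmap_dir, paste0(s, "_r2t_star.nii"))
      if (!file.exists(r2t_path)) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0("no maps for subject: ", s))
        next
      }
      rd <- function(suffix) {
        img <- RNifti::readNifti(file.path(qmap_dir, paste0(s, suffix)))
        array(as.numeric(img), dim = dim(img))
      }
      qm <- list(r2t_star_map = rd("_r2t_star.nii"),
                 quality_mask = rd("_quality_mask.nii") > 0.5,
                 acq = NULL)
      sf <- scaling$scaling_factor[scaling$subject_id == s]
      if (length(sf) == 0) sf <- 1
      vox_vol <- prod(RNifti::pixdim(RNifti::readNifti(
        file.path(qmap_dir, paste0(s, "_r2t_star.nii"))))[1:3])
      rows[[s]] <- summarize_subject(qm, label_map, sf, subject_id = s,
                                     region_set = config$region_set,
                                     voxel_volume = vox_vol)
    }
    write_tsv(do.call(rbind, rows), summary_path)
  })

  # --- stats ------------------------------------------------------------
  stats_paths <- file.path(out_dir, c("stats_correlations.tsv",
                                      "stats_groups.tsv"))
  stats_hash <- hash_object(list("stats", config$battery, config$alpha,
                                 hash_files(c(summary_path, cohort_path))))
  run_stage("stats", stats_hash, stats_paths, function() {
    summaries <- read_tsv(summary_path)
    bt <- run_correlation_battery(
      summaries, cohort, region_set = config$region_set,
      scores = config$battery$scores,
      covariates = config$battery$covariates,
      ms_only = isTRUE(config$battery$ms_only), alpha = config$alpha)
    write_tsv(bt, stats_paths[1])
    gc_regions <- intersect(c("hippocampus", "amygdala"), config$region_set)
    if (length(gc_regions) > 0 && "HC" %in% cohort$group) {
      gcmp <- run_group_comparisons(summaries, cohort,
                                    region_set = gc_regions,
                                    alpha = config$alpha)
      write_tsv(gcmp, stats_paths[2])
    } else write_tsv(data.frame(), stats_paths[2])
  })

  # --- report -----------------------------------------------------------
  report_paths <- file.path(out_dir, c("report_R2t_star.tsv",
                                       "report_NV.tsv", "report.txt"))
  rep_hash <- hash_object(list("report", config$alpha,
                               hash_files(stats_paths[1])))
  run_stage("report", rep_hash, report_paths, function() {
    stats <- read_tsv(stats_paths[1])
    rep <- report_tables(stats, alpha = config$alpha)
    write_tsv(rep$`R2t*`, report_paths[1])
    write_tsv(rep$NV, report_paths[2])
    writeLines(rep$text, report_paths[3])
  })

  manifest$seconds_total <- round(proc.time()[3] - t_all, 2)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Format correlation results as region-by-test grids
#'
#' Renders a tidy battery result into one wide table per measure: one row
#' per (region, hemisphere), one pair of columns (correlation estimate and
#' FDR-adjusted p) per clinical test, with significance determined by the
#' adjusted p-value falling below \code{alpha}. Cells significant at
#' \code{alpha} are marked with \code{*} in the plain-text rendering.
#'
#' @param stats Battery result data.frame from
#'   \code{\link{run_correlation_battery}} (or an empty data.frame).
#' @param alpha Significance level.
#' @return List with one wide data.frame per measure present (named by
#'   measure; measures absent from \code{stats} yield empty frames) and a
#'   \code{text} element holding a plain-text rendering.
#' @export
report_tables <- function(stats, alpha = 0.05) {
  out <- list(`R2t*` = data.frame(), NV = data.frame(),
              text = character(0))
  header <- paste0("Correlation battery report (alpha = ", alpha,
                   "; FDR within measure x battery-part families)")
  text <- header
  if (is.null(stats) || nrow(stats) == 0) {
    out$text <- text
    return(out)
  }
  for (measure in intersect(c("R2t*", "NV"), unique(stats$measure))) {
    sub <- stats[stats$measure == measure, ]
    scores <- unique(sub$score)
    keys <- unique(sub[, c("region_name", "hemisphere")])
    wide <- keys
    p_exact <- list()
    for (sc in scores) {
      cells <- sub[sub$score == sc, ]
      idx <- match(paste(keys$region_name, keys$hemisphere),
                   paste(cells$region_name, cells$hemisphere))
      wide[[paste0(sc, "_r")]] <- round(cells$estimate[idx], 3)
      wide[[paste0(sc, "_p")]] <- round(cells$p_fdr[idx], 4)
      p_exact[[sc]] <- cells$p_fdr[idx]
    }
    out[[measure]] <- wide
    text <- c(text, "", paste0("== ", measure, " =="))
    for (i in seq_len(nrow(wide))) {
      cells <- vapply(scores, function(sc) {
        r <- wide[[paste0(sc, "_r")]][i]
        p <- wide[[paste0(sc, "_p")]][i]
        star <- if (!is.na(p_exact[[sc]][i]) && p_exact[[sc]][i] < alpha)
          "*" else ""
        sprintf("%s r=%.2f p=%.3f%s", sc, r, p, star)
      }, character(1))
      text <- c(text, paste0(sprintf("%-24s %-5s | ", wide$region_name[i],
                                     wide$hemisphere[i]),
                             paste(cells, collapse = " | ")))
    }
  }
  out$text <- text
  out
}
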