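## End-to-end orchestration: simulate -> t2map -> extract -> fitdist ->
## stats, driven by one config, with per-stage seeds derived from a single
## root seed and a checksum manifest enabling skip-if-unchanged reruns.

.PIPELINE_STAGES <- c("simulate", "t2map", "extract", "fitdist", "stats")

.default_config <- function() {
  list(
    group_sizes = c(HC = 8, MCI = 6, AD = 2),
    echo_preset = "cpmg10",
    echo_times = NULL,            # used when echo_preset == "custom"
    exclude_first = NULL,         # NULL -> preset default
    grid_shape = c(24L, 24L, 10L),
    s0 = 1000,
    noise_sd = 20,
    noise_model = "rician",
    caps = c(30, 200),
    families = "loglogistic",     # or "default18" / character vector
    seed = 1L,
    log_level = "info")
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path, YAML text, or a list; applies defaults
#' (caps 30/200 ms, 10-echo CPMG train with first-echo exclusion) and
#' collects all schema violations into one error.
#'
#' @param config path, YAML string, list, or NULL (all defaults).
#' @return validated config list of class \code{"run_config"} with
#'   resolved \code{echo_times}/\code{exclude_first}.
#' @export
validate_config <- function(config = NULL) {
  defaults <- .default_config()
  if (is.null(config)) config <- list()
  if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
              else yaml::yaml.load(config)
    if (is.null(config)) config <- list()
  }
  errs <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errs <- c(errs, paste("unknown keys:", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[intersect(names(config), names(defaults))])
  cfg$group_sizes <- unlist(cfg$group_sizes)
  cfg$caps <- as.numeric(unlist(cfg$caps))
  if (length(cfg$caps) != 2 || cfg$caps[1] >= cfg$caps[2])
    errs <- c(errs, "caps must be two increasing values (ms)")
  if (!cfg$echo_preset %in% c("cpmg10", "tse3", "custom"))
    errs <- c(errs, "echo_preset must be cpmg10, tse3 or custom")
  if (cfg$echo_preset == "custom") {
    cfg$echo_times <- as.numeric(unlist(cfg$echo_times))
    if (length(cfg$echo_times) < 2 || any(cfg$echo_times <= 0) ||
        any(diff(cfg$echo_times) <= 0))
      errs <- c(errs, "custom echo_times must be >= 2 strictly increasing positive values")
    if (is.null(cfg$exclude_first)) cfg$exclude_first <- FALSE
  } else {
    preset <- echo_preset(cfg$echo_preset)
    cfg$echo_times <- preset$echo_times
    if (is.null(cfg$exclude_first)) cfg$exclude_first <- preset$exclude_first
  }
  if (!cfg$noise_model %in% c("rician", "gaussian", "none"))
    errs <- c(errs, "noise_model must be rician, gaussian or none")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0)
    errs <- c(errs, "noise_sd must be >= 0")
  if (identical(cfg$families, "default18")) cfg$families <- names(family_registry())
  known <- names(family_registry())
  if (!all(cfg$families %in% known))
    errs <- c(errs, paste("unknown families:",
                          paste(setdiff(cfg$families, known), collapse = ", ")))
  if (length(errs))
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "), call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

.stage_seed <- function(config, stage) {
  # deterministic per-stage seed from the root seed, kept inside 32-bit range
  (config$seed * 131L + match(stage, .PIPELINE_STAGES) * 7919L) %% 2147483587L
}

.hash_obj <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(obj), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

.stage_config <- function(cfg, stage) {
  keep <- switch(stage,
    simulate = c("group_sizes", "grid_shape", "echo_preset", "echo_times",
                 "s0", "noise_sd", "noise_model", "seed"),
    t2map = c("echo_times", "exclude_first"),
    extract = "caps",
    fitdist = "families",
    stats = character())
  cfg[keep]
}

#' Run the full analysis pipeline
#'
#' Executes simulate, t2map, extract, fitdist and stats in order under
#' \code{out_dir} (layout: \code{images/}, \code{maps/}, \code{samples/},
#' \code{fits/}, \code{stats/}, \code{manifest.json}). A stage is skipped
#' when a previous manifest records the same stage configuration, no
#' upstream stage re-ran, and its outputs still checksum-match. Every
#' stochastic stage seeds from a deterministic offset of the root seed.
#'
#' @param config anything [validate_config()] accepts.
#' @param out_dir run directory.
#' @param quiet suppress progress messages.
#' @return the run manifest (invisibly): per-stage config hash, output
#'   checksums, timing, and whether the stage was skipped.
#' @export
run_pipeline <- function(config = NULL, out_dir, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("images", "maps", "samples", "fits", "stats"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  manifest_path <- file.path(out_dir, "manifest.json")
  old <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL

  manifest <- list(package_version = as.character(utils::packageVersion("t2het")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   stages = list())
  upstream_changed <- FALSE
  state <- new.env(parent = emptyenv())

  for (stage in .PIPELINE_STAGES) {
    h <- .hash_obj(.stage_config(cfg, stage))
    prev <- old$stages[[stage]]
    outputs_ok <- !is.null(prev) && identical(prev$config_hash, h) &&
      length(prev$outputs) > 0 &&
      all(file.exists(file.path(out_dir, names(prev$outputs)))) &&
      identical(unname(unlist(prev$outputs)),
                unname(tools::md5sum(file.path(out_dir, names(prev$outputs)))))
    if (outputs_ok && !upstream_changed) {
      say("[%s] unchanged - skipped", stage)
      manifest$stages[[stage]] <- list(config_hash = h,
                                       outputs = as.list(prev$outputs),
                                       skipped = TRUE, seconds = 0)
      next
    }
    t0 <- proc.time()[["elapsed"]]
    outs <- tryCatch(
      .run_stage(stage, cfg, out_dir, state),
      error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e)), call. = FALSE))
    sums <- tools::md5sum(file.path(out_dir, outs))
    names(sums) <- outs
    manifest$stages[[stage]] <- list(config_hash = h,
                                     outputs = as.list(sums),
                                     skipped = FALSE,
                                     seconds = round(proc.time()[["elapsed"]] - t0, 3))
    upstream_changed <- TRUE
    say("[%s] done (%.1fs, %d outputs)", stage,
        manifest$stages[[stage]]$seconds, length(outs))
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.run_stage <- function(stage, cfg, out_dir, state) {
  switch(stage,
         simulate = .stage_simulate(cfg, out_dir, state),
         t2map = .stage_t2map(cfg, out_dir, state),
         extract = .stage_extract(cfg, out_dir, state),
         fitdist = .stage_fitdist(cfg, out_dir, state),
         stats = .stage_stats(cfg, out_dir, state))
}

.stage_simulate <- function(cfg, out_dir, state) {
  seed <- .stage_seed(cfg, "simulate")
  cspec <- cohort_spec(group_sizes = cfg$group_sizes, seed = seed)
  pspec <- phantom_spec(grid_shape = cfg$grid_shape,
                        echo_times = cfg$echo_times, s0 = cfg$s0,
                        noise_sd = cfg$noise_sd, noise_model = cfg$noise_model)

  cohort <- generate_cohort_table(cspec)
  truth <- cohort_truth(cohort, cspec)
  cohort <- simulate_cognition(cohort, truth, cspec$cognition, seed = seed + 2L)
  # follow-up subsample: up to 10 MCI per study
  cohort$followup <- FALSE
  for (s in unique(cohort$study)) {
    idx <- which(cohort$study == s & cohort$group == "MCI")
    cohort$followup[utils::head(idx, 10)] <- TRUE
  }
  outs <- c("cohort.csv", "truth.csv")
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)

  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[i]
    tp <- truth[truth$subject_id == sid, ]
    field <- render_t2_field(tp, pspec, seed = seed + 100L + i)
    img <- simulate_multi_echo(field$t2, pspec, seed = seed + 5000L + i)
    ipath <- file.path("images", paste0(sid, ".nii.gz"))
    write_multi_echo(img, file.path(out_dir, ipath))
    outs <- c(outs, ipath, sub("\\.nii\\.gz$", ".yaml", ipath))
    for (rn in names(field$masks)) for (h in names(field$masks[[rn]])) {
      mpath <- file.path("images", sprintf("%s_%s_%s_mask.nii.gz", sid, rn, h))
      write_mask(field$masks[[rn]][[h]], file.path(out_dir, mpath),
                 voxel_size = pspec$voxel_size)
      outs <- c(outs, mpath)
    }
  }
  state$voxel_size <- pspec$voxel_size
  outs
}

.stage_t2map <- function(cfg, out_dir, state) {
  imgs <- list.files(file.path(out_dir, "images"),
                     pattern = "^S[0-9]+\\.nii\\.gz$", full.names = FALSE)
  outs <- character()
  for (f in imgs) {
    img <- read_multi_echo(file.path(out_dir, "images", f))
    map <- compute_t2_map(img, exclude_first = cfg$exclude_first)
    mpath <- file.path("maps", sub("\\.nii\\.gz$", "_t2map.nii.gz", f))
    write_t2_map(map, file.path(out_dir, mpath))
    outs <- c(outs, mpath)
  }
  outs
}

.stage_extract <- function(cfg, out_dir, state) {
  maps <- list.files(file.path(out_dir, "maps"), pattern = "_t2map\\.nii\\.gz$")
  rows <- list()
  vols <- list()
  for (f in maps) {
    sid <- sub("_t2map\\.nii\\.gz$", "", f)
    map <- read_t2_map(file.path(out_dir, "maps", f))
    masks <- list.files(file.path(out_dir, "images"),
                        pattern = paste0("^", sid, "_.*_mask\\.nii\\.gz$"))
    for (mf in masks) {
      parts <- strsplit(sub("_mask\\.nii\\.gz$", "", mf), "_")[[1]]
      rn <- parts[2]; h <- parts[3]
      mask <- read_mask(file.path(out_dir, "images", mf))
      s <- extract_roi_samples(map, mask, cfg$caps[1], cfg$caps[2],
                               region = rn, hemisphere = h, subject_id = sid)
      rows[[length(rows) + 1]] <- s
      vols[[length(vols) + 1]] <-
        data.frame(subject_id = sid, region = rn, hemisphere = h,
                   vol_mm3 = roi_volume(mask, map$voxel_size))
    }
  }
  utils::write.csv(roi_samples_table(rows),
                   file.path(out_dir, "samples", "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, vols),
                   file.path(out_dir, "samples", "volumes.csv"),
                   row.names = FALSE)
  file.path("samples", c("samples.csv", "volumes.csv"))
}

.stage_fitdist <- function(cfg, out_dir, state) {
  samples <- utils::read.csv(file.path(out_dir, "samples", "samples.csv"),
                             stringsAsFactors = FALSE)
  registry <- family_registry(cfg$families)
  fit_rows <- list()
  sum_rows <- list()
  for (sid in unique(samples$subject_id)) {
    for (rn in unique(samples$region[samples$subject_id == sid])) {
      sub <- samples[samples$subject_id == sid & samples$region == rn, ]
      hemis <- split(sub$t2_ms, sub$hemisphere)
      for (h in names(hemis)) {
        fits <- fit_all_families(hemis[[h]], registry)
        for (f in fits) {
          if (isTRUE(f$skipped)) next
          fit_rows[[length(fit_rows) + 1]] <- data.frame(
            subject_id = sid, region = rn, hemisphere = h, family = f$family,
            params = paste(sprintf("%s=%.6g", names(f$params), f$params),
                           collapse = ";"),
            loglik = f$loglik, aic = f$aic, n = f$n, converged = f$converged)
        }
      }
      summ <- summarize_region(hemis[["left"]], hemis[["right"]],
                               registry = registry, subject_id = sid,
                               region = rn)
      sum_rows[[length(sum_rows) + 1]] <- data.frame(
        subject_id = sid, region = rn, T2mu = summ$T2mu,
        T2sigma = summ$T2sigma, best_family = summ$best_family)
    }
  }
  utils::write.csv(do.call(rbind, fit_rows),
                   file.path(out_dir, "fits", "fits.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, sum_rows),
                   file.path(out_dir, "fits", "summaries.csv"),
                   row.names = FALSE)
  file.path("fits", c("fits.csv", "summaries.csv"))
}

.stage_stats <- function(cfg, out_dir, state) {
  cohort <- utils::read.csv(file.path(out_dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  cohort$group <- factor(cohort$group, levels = c("HC", "MCI", "AD"))
  summaries <- utils::read.csv(file.path(out_dir, "fits", "summaries.csv"),
                               stringsAsFactors = FALSE)
  vols <- utils::read.csv(file.path(out_dir, "samples", "volumes.csv"),
                          stringsAsFactors = FALSE)
  results <- list(modal_family = list(), ancova = list())
  for (rn in unique(summaries$region)) {
    sr <- summaries[summaries$region == rn, ]
    i <- match(cohort$subject_id, sr$subject_id)
    vr <- stats::aggregate(vol_mm3 ~ subject_id, data = vols[vols$region == rn, ], sum)
    metrics <- list(T2mu = sr$T2mu[i], T2sigma = sr$T2sigma[i],
                    volume = icv_correct(
                      vr$vol_mm3[match(cohort$subject_id, vr$subject_id)],
                      cohort$icv_mm3))
    results$modal_family[[rn]] <- modal_best_family(sr$best_family)$family
    results$ancova[[rn]] <- lapply(metrics, function(v) {
      ok <- is.finite(v)
      grp <- droplevels(cohort$group[ok])
      if (nlevels(grp) < 2 || any(table(grp) < 2)) return(NULL)
      z <- zscore_to_reference(v[ok], cohort$group[ok] == "HC",
                               cohort$study[ok])
      a <- ancova_group(z, grp, data.frame(age = cohort$age[ok]))
      list(F = a$F, df1 = a$df1, df2 = a$df2, p = a$p, emm = a$emm,
           pairwise = a$pairwise,
           levene = a$levene[c("W", "p")])
    })
  }
  mci <- cohort[cohort$group == "MCI" & cohort$followup, ]
  rn1 <- unique(summaries$region)[1]
  sr <- summaries[summaries$region == rn1, ]
  if (nrow(mci) >= 6) {
    marker <- sr$T2sigma[match(mci$subject_id, sr$subject_id)]
    marker <- zscore_to_reference(marker, rep(TRUE, length(marker)), mci$study)
    fr <- followup_regression(mci$cog_followup, mci$age, mci$cog_baseline,
                              marker, marker_name = "T2sigma")
    results$followup <- list(r2 = fr$r2, F = fr$F, df1 = fr$df1, df2 = fr$df2,
                             p = fr$p, coefficients = fr$coefficients)
  }
  hc <- cohort$group == "HC"
  if (sum(hc) >= 3) {
    results$age_regression <- lapply(
      list(T2mu = sr$T2mu, T2sigma = sr$T2sigma), function(v) {
        m <- v[match(cohort$subject_id[hc], sr$subject_id)]
        age_regression(m, cohort$age[hc])[c("r2", "slope", "p", "n")]
      })
  }
  jsonlite::write_json(results, file.path(out_dir, "stats", "results.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  file.path("stats", "results.json")
}
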