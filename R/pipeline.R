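#' Run the phantom parameter-recovery study
#'
#' Simulates each subject of the configured study and pushes it through
#' the full quantitative pipeline: Dixon decomposition and fat-fraction
#' mapping, vertebral-level ROI aggregation and (optionally) tensor
#' fitting with eigenvalue metrics. Subjects are processed one at a time
#' so memory stays bounded.
#'
#' @param config a [PhantomConfig-class].
#' @param withDti simulate and fit the diffusion series.
#' @param highFatThreshold cutoff for the pooled high-fat voxel count
#'   (default 0.45).
#' @param verbose log progress via `message()`.
#' @param keepLast also return the final subject's dataset and maps (for
#'   plotting or export).
#' @return list with `levelTable` (all subjects stacked, see
#'   [aggregateLevels()]), `highFat` (named vector: labeled Dixon-grid
#'   voxels above/below the threshold pooled over subjects), `truth` (the
#'   unperturbed truth table) and, when `keepLast`, `last` (list of
#'   dataset, fatWater, diffusion).
#' @export
phantomRecoveryStudy <- function(config, withDti = TRUE,
                                 highFatThreshold = 0.45, verbose = FALSE,
                                 keepLast = FALSE) {
  stopifnot(is(config, "PhantomConfig"))
  tabs <- vector("list", config@nSubjects)
  above <- 0
  total <- 0
  last <- NULL
  for (s in seq_len(config@nSubjects)) {
    if (verbose) message(sprintf("[subject %d/%d] simulating", s,
                                 config@nSubjects))
    ds <- simulateSubject(config, s, withDwi = withDti)
    fw <- dixonDecompose(ds@inPhase, ds@outPhase)
    dmaps <- NULL
    fit <- NULL
    if (withDti) {
      fit <- fitTensor(ds@dwi, mask = validMask(ds@truthTensors) * 1)
      dmaps <- eigenMetrics(fit)
    }
    tabs[[s]] <- aggregateLevels(s, ds@labels, ds@levelEdges,
                                 fatWater = fw, diffusion = dmaps)
    mkD <- resampleMask(ds@labels, fw@fatFraction)
    inside <- imgData(mkD) > 0
    above <- above + sum(imgData(fw@fatFraction)[inside] > highFatThreshold)
    total <- total + sum(inside)
    if (keepLast && s == config@nSubjects)
      last <- list(dataset = ds, fatWater = fw, diffusion = dmaps,
                   tensorFit = fit)
  }
  out <- list(levelTable = do.call(rbind, tabs),
              highFat = c(above = above, total = total,
                          fraction = above / total),
              truth = config@truth)
  if (keepLast) out$last <- last
  out
}

#' Run configuration for the end-to-end pipeline
#'
#' @param mode "simulate" (write phantom datasets only), "analyze"
#'   (quantitative maps, tables and statistics) or "full" (both, plus
#'   tractography export).
#' @param phantom a [PhantomConfig-class].
#' @param tract settings from [tractographyConfig()]; the pipeline caps
#'   seeding at `max_seeds` per subject (default 400) to keep runs
#'   tractable.
#' @param alpha significance threshold for the statistics stage.
#' @param outputDir directory for all outputs.
#' @param logLevel "quiet" or "info".
#' @return validated list.
#' @export
runConfig <- function(mode = c("full", "simulate", "analyze"),
                      phantom = phantomConfig(), tract = tractographyConfig(
                        max_seeds = 400L),
                      alpha = 0.05, outputDir = "lumbarqmri-out",
                      logLevel = c("info", "quiet")) {
  mode <- match.arg(mode)
  logLevel <- match.arg(logLevel)
  stopifnot(is(phantom, "PhantomConfig"), alpha > 0, alpha < 1)
  validObject(phantom)
  list(mode = mode, phantom = phantom, tract = tract, alpha = alpha,
       outputDir = outputDir, logLevel = logLevel)
}

#' Execute a configured pipeline run
#'
#' Depending on the mode, writes per-subject phantom datasets (NIfTI +
#' bvec/bval + CSV), quantitative maps (fat fraction, FA, MD, RD,
#' lambda1-3), TrackVis streamline files, a stacked level table CSV, an
#' ANOVA/post hoc CSV and a human-readable summary. A serialized copy of
#' the configuration is written into the output directory. All outputs
#' are deterministic functions of the configuration (including its seed).
#'
#' @param config list from [runConfig()].
#' @return invisibly, a list with the output paths, the level table and
#'   the ANOVA results (where computed).
#' @export
runPipeline <- function(config) {
  t0 <- Sys.time()
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  logi <- function(...) if (config$logLevel != "quiet")
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...)))
  paths <- list()
  cfgPath <- file.path(config$outputDir, "run_config.txt")
  writeLines(c(
    sprintf("mode: %s", config$mode),
    sprintf("subjects: %d", config$phantom@nSubjects),
    sprintf("cv: %g", config$phantom@betweenSubjectCV),
    sprintf("snr: %g", config$phantom@snr),
    sprintf("seed: %d", config$phantom@seed),
    sprintf("alpha: %g", config$alpha),
    sprintf("tract: angle %g deg, step %g mm, min length %g mm",
            config$tract$angle_threshold_deg, config$tract$step_mm,
            config$tract$min_length_mm)), cfgPath)
  paths$config <- cfgPath
  ph <- config$phantom
  doSim <- config$mode %in% c("simulate", "full")
  doAna <- config$mode %in% c("analyze", "full")
  doTract <- config$mode == "full"
  tabs <- list()
  above <- 0; total <- 0
  for (s in seq_len(ph@nSubjects)) {
    logi("subject %d/%d", s, ph@nSubjects)
    ds <- simulateSubject(ph, s, withDwi = doAna || doTract || doSim)
    sdir <- file.path(config$outputDir, sprintf("subject%02d", s))
    if (doSim) {
      logi("  writing phantom dataset")
      writeDataset(ds, sdir)
      paths$datasets <- c(paths$datasets, sdir)
    }
    if (doAna) {
      fw <- dixonDecompose(ds@inPhase, ds@outPhase)
      fit <- fitTensor(ds@dwi, mask = validMask(ds@truthTensors) * 1)
      dmaps <- eigenMetrics(fit)
      tabs[[s]] <- aggregateLevels(s, ds@labels, ds@levelEdges,
                                   fatWater = fw, diffusion = dmaps)
      mkD <- resampleMask(ds@labels, fw@fatFraction)
      inside <- imgData(mkD) > 0
      above <- above + sum(imgData(fw@fatFraction)[inside] > 0.45)
      total <- total + sum(inside)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      writeNiftiVolume(fw@fatFraction, file.path(sdir, "ff.nii.gz"))
      for (nm in c("fa", "md", "rd", "lambda1", "lambda2", "lambda3"))
        writeNiftiVolume(slot(dmaps, nm),
                         file.path(sdir, paste0(nm, ".nii.gz")))
      if (doTract) {
        logi("  tractography")
        mkT <- resampleMask(ds@labels, fit)
        ts <- trackStreamlines(fit, mkT, config$tract,
                               seed = subjectSeed(ph, s, "tract"))
        if (length(ts))
          writeTrk(ts, ImageVolume(array(0, dim(imgData(fit))[1:3]),
                                   fit@spacing, fit@origin),
                   file.path(sdir, "tracks.trk"))
      }
    }
    rm(ds)
  }
  result <- list(paths = paths)
  if (doAna) {
    lt <- do.call(rbind, tabs)
    ltPath <- file.path(config$outputDir, "level_table.csv")
    utils::write.csv(lt, ltPath, row.names = FALSE)
    paths$levelTable <- ltPath
    anovas <- list()
    statRows <- list()
    for (metric in c("volume_ml", "fat_fraction", "fa", "md", "rd",
                     "lambda1", "lambda2", "lambda3")) {
      if (all(!is.finite(lt[[metric]]))) next
      an <- tryCatch(rmAnova(lt, metric, alpha = config$alpha),
                     error = function(e) NULL)
      if (is.null(an)) next
      anovas[[metric]] <- an
      ef <- an@effects
      ef$metric <- metric
      statRows[[metric]] <- ef
    }
    if (length(statRows)) {
      anPath <- file.path(config$outputDir, "anova.csv")
      utils::write.csv(do.call(rbind, statRows), anPath, row.names = FALSE)
      paths$anova <- anPath
      phPath <- file.path(config$outputDir, "posthoc.csv")
      phRows <- do.call(rbind, lapply(names(anovas), function(m) {
        x <- anovas[[m]]@posthoc
        if (nrow(x)) cbind(metric = m, x) else NULL
      }))
      utils::write.csv(phRows, phPath, row.names = FALSE)
      paths$posthoc <- phPath
    }
    sumPath <- file.path(config$outputDir, "summary.txt")
    writeLines(pipelineSummary(lt, above / max(total, 1), anovas,
                               config), sumPath)
    paths$summary <- sumPath
    result$levelTable <- lt
    result$anovas <- anovas
    result$highFatFraction <- above / max(total, 1)
  }
  result$paths <- paths
  logi("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(result)
}

pipelineSummary <- function(lt, highFat, anovas, config) {
  agg <- function(muscle, col) {
    lm_ <- stats::aggregate(lt[[col]][lt$muscle == muscle],
                            by = list(level = lt$level[lt$muscle == muscle]),
                            FUN = mean, na.rm = TRUE)
    mean(lm_$x)
  }
  lines <- c(
    "Lumbar muscle phantom recovery summary",
    sprintf("subjects: %d, CV %.2f, SNR %g, seed %d",
            config$phantom@nSubjects, config$phantom@betweenSubjectCV,
            config$phantom@snr, config$phantom@seed),
    "",
    sprintf("mean volume across levels:  erector spinae %.1f mL, multifidus %.1f mL",
            agg("erector_spinae", "volume_ml"), agg("multifidus", "volume_ml")),
    sprintf("mean fat signal fraction:   erector spinae %.3f, multifidus %.3f",
            agg("erector_spinae", "fat_fraction"), agg("multifidus", "fat_fraction")),
    sprintf("labeled voxels with fat fraction > 0.45: %.1f%%", 100 * highFat),
    "")
  for (m in names(anovas)) {
    ef <- anovas[[m]]@effects
    lines <- c(lines, sprintf(
      "%s: %s", m, paste(sprintf("%s F=%.2f p=%.3g", ef$effect, ef$F, ef$p),
                         collapse = "; ")))
  }
  lines
}
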