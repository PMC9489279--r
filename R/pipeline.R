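#' Pipeline configuration
#'
#' Either point \code{treeFile}, \code{ctFile} and \code{trajectoryFile} at
#' input files, or supply a \code{simulation} config to generate the whole
#' study in silico. The default model suites are the two compared in the
#' analysis: four binomial susceptibility models (fixed distance from the
#' focal host in/out, random phylogenetic term in/out, species retained
#' throughout) and eight Gaussian transmission models (fixed passage-0 Ct
#' and focal distance in/out, random phylogenetic term in/out, species and
#' strain retained throughout).
#'
#' @param treeFile,ctFile,trajectoryFile input paths (Newick, delimited Ct
#'   table, delimited long-format trajectories); ignored when
#'   \code{simulation} is given
#' @param simulation a [simulationConfig()] list, or NULL to read files
#' @param focalTaxon focal host tip label; defaults to the first tip
#' @param benchmark 4 or 5, the thresholding benchmark
#' @param chain [chainSettings()] used for every model fit
#' @param undetectedCt Ct imputed for non-detections (default 40)
#' @param outDir output directory
#' @param seed master seed; per-stage and per-model seeds are derived from
#'   it deterministically
#' @return config list for [runPipeline()]
#' @export
pipelineConfig <- function(treeFile = NULL, ctFile = NULL,
                           trajectoryFile = NULL, simulation = NULL,
                           focalTaxon = NULL, benchmark = 4,
                           chain = chainSettings(), undetectedCt = 40,
                           outDir = tempfile("hostrange_"), seed = 1) {
  if (is.null(simulation) &&
      (is.null(treeFile) || is.null(ctFile)))
    stop("supply input files or a simulation config")
  list(treeFile = treeFile, ctFile = ctFile,
       trajectoryFile = trajectoryFile, simulation = simulation,
       focalTaxon = focalTaxon, benchmark = benchmark, chain = chain,
       undetectedCt = undetectedCt, outDir = outDir,
       seed = as.integer(seed))
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain any argument of [pipelineConfig()]; nested blocks
#' \code{simulation} and \code{chain} are passed through
#' [simulationConfig()] and [chainSettings()] so defaults fill in whatever
#' the file omits.
#'
#' @param path YAML file
#' @return config list for [runPipeline()]
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation))
    raw$simulation <- do.call(simulationConfig, raw$simulation)
  if (!is.null(raw$chain))
    raw$chain <- do.call(chainSettings, raw$chain)
  do.call(pipelineConfig, raw)
}

.susceptibility_suite <- function() list(
  dist_phylo = list(fixed = "focal_distance",
                    random = c("phylo", "species")),
  dist = list(fixed = "focal_distance", random = "species"),
  phylo = list(fixed = character(), random = c("phylo", "species")),
  null = list(fixed = character(), random = "species"))

.transmission_suite <- function() {
  out <- list()
  for (ct in c(TRUE, FALSE)) for (dist in c(TRUE, FALSE))
    for (ph in c(TRUE, FALSE)) {
      fixed <- c(if (ct) "passage0_ct", if (dist) "focal_distance")
      random <- c(if (ph) "phylo", "species", "strain")
      id <- paste0(if (ct) "ct_" else "", if (dist) "dist_" else "",
                   if (ph) "phylo" else "base")
      out[[id]] <- list(fixed = if (is.null(fixed)) character() else fixed,
                        random = random)
    }
  out
}

.stage_log <- function(con, stage, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  writeLines(line, con)
  flush(con)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full host-range analysis
#'
#' One call reproduces the whole analysis: susceptibility threshold and
#' calls from the Ct table, transmission scores from the passage
#' trajectories, the two model suites fitted by MCMC, DIC weight tables,
#' component weights for the phylogenetic terms, and the variance
#' decomposition of each suite's best (minimum-DIC) model. All artifacts
#' are written to \code{config$outDir} as TSV/JSON together with a
#' structured \code{run.log}; a stage failure aborts with the stage name
#' and preserves outputs already written. Controls and benchmarks never
#' enter the model fits.
#'
#' @param config from [pipelineConfig()]
#' @return invisibly, a list with the threshold, calls, scores, both weight
#'   tables, component-weight lists, best-model ids and R-squared summaries
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file(file.path(config$outDir, "run.log"), open = "wt")
  on.exit(close(logfile), add = TRUE)
  stage <- "setup"
  result <- tryCatch({
    .stage_log(logfile, stage, sprintf(
      "OrsayHostRange %s | R %s | seed %d",
      as.character(utils::packageVersion("OrsayHostRange")),
      paste(R.version$major, R.version$minor, sep = "."), config$seed))

    stage <- "inputs"
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      tree <- simulateYuleTree(sim$nSpecies, sim$birthRate,
                               seed = config$seed)
      focal <- if (is.null(config$focalTaxon)) tree$tip.label[1]
               else config$focalTaxon
      obs <- simulateSusceptibility(tree, sim, focal = focal,
                                    seed = config$seed + 1L)
      ct <- simulateCtAssay(obs, sim, seed = config$seed + 2L)
      ape::write.tree(tree, file.path(config$outDir, "tree.nwk"))
      writeCtTable(ct, file.path(config$outDir, "ct_table.tsv"))
      .stage_log(logfile, stage, sprintf(
        "simulated %d species, %d strains", sim$nSpecies, nrow(obs)))
    } else {
      tree <- readNewick(file = config$treeFile)
      focal <- if (is.null(config$focalTaxon)) tree$tip.label[1]
               else config$focalTaxon
      ct <- readCtTable(config$ctFile, undetectedCt = config$undetectedCt)
      obs <- NULL
      .stage_log(logfile, stage, sprintf(
        "read %d Ct records, tree with %d tips",
        nrow(ctRecords(ct)), length(tree$tip.label)))
    }
    H <- validateUltrametric(tree)
    rel <- relatednessMatrix(tree)

    stage <- "threshold"
    sigmaW <- withinStrainSd(ct)
    thr <- deriveThreshold(ct, sigmaW, benchmark = config$benchmark)
    jsonlite::write_json(thr, file.path(config$outDir, "threshold.json"),
                         auto_unbox = TRUE, digits = NA)
    .stage_log(logfile, stage, sprintf(
      "sigma_w = %.3f, benchmark-%d most-virus Ct = %.2f, tau = %.2f",
      sigmaW, config$benchmark, thr$benchmarkMaxVirusCt, thr$threshold))

    stage <- "susceptibility-calls"
    calls <- callSusceptibility(ct, thr)
    .write_tsv(calls, file.path(config$outDir, "susceptibility_calls.tsv"))
    .stage_log(logfile, stage, sprintf(
      "%d of %d strains susceptible", sum(calls$susceptible), nrow(calls)))

    stage <- "observations"
    if (is.null(obs)) {
      d <- distanceFromFocal(tree, focal)
      on_tree <- calls$species %in% tree$tip.label
      if (any(!on_tree)) {
        excluded <- calls$strain[!on_tree]
        .stage_log(logfile, stage, paste(
          "excluding strains whose species lack a tree position:",
          paste(excluded, collapse = ", ")))
      }
      obs <- calls[on_tree, ]
      obs$focal_distance <- unname(d[obs$species])
    }
    .write_tsv(obs, file.path(config$outDir, "observations.tsv"))

    stage <- "transmission-scores"
    if (!is.null(config$simulation)) {
      susc <- calls[calls$susceptible, ]
      rec <- ctRecords(ct)
      scores <- NULL
      if (nrow(susc)) {
        p0 <- vapply(susc$strain, function(s) {
          v <- rec$ct[rec$strain == s & rec$role == "experimental"]
          if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
        }, numeric(1))
        lines <- data.frame(line_id = paste0(susc$strain, "_L1"),
                            strain = susc$strain, passage0_ct = p0)
        traj <- simulatePassageTrajectories(
          lines, config$simulation, threshold = thr$threshold,
          seed = config$seed + 3L)
        .write_tsv(traj, file.path(config$outDir, "trajectories.tsv"))
        scores <- scoreTransmissionTable(traj)
      }
    } else if (!is.null(config$trajectoryFile)) {
      traj <- readTrajectories(config$trajectoryFile)
      scores <- scoreTransmissionTable(traj)
    } else scores <- NULL
    if (!is.null(scores)) {
      .write_tsv(scores, file.path(config$outDir, "transmission_scores.tsv"))
      .stage_log(logfile, stage, sprintf(
        "%d lines scored (mean score %.2f)", nrow(scores),
        mean(scores$score)))
    } else .stage_log(logfile, stage, "no transmission data")

    stage <- "susceptibility-models"
    suite <- .susceptibility_suite()
    fits <- list()
    for (i in seq_along(suite)) {
      m <- suite[[i]]
      ch <- config$chain
      ch$seed <- config$seed + 100L + i
      fits[[names(suite)[i]]] <- fitPMM(
        obs, fixed = m$fixed, random = m$random, rel = rel,
        family = "binomial", chain = ch)
      .stage_log(logfile, stage, sprintf(
        "model %s: DIC %.2f", names(suite)[i],
        dic(fits[[names(suite)[i]]])))
    }
    sus_dic <- vapply(fits, dic, numeric(1))
    sus_wt <- dicWeights(dic = sus_dic, formulas = suite)
    wt_tab <- weightTable(sus_wt)
    wt_tab$delta <- sprintf("%.3f", wt_tab$delta)
    wt_tab$weight <- sprintf("%.3f", wt_tab$weight)
    .write_tsv(wt_tab, file.path(config$outDir,
                                 "susceptibility_dic_weights.tsv"))
    sus_comp <- list(
      focal_distance = componentWeight(sus_wt, "focal_distance"),
      phylo = componentWeight(sus_wt, "phylo"),
      any_phylogenetic = anyComponentWeight(
        sus_wt, c("focal_distance", "phylo")))
    for (nm in names(fits))
      jsonlite::write_json(
        list(model = nm, dic = dic(fits[[nm]]),
             summary = fitSummary(fits[[nm]]),
             settings = fits[[nm]]@settings),
        file.path(config$outDir, paste0("fit_susceptibility_", nm, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    best_sus <- names(which.min(sus_dic))
    r2_sus <- rSquaredComponents(fits[[best_sus]])
    jsonlite::write_json(
      list(best_model = best_sus, components = sus_comp,
           r_squared = r2_sus$summary),
      file.path(config$outDir, "susceptibility_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")

    stage <- "transmission-models"
    trans <- list(weights = NULL, components = NULL, best = NULL, r2 = NULL)
    if (!is.null(scores) && nrow(scores) >= 3) {
      sdat <- merge(scores, obs[, c("strain", "species", "focal_distance")],
                    by = "strain")
      sdat$passage0_ct[is.na(sdat$passage0_ct)] <- config$undetectedCt
      tsuite <- .transmission_suite()
      tfits <- list()
      for (i in seq_along(tsuite)) {
        m <- tsuite[[i]]
        ch <- config$chain
        ch$seed <- config$seed + 200L + i
        tfits[[names(tsuite)[i]]] <- fitPMM(
          sdat, fixed = m$fixed, random = m$random, rel = rel,
          family = "gaussian", response = "score", chain = ch)
        .stage_log(logfile, stage, sprintf(
          "model %s: DIC %.2f", names(tsuite)[i],
          dic(tfits[[names(tsuite)[i]]])))
      }
      t_dic <- vapply(tfits, dic, numeric(1))
      t_wt <- dicWeights(dic = t_dic, formulas = tsuite)
      twt_tab <- weightTable(t_wt)
      twt_tab$delta <- sprintf("%.3f", twt_tab$delta)
      twt_tab$weight <- sprintf("%.3f", twt_tab$weight)
      .write_tsv(twt_tab, file.path(config$outDir,
                                    "transmission_dic_weights.tsv"))
      t_comp <- list(
        passage0_ct = componentWeight(t_wt, "passage0_ct"),
        focal_distance = componentWeight(t_wt, "focal_distance"),
        phylo = componentWeight(t_wt, "phylo"),
        any_phylogenetic = anyComponentWeight(
          t_wt, c("focal_distance", "phylo")))
      best_t <- names(which.min(t_dic))
      r2_t <- rSquaredComponents(tfits[[best_t]])
      jsonlite::write_json(
        list(best_model = best_t, components = t_comp,
             r_squared = r2_t$summary),
        file.path(config$outDir, "transmission_report.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      trans <- list(weights = t_wt, components = t_comp, best = best_t,
                    r2 = r2_t$summary)
    } else {
      .stage_log(logfile, stage,
                 "fewer than 3 scored lines; transmission suite skipped")
    }

    .stage_log(logfile, "done", "pipeline complete")
    list(threshold = thr, calls = calls, scores = scores,
         susceptibility = list(weights = sus_wt, components = sus_comp,
                               best = best_sus, r2 = r2_sus$summary,
                               dic = sus_dic),
         transmission = trans, outDir = config$outDir)
  }, error = function(e) {
    .stage_log(logfile, stage, paste("FAILED:", conditionMessage(e)))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
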