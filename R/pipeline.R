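#' Full pipeline configuration
#'
#' Bundles every module's settings plus the master seed. The resolved
#' configuration is written alongside every pipeline run's outputs, so each
#' output directory records exactly what produced it.
#'
#' @param W Window length (default 13; predictors in the field use up to
#'   21, so this is configurable, never hard-coded).
#' @param scoring A [ScoringParams-class].
#' @param cutHeight Dendrogram cut height, or `NULL` for
#'   [defaultCutHeight].
#' @param cutIdentity Identity fraction used by [defaultCutHeight] when
#'   `cutHeight` is `NULL`.
#' @param assembly An [assemblyConfig].
#' @param nReplicas,frac Replica-set parameters (default 1000 balanced
#'   replicas of 70% of positives).
#' @param pseudocount,evalueMax,nNull Profile-baseline parameters.
#' @param synthetic A [syntheticConfig].
#' @param evalSplits Splits to evaluate predictors on.
#' @param seed Master seed for every downstream random stream.
#' @return A classed list.
#' @export
runConfig <- function(W = 13L, scoring = ScoringParams(), cutHeight = NULL,
                      cutIdentity = 0.7, assembly = assemblyConfig(),
                      nReplicas = 1000L, frac = 0.7, pseudocount = 0.02,
                      evalueMax = 1.0, nNull = 10000L,
                      synthetic = syntheticConfig(),
                      evalSplits = c("Literature", "MS", "MS-collagen",
                                     "MS-noncollagen"),
                      seed = 1L) {
  structure(list(W = as.integer(W), scoring = scoring, cutHeight = cutHeight,
                 cutIdentity = cutIdentity, assembly = assembly,
                 nReplicas = as.integer(nReplicas), frac = frac,
                 pseudocount = pseudocount, evalueMax = evalueMax,
                 nNull = as.integer(nNull), synthetic = synthetic,
                 evalSplits = evalSplits, seed = as.integer(seed)),
            class = "RunConfig")
}

PIPELINE_STAGES <- c("simulate", "build-dataset", "cluster", "replicas",
                     "evaluate", "baseline-profile", "characterize")

resolvedConfigList <- function(config) {
  list(W = config$W,
       scoring = list(matrix = config$scoring@matrixName,
                      gap_open = config$scoring@gapOpen,
                      gap_extend = config$scoring@gapExtend),
       cut_height = config$cutHeight, cut_identity = config$cutIdentity,
       assembly = unclass(config$assembly),
       n_replicas = config$nReplicas, frac = config$frac,
       pseudocount = config$pseudocount, evalue_max = config$evalueMax,
       n_null = config$nNull,
       synthetic = lapply(unclass(config$synthetic), function(x)
         if (is.numeric(x) && length(x) > 1) as.list(x) else x),
       eval_splits = config$evalSplits, seed = config$seed)
}

#' Run the benchmark pipeline
#'
#' Chains the pipeline stages (`simulate`, `build-dataset`, `cluster`,
#' `replicas`, `evaluate`, `baseline-profile`, `characterize`) on the
#' synthetic benchmark, writing all artifacts plus the resolved
#' configuration and seed into `outDir`. Each stage consumes only the state
#' of earlier stages; requesting a stage whose inputs have not been built is
#' an error naming the missing stage. Re-running with the same configuration
#' and seed reproduces every output byte for byte.
#'
#' @param outDir Output directory (created if needed).
#' @param config A [runConfig].
#' @param stages Character vector of stages, or `"all"`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the pipeline state (proteome,
#'   annotations, clustering, splits, metrics, ...).
#' @export
runPipeline <- function(outDir, config = runConfig(), stages = "all",
                        quiet = FALSE) {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop("unknown stage '", unknown[1], "'; known stages: ",
         paste(PIPELINE_STAGES, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  st <- list(config = config)
  yaml::write_yaml(resolvedConfigList(config),
                   file.path(outDir, "resolved_config.yaml"))

  need <- function(what, stage) {
    if (is.null(st[[what]]))
      stop("stage needs '", what, "' but stage '", stage,
           "' has not been run in this call")
    st[[what]]
  }

  if ("simulate" %in% stages) {
    syn <- config$synthetic
    syn$seed <- deriveSeed(config$seed, 11L)
    gen <- generateProteome(syn)
    st$proteome <- gen$proteome
    st$annotations <- gen$annotations
    st$truth <- gen$truth
    paths <- writeBenchmarkInputs(gen$proteome, gen$annotations, outDir)
    write.table(gen$truth, file.path(outDir, "truth_manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    st$inputPaths <- paths
    say(sprintf("simulate: %d proteins, %d candidate prolines, %d positives",
                length(gen$proteome), nrow(gen$annotations),
                sum(gen$annotations$label == "positive")))
  }

  if ("build-dataset" %in% stages) {
    paths <- need("inputPaths", "simulate")
    loaded <- readProteome(paths$fasta, paths$annotations, paths$tracks)
    st$proteome <- loaded$proteome
    st$annotations <- loaded$annotations
    sites <- splitSiteKey(unique(st$annotations$key))
    st$windows <- siteWindows(st$proteome, sites, config$W)
    writeWindowsTSV(st$windows, file.path(outDir, "site_windows.tsv"))
    say(sprintf("build-dataset: %d site windows of width %d (%d rejected rows)",
                length(st$windows), config$W, nrow(loaded$rejected)))
  }

  if ("cluster" %in% stages) {
    windows <- need("windows", "build-dataset")
    S <- siteScoreMatrix(windows, config$scoring)
    st$distance <- scoreToDistance(S)
    ch <- if (is.null(config$cutHeight))
      defaultCutHeight(st$distance, config$cutIdentity) else config$cutHeight
    st$clustering <- clusterSites(st$distance, ch)
    say(sprintf("cluster: %d clusters at cut height %.2f",
                max(clusterIDs(st$clustering)), ch))
  }

  if ("replicas" %in% stages) {
    clustering <- need("clustering", "cluster")
    st$splits <- buildSplits(st$annotations, clustering, st$proteome,
                             config$assembly)
    write.table(splitSummary(st$splits, clustering),
                file.path(outDir, "split_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    st$replicas <- list()
    for (nm in config$evalSplits) {
      st$replicas[[nm]] <- makeReplicas(st$splits, nm, config$nReplicas,
                                        config$frac,
                                        deriveSeed(config$seed, 23L))
    }
    say(sprintf("replicas: %d x %d replicas (%s); %d negatives removed",
                length(st$replicas), config$nReplicas,
                paste(config$evalSplits, collapse = ", "),
                st$splits@meta$nNegativesRemoved))
  }

  if ("evaluate" %in% stages) {
    replicas <- need("replicas", "replicas")
    keys <- siteKeys(need("windows", "build-dataset"))
    litTrain <- splitPositives(st$splits, "Literature")
    preds <- list(
      random = randomBaseline(keys, 0.5, deriveSeed(config$seed, 31L)),
      memorizer = simulatePredictor(
        st$windows, litTrain, lambda = 1, epsilon = 0.02,
        seed = deriveSeed(config$seed, 37L), params = config$scoring,
        method = "memorizer"),
      generalizer = simulatePredictor(
        st$windows, litTrain, lambda = 0.5, g = 0.9,
        motif = config$synthetic$oldMotif, epsilon = 0.02,
        seed = deriveSeed(config$seed, 41L), params = config$scoring,
        method = "generalizer"))
    preds$consensus <- consensusBaseline(preds)
    rows <- list()
    for (nm in names(replicas)) {
      for (m in names(preds)) {
        ev <- evaluatePredictor(preds[[m]], replicas[[nm]])
        s <- ev$summary
        s$method <- m; s$level <- NA_character_; s$split <- nm
        s$nReplicas <- nReplicas(replicas[[nm]])
        s$seed <- config$seed
        rows[[paste(nm, m)]] <- s
      }
    }
    st$predictions <- preds
    st$metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    writeMetricsJSON(st$metrics, file.path(outDir, "metrics.json"))
    say(sprintf("evaluate: %d predictor x split combinations",
                length(rows)))
  }

  if ("baseline-profile" %in% stages) {
    clustering <- need("clustering", "cluster")
    bg <- backgroundFrequencies(st$proteome)
    db <- buildProfiles(clustering, st$windows, st$annotations, bg,
                        config$pseudocount, config$evalueMax)
    db <- calibrateNull(db, config$nNull, deriveSeed(config$seed, 43L))
    st$profileDB <- db
    scan <- scanSites(st$windows, db)
    scan$method <- "naive-profile"
    st$profileScan <- scan
    writeProfilesTSV(db, file.path(outDir, "profile_db.tsv"))
    rows <- list()
    for (nm in names(st$replicas)) {
      ev <- evaluatePredictor(scan, st$replicas[[nm]])
      s <- ev$summary
      s$method <- "naive-profile"; s$level <- NA_character_; s$split <- nm
      s$nReplicas <- nReplicas(st$replicas[[nm]])
      s$seed <- config$seed
      rows[[nm]] <- s
    }
    st$metrics <- rbind(st$metrics,
                        do.call(rbind, c(rows, list(make.row.names = FALSE))))
    writeMetricsJSON(st$metrics, file.path(outDir, "metrics.json"))
    say(sprintf("baseline-profile: %d profiles, calibrated on %d null windows",
                profileCount(db), config$nNull))
  }

  if ("characterize" %in% stages) {
    windows <- need("windows", "build-dataset")
    splits <- need("splits", "replicas")
    keys <- siteKeys(windows)
    rowsFreq <- list()
    for (nm in c("Literature", "MS")) {
      pos <- splitPositives(splits, nm)
      sub <- windows[match(pos, keys)]
      fp <- residueFrequencyProfile(sub)
      df <- as.data.frame(as.table(fp))
      names(df) <- c("position", "symbol", "frequency")
      df$split <- nm
      rowsFreq[[nm]] <- df
    }
    write.table(do.call(rbind, rowsFreq),
                file.path(outDir, "residue_frequencies.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    content <- data.frame(
      key = keys,
      proline = siteContent(windows, st$proteome, "proline"),
      disorder = siteContent(windows, st$proteome, "disorder"),
      low_complexity = siteContent(windows, st$proteome, "low_complexity"))
    write.table(content, file.path(outDir, "site_content.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    dens <- sitesPerProteinDensity(st$annotations)
    write.table(data.frame(n_sites = names(dens), n_proteins = dens),
                file.path(outDir, "sites_per_protein.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("characterize: residue frequencies, site content, site density")
  }

  invisible(st)
}
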