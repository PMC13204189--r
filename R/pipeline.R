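# Declarative orchestration: a YAML (or list) run configuration drives
# simulate/ingest -> harmonize -> fit or import bundle -> project ->
# purity adjustment -> IDH-stratified survival + meta-analysis ->
# C-index benchmarking -> survival extremes, with a run manifest and a
# per-cohort sample-attrition ledger.

pipelineDefaults <- function() {
  list(ties = "efron", bootstrap_B = 1000L, extremes_low = 6,
       extremes_high = 15, imputation_warn = 0.10, seed = 1L,
       k_init = 25L, prune_min_ve = 1, top_n = 2000L)
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or an R list. Recognized top-level keys:
#' \code{simulation} (arguments to \code{\link{simConfig}}),
#' \code{cohorts} (named list of directories with expression.tsv /
#' clinical.tsv), \code{bundle} (path to an existing projection bundle),
#' \code{fit} (stand-in factorization parameters \code{k_init},
#' \code{prune_min_ve}, \code{top_n}), \code{analysis} (ties,
#' bootstrap_B, extremes_low/high, imputation_warn, seed) and
#' \code{output_dir}. Exactly one of \code{bundle} / \code{fit} may be
#' given (a missing \code{fit} means default fit parameters); unknown
#' keys are rejected.
#'
#' @param config YAML path or list.
#' @return the resolved configuration list with defaults filled in.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    stopIfNot(file.exists(config), "config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopIfNot(is.list(config), "config must be a list or a YAML path")
  known <- c("simulation", "cohorts", "bundle", "fit", "analysis",
             "output_dir")
  unknown <- setdiff(names(config), known)
  stopIfNot(length(unknown) == 0,
            "unknown config key(s): ", paste(unknown, collapse = ", "))
  stopIfNot(!is.null(config$simulation) || !is.null(config$cohorts),
            "config must provide 'simulation' or 'cohorts'")
  stopIfNot(is.null(config$bundle) || is.null(config$fit),
            "conflict: provide either 'bundle' or 'fit', not both")
  defaults <- pipelineDefaults()
  an <- config$analysis
  unknownAn <- setdiff(names(an), names(defaults))
  stopIfNot(length(unknownAn) == 0,
            "unknown analysis key(s): ", paste(unknownAn, collapse = ", "))
  config$analysis <- modifyList(defaults, if (is.null(an)) list() else an)
  if (is.null(config$fit) && is.null(config$bundle))
    config$fit <- list(k_init = config$analysis$k_init,
                       prune_min_ve = config$analysis$prune_min_ve)
  config
}

loadCohorts <- function(config) {
  if (!is.null(config$simulation)) {
    sim <- do.call(simConfig, config$simulation)
    cohorts <- simulateMulticohort(sim)
    lapply(cohorts, function(se) list(
      counts = ExpressionMatrix(SummarizedExperiment::assay(se, "counts")),
      clinical = as.data.frame(SummarizedExperiment::colData(se)),
      truth = S4Vectors::metadata(se)$truth))
  } else {
    lapply(config$cohorts, function(dir) list(
      counts = readExpression(file.path(dir, "expression.tsv")),
      clinical = read.delim(file.path(dir, "clinical.tsv"),
                            stringsAsFactors = FALSE),
      truth = NULL))
  }
}

#' Run the full prognostic-axis pipeline
#'
#' Executes the stages in order on the configured cohorts: preprocess
#' (log2 + duplicate collapse + information filter on the training
#' cohort), fit the stand-in factor model and freeze a projection bundle
#' (or import an existing bundle), harmonize and project every cohort
#' through the frozen bundle, purity-residualize and quantify
#' attenuation/stratum concordance for factor 1, build the
#' IDH-stratified Cox table with BH-FDR and pool the per-cohort factor-1
#' effects by DerSimonian-Laird (with leave-one-cohort-out), benchmark
#' the factor-1 C-index by bootstrap, and select survival extremes with
#' a log-rank comparison and a Mann-Whitney test of the purity-adjusted
#' scores between extreme groups. Writes per-stage TSV/JSON outputs, a
#' sample-attrition ledger per cohort, and a manifest; any stage failure
#' halts with the stage name.
#'
#' @param config validated configuration (see
#'   \code{\link{validateConfig}}); a path or raw list is validated
#'   first.
#' @param outputDir overrides \code{config$output_dir}.
#' @return the manifest list, invisibly (stages with timings, seeds,
#'   attrition ledger, headline results).
#' @export
runPipeline <- function(config, outputDir = NULL) {
  config <- validateConfig(config)
  outDir <- if (!is.null(outputDir)) outputDir else
    if (!is.null(config$output_dir)) config$output_dir else tempfile("run")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  an <- config$analysis
  manifest <- list(seed = an$seed, stages = list(), attrition = list())
  results <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[3]
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[3] - t0, 2))
    out
  }

  cohorts <- stage("ingest", function() loadCohorts(config))
  for (cn in names(cohorts))
    manifest$attrition[[cn]] <-
      list(input = ncol(exprValues(cohorts[[cn]]$counts)))

  prep <- stage("preprocess", function() {
    lapply(cohorts, function(co) {
      lg <- collapseDuplicateGenes(log2Transform(co$counts))
      c(co, list(log2 = lg))
    })
  })

  bundle <- stage("bundle", function() {
    if (!is.null(config$bundle)) return(importBundle(config$bundle))
    tr <- prep[[1]]
    filtered <- filterLowInformation(tr$log2,
                                     topN = config$analysis$top_n)
    sp <- zscoreFit(filtered)
    std <- zscoreApply(filtered, sp)
    model <- fitFactorModel(list(rna = std),
                            kInit = config$fit$k_init,
                            pruneMinVe = config$fit$prune_min_ve,
                            scaling = list(rna = sp))
    exportBundle(model, "rna")
  })
  writeBundle(bundle, file.path(outDir, "bundle"))

  projections <- stage("project", function() {
    lapply(names(prep), function(cn) {
      h <- harmonizeFeatures(prep[[cn]]$log2, bundle,
                             warnThreshold = an$imputation_warn)
      sc <- projectScores(h$matrix, bundle, cohort = cn)
      write.table(data.frame(sample_id = rownames(scoreMatrix(sc)),
                             scoreMatrix(sc), check.names = FALSE),
                  file.path(outDir, paste0("scores_", cn, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(scores = sc, report = h$report)
    }) |> setNames(names(prep))
  })
  for (cn in names(projections))
    manifest$attrition[[cn]]$projected <-
      nrow(scoreMatrix(projections[[cn]]$scores))

  purity <- stage("purity", function() {
    lapply(names(prep), function(cn) {
      co <- prep[[cn]]
      sens <- puritySensitivity(projections[[cn]]$scores, co$clinical)
      resid <- residualizeScores(
        projections[[cn]]$scores,
        co$clinical[, c("sample_id", "purity")])
      list(sensitivity = sens, residualized = resid)
    }) |> setNames(names(prep))
  })
  for (cn in names(purity))
    manifest$attrition[[cn]]$purity_complete <- purity[[cn]]$sensitivity$nUsed

  stratified <- stage("stratified_survival", function() {
    tab <- stratifiedCoxTable(lapply(names(prep), function(cn)
      list(clinical = prep[[cn]]$clinical,
           scores = projections[[cn]]$scores)) |> setNames(names(prep)),
      factors = "Factor1")
    write.table(tab, file.path(outDir, "stratified_cox.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tab
  })

  meta <- stage("meta_analysis", function() {
    out <- lapply(c("wildtype", "mutant"), function(st) {
      sub <- stratified[stratified$stratum == st & !is.na(stratified$p), ]
      if (nrow(sub) < 1) return(NULL)
      eff <- studyEffects(sub$cohort, sub$hr, sub$ci_low, sub$ci_high)
      pooled <- poolDL(eff)
      loco <- if (nrow(eff) >= 2) leaveOneOut(eff) else NULL
      list(pooled = pooled, loco = loco)
    }) |> setNames(c("wildtype", "mutant"))
    jsonlite::write_json(
      lapply(out, function(x) if (is.null(x)) NULL else
        list(hr = x$pooled$hr, ci = x$pooled$ci, tau2 = x$pooled$tau2,
             Q = x$pooled$Q, I2 = x$pooled$I2,
             loco_range = if (is.null(x$loco)) NULL else
               c(x$loco$minHr, x$loco$maxHr))),
      file.path(outDir, "meta.json"), auto_unbox = TRUE, digits = NA)
    out
  })

  benchmark <- stage("benchmark", function() {
    tr <- prep[[1]]
    sc <- scoreMatrix(projections[[1]]$scores)[tr$clinical$sample_id, 1]
    bootstrapC(sc, tr$clinical, B = an$bootstrap_B, seed = an$seed)
  })

  extremes <- stage("extremes", function() {
    lapply(names(prep), function(cn) {
      cl <- prep[[cn]]$clinical
      ext <- selectExtremes(cl, low = an$extremes_low,
                            high = an$extremes_high)
      if (nrow(ext) < 4 || length(unique(ext$extreme_group)) < 2)
        return(list(n = nrow(ext)))
      adj <- scoreMatrix(purity[[cn]]$residualized)
      ext <- ext[ext$sample_id %in% rownames(adj), ]
      s <- adj[ext$sample_id, 1]
      grp <- s > median(s)
      lr <- logrankTest(ext, ifelse(grp, "high", "low"))
      mw <- mwuTest(s[ext$extreme_group == "ultra_short"],
                    s[ext$extreme_group == "long"])
      list(n = nrow(ext), logrank = lr, mwu = mw)
    }) |> setNames(names(prep))
  })
  for (cn in names(extremes))
    manifest$attrition[[cn]]$extremes <- extremes[[cn]]$n

  results <- list(projections = lapply(projections, `[[`, "report"),
                  purity = lapply(purity, `[[`, "sensitivity"),
                  stratified = stratified, meta = meta,
                  benchmark = benchmark, extremes = extremes)
  manifest$results <- results
  jsonlite::write_json(
    list(seed = an$seed,
         stages = manifest$stages,
         attrition = manifest$attrition),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
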