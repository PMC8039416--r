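#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline()]. With
#' no input paths the pipeline runs self-contained on the packaged
#' manifest fixtures (the synthetic stand-ins for the cohort and
#' disease-database data); otherwise the supplied variant, score and
#' RLU tables are used. Referenced input paths must resolve when the
#' run starts.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stochastic stage.
#' @param k consensus threshold (default 10 of 12).
#' @param band_offset secretory-defect band half-width in RLU.
#' @param filter a [filterConfig()].
#' @param registry_path optional tool registry TSV; default registry
#'   otherwise.
#' @param variant_path,score_path,rlu_path optional input tables.
#' @param verbose emit per-stage progress messages.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(out_dir, seed = 42L, k = 10L, band_offset = 50,
                           filter = filterConfig(), registry_path = NULL,
                           variant_path = NULL, score_path = NULL,
                           rlu_path = NULL, verbose = TRUE) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), k = as.integer(k),
              band_offset = band_offset, filter = filter,
              registry_path = registry_path, variant_path = variant_path,
              score_path = score_path, rlu_path = rlu_path,
              verbose = isTRUE(verbose))
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipelineConfig()] arguments, with an
#' optional `filter` block (`maf_threshold`, `comparison`,
#' `population_policy`).
#'
#' @param path YAML file.
#' @return a `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  fl <- do.call(filterConfig, if (is.null(y$filter)) list() else y$filter)
  pipelineConfig(out_dir = y$out_dir %||% "col4eval_out",
                 seed = y$seed %||% 42L, k = y$k %||% 10L,
                 band_offset = y$band_offset %||% 50, filter = fl,
                 registry_path = y$registry_path,
                 variant_path = y$variant_path, score_path = y$score_path,
                 rlu_path = y$rlu_path, verbose = y$verbose %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(name, " stage: ", conditionMessage(e), call. = FALSE))
}

#' Run the full evaluation pipeline
#'
#' Executes the stages in order — simulate (or load inputs), filter,
#' classify, evaluate, roc, correlate, luciferase — writing one TSV
#' report per stage into `out_dir` and logging per-stage counts. The
#' whole run is deterministic under the configured seed: re-running
#' with an identical configuration reproduces every report byte for
#' byte.
#'
#' @param config a [pipelineConfig()] or path to a YAML config.
#' @return invisibly, a named list of the stage results and the report
#'   paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  say <- if (config$verbose) message else function(...) invisible(NULL)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  op <- function(f) file.path(config$out_dir, f)
  for (p in c(config$registry_path, config$variant_path)) {
    if (!is.null(p) && !file.exists(p))
      stop("simulate stage: input file not found: ", p, call. = FALSE)
  }
  if (!is.null(config$score_path) && !file.exists(config$score_path))
    stop("classify stage: score file not found: ", config$score_path,
         call. = FALSE)
  if (!is.null(config$rlu_path) && !file.exists(config$rlu_path))
    stop("luciferase stage: RLU file not found: ", config$rlu_path,
         call. = FALSE)

  registry <- .stage("simulate", {
    if (is.null(config$registry_path)) defaultToolRegistry()
    else readToolRegistry(config$registry_path)
  })
  params <- generatorParams(config$seed)

  inputs <- .stage("simulate", {
    if (is.null(config$variant_path)) {
      cohort <- generateFsgsCohort(config$seed, params = params)
      fx <- generateFixture(registry = registry, seed = config$seed + 1L,
                            params = params, k = config$k)
      fn <- generateFunctionalFixture(registry, config$seed + 2L, params)
      say("simulate: cohort ", nrow(cohort), " variants; strata fixture ",
          nrow(fx$variants), "; functional panel ", nrow(fn$variants))
      list(cohort = cohort, variants = fx$variants, panels = fx$panels,
           fn = fn)
    } else {
      vt <- readVariantTable(config$variant_path)
      pn <- if (is.null(config$score_path)) NULL
      else readScoreTable(config$score_path, registry)
      list(cohort = vt, variants = vt, panels = pn, fn = NULL)
    }
  })

  filtered <- .stage("filter", {
    out <- withCallingHandlers(
      filterRareMissense(inputs$cohort, config$filter),
      message = function(m) { say("filter: ", conditionMessage(m));
        invokeRestart("muffleMessage") })
    writeVariantTable(out, op("filtered_variants.tsv"))
    out
  })

  if (is.null(inputs$panels))
    stop("classify stage: no score table available", call. = FALSE)

  calls <- .stage("classify", {
    cc <- classifyCohort(inputs$panels, registry, config$k)
    utils::write.table(
      data.frame(variant_id = variantIds(cc),
                 n_deleterious = nDeleterious(cc), n_missing = nMissing(cc),
                 call = consensusCalls(cc)),
      op("consensus_calls.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    summ <- summarizeCalls(cc, inputs$variants)
    utils::write.table(summ, op("cohort_predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    say("classify: ", sum(isPredictedPathogenic(cc)), "/",
        length(variantIds(cc)), " predicted pathogenic")
    cc
  })

  report <- .stage("evaluate", {
    rep <- concordance(calls, inputs$variants)
    writeReport(rep, op("concordance.tsv"))
    say("evaluate: ", nrow(strata(rep)), " labeled strata")
    rep
  })

  roc_tab <- .stage("roc", {
    labeled <- inputs$variants$clinical_label %in% c("pathogenic", "benign")
    ids <- inputs$variants$variant_id[labeled]
    lab <- inputs$variants$clinical_label[labeled]
    rows <- lapply(toolNames(registry), function(tool) {
      spec <- toolSpec(registry, tool)
      if (spec$orientation == "categorical") return(NULL)
      sc <- inputs$panels@scores[[tool]][match(ids, inputs$panels@variantIds)]
      r <- tryCatch(rocCurve(sc, lab, spec), error = function(e) NULL)
      if (is.null(r)) return(NULL)
      cmp <- compareCutoffs(r, spec)
      data.frame(tool = tool, auc = auc(r), youden_j = youdenJ(r),
                 recommended = cmp$recommended, optimal = cmp$optimal,
                 direction = cmp$direction, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    utils::write.table(tab, op("roc_optimal_cutoffs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tab
  })

  corr <- .stage("correlate", {
    cm <- spearmanMatrix(inputs$panels, registry)
    utils::write.table(round(rho(cm), 4), op("spearman_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    cm
  })

  lucif <- .stage("luciferase", {
    rlu <- if (!is.null(config$rlu_path)) readRluTable(config$rlu_path)
    else if (!is.null(inputs$fn)) inputs$fn$rlu else NULL
    if (is.null(rlu)) {
      say("luciferase: no RLU data; stage skipped")
      NULL
    } else {
      dcN <- callSecretoryDefect(summarizeReplicates(rlu, "N"),
                                 config$band_offset)
      dcC <- callSecretoryDefect(summarizeReplicates(rlu, "C"),
                                 config$band_offset)
      both <- rbind(defectCalls(dcN), defectCalls(dcC))
      utils::write.table(both, op("defect_calls.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cmp <- suppressMessages(compareTerminals(dcN, dcC))
      utils::write.table(cmp, op("terminal_comparison.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cong <- if (!is.null(inputs$fn)) {
        fcalls <- classifyCohort(inputs$fn$panels, registry, config$k)
        functionalCongruence(dcN, fcalls, inputs$fn$variants)
      } else NULL
      if (!is.null(cong))
        utils::write.table(cong, op("functional_congruence.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      say("luciferase: ", sum(defectCalls(dcN)$defect),
          " N-terminal defect(s)")
      list(defects_N = dcN, defects_C = dcC, terminal_comparison = cmp,
           congruence = cong)
    }
  })

  invisible(list(registry = registry, filtered = filtered, calls = calls,
                 report = report, roc = roc_tab, correlation = corr,
                 luciferase = lucif, out_dir = config$out_dir))
}
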