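#' @import methods
NULL

COL4_GENES <- c("COL4A3", "COL4A4", "COL4A5")
CONSEQUENCES <- c("missense", "stop_gain", "synonymous", "other")
CLINICAL_LABELS <- c("pathogenic", "benign", "vus", "unlabeled")
VARIANT_SOURCES <- c("FSGS", "gnomAD", "ClinVar", "ARUP", "LOVD", "synthetic")
ORIENTATIONS <- c("lower_is_damaging", "higher_is_damaging", "categorical")
VOTE_LEVELS <- c("deleterious", "tolerated", "missing")
CALL_LEVELS <- c("predicted_pathogenic", "not_predicted_pathogenic")
GNOMAD_POPULATIONS <- c("afr", "amr", "asj", "eas", "fin", "nfe", "sas", "oth")

#' ToolRegistry: score semantics for a panel of in silico predictors
#'
#' Each row of the registry describes one predictor: the direction in
#' which its score indicates damage (`orientation`), its recommended
#' cutoff and whether a score exactly at the cutoff counts as damaging
#' (`cutoff_inclusive`), and, for categorical tools, which output tokens
#' count as damaging plus an ordered severity map used when ranks are
#' needed (Spearman correlation).
#'
#' @slot specs data.frame with columns `name`, `orientation`, `cutoff`,
#'   `cutoff_inclusive`, `damaging_categories` (comma-separated tokens,
#'   categorical tools only) and `category_order` (comma-separated,
#'   least to most severe).
#' @seealso [defaultToolRegistry()] for the packaged 12-tool panel.
#' @export
setClass("ToolRegistry", representation(specs = "data.frame"))

setValidity("ToolRegistry", function(object) {
  sp <- object@specs
  need <- c("name", "orientation", "cutoff", "cutoff_inclusive",
            "damaging_categories", "category_order")
  if (!all(need %in% names(sp)))
    return(paste("specs must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(sp$name))
    return("tool names must be unique")
  if (!all(sp$orientation %in% ORIENTATIONS))
    return("orientation must be lower_is_damaging, higher_is_damaging or categorical")
  cat_rows <- sp$orientation == "categorical"
  if (any(cat_rows & (is.na(sp$damaging_categories) | sp$damaging_categories == "")))
    return("categorical tools must define a nonempty damaging_categories set")
  if (any(!cat_rows & !is.finite(sp$cutoff)))
    return("numeric tools must define a finite cutoff")
  TRUE
})

#' ScorePanelSet: per-variant predictor scores
#'
#' One row per variant, one column per tool. Numeric tools hold numeric
#' scores, categorical tools hold their output tokens verbatim; `NA`
#' represents a missing prediction (the tool generated no output), which
#' is distinct from any numeric value.
#'
#' @slot variantIds character vector of unique variant keys.
#' @slot scores data.frame of scores, columns a subset of the registry.
#' @slot registry the [ToolRegistry-class] the columns resolve against.
#' @export
setClass("ScorePanelSet",
         representation(variantIds = "character",
                        scores = "data.frame",
                        registry = "ToolRegistry"))

setValidity("ScorePanelSet", function(object) {
  if (anyDuplicated(object@variantIds))
    return("duplicate variant_id in score panel")
  if (nrow(object@scores) != length(object@variantIds))
    return("scores rows must match variantIds")
  reg <- object@registry@specs
  bad <- setdiff(names(object@scores), reg$name)
  if (length(bad))
    return(paste("score columns not in registry:", paste(bad, collapse = ", ")))
  for (nm in names(object@scores)) {
    ori <- reg$orientation[reg$name == nm]
    col <- object@scores[[nm]]
    if (ori == "categorical" && !is.character(col))
      return(paste0("categorical tool ", nm, " must hold character tokens"))
    if (ori != "categorical" && !is.numeric(col))
      return(paste0("numeric tool ", nm, " must hold numeric scores"))
  }
  TRUE
})

#' ConsensusCalls: per-tool votes and the aggregate k-of-m call
#'
#' Holds the harmonized vote of every registry tool on every variant
#' (`deleterious`, `tolerated` or `missing`) together with the aggregate
#' call: a variant is `predicted_pathogenic` when at least `k` tools
#' vote deleterious. Missing votes never count toward the deleterious
#' tally and the denominator stays at the full panel size, so a variant
#' with more than `m - k` missing tools can never be called pathogenic.
#'
#' @slot variantIds character vector of variant keys.
#' @slot votes character matrix (variants x tools) of vote levels.
#' @slot nDeleterious,nTolerated,nMissing integer tallies per variant.
#' @slot call character, `predicted_pathogenic` or `not_predicted_pathogenic`.
#' @slot k integer consensus threshold (default 10 of 12).
#' @export
setClass("ConsensusCalls",
         representation(variantIds = "character",
                        votes = "matrix",
                        nDeleterious = "integer",
                        nTolerated = "integer",
                        nMissing = "integer",
                        call = "character",
                        k = "integer"))

setValidity("ConsensusCalls", function(object) {
  n <- length(object@variantIds)
  m <- ncol(object@votes)
  if (nrow(object@votes) != n) return("votes rows must match variantIds")
  if (!all(object@votes %in% VOTE_LEVELS)) return("invalid vote level")
  if (!all(object@nDeleterious + object@nTolerated + object@nMissing == m))
    return("vote tallies must sum to the number of tools")
  if (!all(object@call %in% CALL_LEVELS)) return("invalid call level")
  if (!all((object@call == "predicted_pathogenic") ==
           (object@nDeleterious >= object@k)))
    return("call must equal (nDeleterious >= k)")
  TRUE
})

#' EvaluationReport: stratified concordance against clinical labels
#'
#' One stratum per (source, gene, label class) with the number of
#' variants whose consensus call matches the clinical label. For a
#' pathogenic stratum a concordant call is `predicted_pathogenic`; for a
#' benign stratum it is an explicit `not_predicted_pathogenic`.
#'
#' @slot strata data.frame with columns `source`, `gene`, `label_class`,
#'   `n_concordant`, `n`, `fraction`.
#' @slot confusion data.frame of TP/FP/TN/FN per (source, gene) where
#'   both label classes are present.
#' @export
setClass("EvaluationReport",
         representation(strata = "data.frame", confusion = "data.frame"))

setValidity("EvaluationReport", function(object) {
  st <- object@strata
  need <- c("source", "gene", "label_class", "n_concordant", "n", "fraction")
  if (!all(need %in% names(st)))
    return(paste("strata must have columns:", paste(need, collapse = ", ")))
  if (nrow(st)) {
    if (any(st$n_concordant < 0 | st$n_concordant > st$n))
      return("0 <= n_concordant <= n violated")
    if (any(st$fraction < 0 | st$fraction > 1))
      return("fraction must lie in [0, 1]")
  }
  TRUE
})

#' RocCurve: threshold sweep, AUC and the Youden-optimal cutoff
#'
#' @slot tool tool name.
#' @slot points data.frame (`threshold`, `tpr`, `fpr`), one row per
#'   candidate threshold swept over the observed scores.
#' @slot auc area under the curve in [0, 1].
#' @slot optimalThreshold the threshold maximizing Youden's J = TPR - FPR;
#'   ties broken by smaller FPR, then by the stricter threshold.
#' @slot youdenJ the maximal J.
#' @slot nMissing number of variants excluded for missing scores.
#' @export
setClass("RocCurve",
         representation(tool = "character", points = "data.frame",
                        auc = "numeric", optimalThreshold = "numeric",
                        youdenJ = "numeric", nMissing = "integer"))

#' ToolCorrelation: pairwise-complete Spearman matrix over the panel
#'
#' Raw (un-reoriented) scores are rank-correlated; categorical tools are
#' ranked through their ordered severity categories. Cells with fewer
#' than 3 complete pairs are undefined (`NA`).
#'
#' @slot rho symmetric matrix of Spearman coefficients.
#' @slot nPairs matrix of pairwise-complete observation counts.
#' @export
setClass("ToolCorrelation",
         representation(rho = "matrix", nPairs = "matrix"))

setValidity("ToolCorrelation", function(object) {
  r <- object@rho
  if (!isTRUE(all.equal(r, t(r), check.attributes = FALSE)))
    return("rho must be symmetric")
  fin <- r[is.finite(r)]
  if (length(fin) && any(fin < -1 - 1e-12 | fin > 1 + 1e-12))
    return("rho entries must lie in [-1, 1]")
  TRUE
})

#' DefectCalls: band-rule secretory-defect decisions per mutant
#'
#' A mutant is called defective when its mean secreted signal falls
#' below its mean intracellular signal minus `bandOffset` relative light
#' units, i.e. under the Y = X - band line of the wild-type-referenced
#' scatter (X = intracellular RLU, Y = secreted RLU).
#'
#' @slot calls data.frame with columns `mutant_id`, `gene`, `terminal`,
#'   `label`, `mean_intracellular`, `mean_secreted`, `n_replicates`,
#'   `defect`.
#' @slot bandOffset positive band half-width in RLU (default 50).
#' @export
setClass("DefectCalls",
         representation(calls = "data.frame", bandOffset = "numeric"))

setValidity("DefectCalls", function(object) {
  if (object@bandOffset <= 0) return("bandOffset must be > 0")
  cl <- object@calls
  need <- c("mutant_id", "terminal", "mean_intracellular", "mean_secreted",
            "n_replicates", "defect")
  if (!all(need %in% names(cl)))
    return(paste("calls must have columns:", paste(need, collapse = ", ")))
  if (nrow(cl)) {
    ok <- cl$defect == (cl$mean_secreted < cl$mean_intracellular - object@bandOffset)
    if (!all(ok)) return("defect flag inconsistent with the band rule")
  }
  TRUE
})
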