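#' Concordance of consensus calls with clinical labels
#'
#' Stratifies the labeled variants by (source, gene, label class) and
#' counts, per stratum, the calls that match the label: a pathogenic
#' variant is concordant when called `predicted_pathogenic`, a benign
#' variant when called `not_predicted_pathogenic` (so a benign variant
#' whose panel is mostly missing still counts as discordant — lack of
#' output is never credited as a benign call). VUS and unlabeled
#' variants are excluded; empty strata are omitted. A confusion table
#' (TP/FP/TN/FN) is attached for each (source, gene) with both classes
#' present.
#'
#' @param calls a [ConsensusCalls-class].
#' @param variants a variant table resolving every call's variant id.
#' @return an [EvaluationReport-class].
#' @export
concordance <- function(calls, variants) {
  i <- match(calls@variantIds, variants$variant_id)
  if (anyNA(i))
    stop("unresolved variant_id(s): ",
         paste(utils::head(calls@variantIds[is.na(i)], 10), collapse = ", "))
  df <- data.frame(source = variants$source[i], gene = variants$gene[i],
                   label_class = variants$clinical_label[i],
                   pred = isPredictedPathogenic(calls),
                   stringsAsFactors = FALSE)
  df <- df[df$label_class %in% c("pathogenic", "benign"), , drop = FALSE]
  .buildReport(df)
}

.buildReport <- function(df) {
  if (nrow(df) == 0)
    return(new("EvaluationReport",
               strata = data.frame(source = character(), gene = character(),
                                   label_class = character(),
                                   n_concordant = integer(), n = integer(),
                                   fraction = numeric()),
               confusion = data.frame()))
  df$conc <- ifelse(df$label_class == "pathogenic", df$pred, !df$pred)
  key <- interaction(df$source, df$gene, df$label_class, drop = TRUE)
  pieces <- lapply(split(df, key), function(s)
    data.frame(source = s$source[1], gene = s$gene[1],
               label_class = s$label_class[1],
               n_concordant = sum(s$conc), n = nrow(s),
               stringsAsFactors = FALSE))
  st <- do.call(rbind, pieces)
  st$fraction <- st$n_concordant / st$n
  st <- st[order(st$source, st$gene, st$label_class), , drop = FALSE]
  rownames(st) <- NULL
  gk <- interaction(df$source, df$gene, drop = TRUE)
  conf <- do.call(rbind, lapply(split(df, gk), function(s) {
    if (length(unique(s$label_class)) < 2) return(NULL)
    data.frame(source = s$source[1], gene = s$gene[1],
               TP = sum(s$label_class == "pathogenic" & s$pred),
               FN = sum(s$label_class == "pathogenic" & !s$pred),
               FP = sum(s$label_class == "benign" & s$pred),
               TN = sum(s$label_class == "benign" & !s$pred),
               stringsAsFactors = FALSE)
  }))
  if (is.null(conf)) conf <- data.frame()
  rownames(conf) <- NULL
  new("EvaluationReport", strata = st, confusion = conf)
}

#' Accessors for EvaluationReport
#'
#' @param object an [EvaluationReport-class].
#' @return `strata`: the per-(source, gene, label class) concordance
#'   table; `confusion`: TP/FP/TN/FN per (source, gene).
#' @export
strata <- function(object) object@strata

#' @rdname strata
#' @export
confusion <- function(object) object@confusion

setMethod("show", "EvaluationReport", function(object) {
  st <- object@strata
  cat("EvaluationReport:", nrow(st), "strata\n")
  if (nrow(st)) {
    st$display <- sprintf("%d/%d (%.1f%%)", st$n_concordant, st$n,
                          100 * st$fraction)
    print(st[c("source", "gene", "label_class", "display")],
          row.names = FALSE)
  }
})

#' Single-tool concordance evaluation
#'
#' Evaluates one predictor on its own: each variant's vote comes from
#' [binarizeScore()] for that tool alone, and a missing vote is
#' concordant with neither class — a tool that fails to generate output
#' is penalized on both the pathogenic and the benign side. This is the
#' evaluation mode used for M-CAP-only analysis of disease-database
#' variants.
#'
#' @param panels a [ScorePanelSet-class].
#' @param variants a variant table resolving every panel id.
#' @param tool tool name.
#' @param registry a [ToolRegistry-class]; defaults to the panel's own.
#' @return an [EvaluationReport-class].
#' @export
singleToolEval <- function(panels, variants, tool,
                           registry = panels@registry) {
  i <- match(panels@variantIds, variants$variant_id)
  if (anyNA(i))
    stop("unresolved variant_id(s): ",
         paste(utils::head(panels@variantIds[is.na(i)], 10), collapse = ", "))
  score <- if (tool %in% names(panels@scores)) panels@scores[[tool]] else
    rep(NA, length(panels@variantIds))
  vote <- binarizeScore(registry, tool, score)
  df <- data.frame(source = variants$source[i], gene = variants$gene[i],
                   label_class = variants$clinical_label[i],
                   stringsAsFactors = FALSE)
  df <- cbind(df, vote = vote)
  df <- df[df$label_class %in% c("pathogenic", "benign"), , drop = FALSE]
  # pred=TRUE counts for pathogenic strata; a missing vote matches neither,
  # so encode it as pred=TRUE for benign rows and pred=FALSE for pathogenic.
  df$pred <- ifelse(df$vote == "deleterious", TRUE,
                    ifelse(df$vote == "tolerated", FALSE,
                           df$label_class == "benign"))
  .buildReport(df[c("source", "gene", "label_class", "pred")])
}

#' ROC curve with the Youden-optimal cutoff
#'
#' Sweeps every distinct observed score as a candidate threshold (plus
#' one extreme so the curve reaches (1,1)), classifying a variant as
#' damaging when its score lies strictly on the tool's damaging side of
#' the threshold. The reported optimal threshold maximizes Youden's
#' J = TPR - FPR; ties are broken by smaller FPR, then by the stricter
#' threshold. Variants with missing scores are excluded from the curve
#' and their count recorded.
#'
#' @param scores numeric score vector for one tool.
#' @param labels character vector, `"pathogenic"` / `"benign"`.
#' @param spec a single tool spec from [toolSpec()] (orientation and
#'   recommended cutoff).
#' @return a [RocCurve-class].
#' @export
rocCurve <- function(scores, labels, spec) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores)
  nmiss <- sum(!keep)
  scores <- as.numeric(scores[keep])
  labels <- labels[keep]
  pos <- labels == "pathogenic"
  if (!any(pos) || all(pos))
    stop("ROC undefined: need at least one pathogenic and one benign ",
         "variant with a non-missing score")
  lower <- spec$orientation == "lower_is_damaging"
  cand <- sort(unique(scores), decreasing = !lower)
  thresholds <- c(cand, if (lower) Inf else -Inf)
  pts <- vapply(thresholds, function(t) {
    dmg <- if (lower) scores < t else scores > t
    c(tpr = sum(dmg & pos) / sum(pos), fpr = sum(dmg & !pos) / sum(!pos))
  }, c(tpr = 0, fpr = 0))
  points <- data.frame(threshold = thresholds, tpr = pts["tpr", ],
                       fpr = pts["fpr", ])
  # trapezoid over the sweep; equals the Mann-Whitney U / (n+ * n-)
  o <- order(points$fpr, points$tpr)
  fpr0 <- c(0, points$fpr[o]); tpr0 <- c(0, points$tpr[o])
  auc <- sum(diff(fpr0) * (utils::head(tpr0, -1) + utils::tail(tpr0, -1)) / 2)
  j <- points$tpr - points$fpr
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[points$fpr[best] == min(points$fpr[best])]
  if (length(best) > 1) {
    t_best <- points$threshold[best]
    best <- best[if (lower) which.min(t_best) else which.max(t_best)]
  }
  new("RocCurve", tool = if (is.null(spec$name)) "" else spec$name,
      points = points, auc = auc,
      optimalThreshold = points$threshold[best[1]],
      youdenJ = max(j), nMissing = as.integer(nmiss))
}

#' Accessors for RocCurve
#'
#' @param object a [RocCurve-class].
#' @export
auc <- function(object) object@auc

#' @rdname auc
#' @export
optimalThreshold <- function(object) object@optimalThreshold

#' @rdname auc
#' @export
youdenJ <- function(object) object@youdenJ

#' @rdname auc
#' @export
rocPoints <- function(object) object@points

setMethod("show", "RocCurve", function(object) {
  cat("RocCurve", if (nzchar(object@tool)) paste0("[", object@tool, "]"),
      "auc =", signif(object@auc, 4),
      "optimal threshold =", signif(object@optimalThreshold, 4),
      "(J =", paste0(signif(object@youdenJ, 4), ")"), "\n")
})

#' Compare the ROC-optimal cutoff with a tool's recommendation
#'
#' Classifies the Youden-optimal threshold relative to the tool's
#' recommended cutoff under its orientation: `optimal_stricter` means
#' the optimum demands stronger evidence of damage than the
#' recommendation (e.g. a SIFT optimum near 0.004 against the
#' recommended 0.05, where scores between the two produce false
#' positives), `optimal_looser` the opposite.
#'
#' @param roc a [RocCurve-class].
#' @param spec the tool spec from [toolSpec()].
#' @return list with `recommended`, `optimal` and `direction`
#'   (`optimal_stricter` / `optimal_looser` / `equal`).
#' @export
compareCutoffs <- function(roc, spec) {
  opt <- roc@optimalThreshold
  rec <- spec$cutoff
  direction <- if (isTRUE(all.equal(opt, rec))) "equal"
  else if (spec$orientation == "lower_is_damaging") {
    if (opt < rec) "optimal_stricter" else "optimal_looser"
  } else {
    if (opt > rec) "optimal_stricter" else "optimal_looser"
  }
  list(recommended = rec, optimal = opt, direction = direction)
}

#' Cross-predictor Spearman correlation matrix
#'
#' Pairwise-complete Spearman rank correlation over the raw
#' (un-reoriented) scores of every registry tool, so tools whose scales
#' run in opposite directions (e.g. FATHMM against a higher-is-damaging
#' tool) show up as anticorrelated. Categorical tools are ranked
#' through their ordered severity categories. Cells with fewer than 3
#' complete pairs are undefined (`NA`); the diagonal is 1 wherever a
#' tool has at least 2 non-missing scores.
#'
#' @param panels a [ScorePanelSet-class].
#' @param registry a [ToolRegistry-class]; defaults to the panel's own.
#' @return a [ToolCorrelation-class].
#' @export
spearmanMatrix <- function(panels, registry = panels@registry) {
  if (length(panels@variantIds) < 2)
    stop("need at least 2 variants for a correlation matrix")
  tools <- toolNames(registry)
  m <- matrix(NA_real_, nrow = length(panels@variantIds),
              ncol = length(tools), dimnames = list(NULL, tools))
  for (tool in intersect(tools, names(panels@scores))) {
    spec <- toolSpec(registry, tool)
    col <- panels@scores[[tool]]
    m[, tool] <- if (spec$orientation == "categorical")
      as.numeric(match(col, spec$category_order)) else as.numeric(col)
  }
  rho <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  ok <- !is.na(m)
  npairs <- t(ok) %*% ok
  rho[npairs < 3] <- NA_real_
  d <- diag(rho)
  d[diag(npairs) >= 2] <- 1
  diag(rho) <- d
  new("ToolCorrelation", rho = rho,
      nPairs = matrix(as.integer(npairs), nrow = nrow(npairs),
                      dimnames = dimnames(npairs)))
}

#' Accessors for ToolCorrelation
#'
#' @param object a [ToolCorrelation-class].
#' @export
rho <- function(object) object@rho

#' @rdname rho
#' @export
nPairs <- function(object) object@nPairs

setMethod("show", "ToolCorrelation", function(object) {
  cat("ToolCorrelation over", nrow(object@rho), "tools\n")
  print(round(object@rho, 2))
})
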