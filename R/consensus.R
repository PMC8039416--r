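#' Binarize one predictor score into a vote
#'
#' A missing score yields a `missing` vote. Numeric scores are compared
#' on the tool's damaging side of its recommended cutoff: below the
#' cutoff for lower-is-damaging tools (e.g. SIFT < 0.05), above it for
#' higher-is-damaging tools, with a score exactly at the cutoff voting
#' deleterious only when the tool's documentation states an inclusive
#' boundary. Categorical tools vote deleterious when their token is in
#' the damaging category set.
#'
#' @param registry a [ToolRegistry-class].
#' @param tool tool name.
#' @param score numeric score vector, or character token vector for a
#'   categorical tool; `NA` means no output.
#' @return character vector of votes: `deleterious`, `tolerated` or
#'   `missing`.
#' @export
binarizeScore <- function(registry, tool, score) {
  spec <- toolSpec(registry, tool)
  if (spec$orientation == "categorical") {
    if (is.numeric(score))
      stop("type error: numeric score supplied to categorical tool ", tool)
    ifelse(is.na(score), "missing",
           ifelse(score %in% spec$damaging_categories,
                  "deleterious", "tolerated"))
  } else {
    if (is.character(score) && !all(is.na(score)))
      stop("type error: categorical token supplied to numeric tool ", tool)
    score <- as.numeric(score)
    damaging <- if (spec$orientation == "lower_is_damaging") {
      if (spec$cutoff_inclusive) score <= spec$cutoff else score < spec$cutoff
    } else {
      if (spec$cutoff_inclusive) score >= spec$cutoff else score > spec$cutoff
    }
    ifelse(is.na(score), "missing", ifelse(damaging, "deleterious", "tolerated"))
  }
}

#' Consensus classification of score panels
#'
#' Each of the registry's tools votes on each variant via
#' [binarizeScore()]; a variant is `predicted_pathogenic` when at least
#' `k` of the tools vote deleterious (default 10 of the 12-tool panel).
#' Tools absent from the panel, and tools that generated no output,
#' vote `missing`: they never count toward the deleterious tally and
#' the denominator stays at the full panel size, so a failure to
#' generate output is a classification failure, not a benign vote.
#'
#' @param panels a [ScorePanelSet-class].
#' @param registry a [ToolRegistry-class]; defaults to the panel's own.
#' @param k consensus threshold, an integer in 1..(number of tools).
#' @return a [ConsensusCalls-class], in panel order.
#' @examples
#' reg <- defaultToolRegistry()
#' sc <- data.frame(SIFT = c(0.01, 0.4), `M-CAP` = c(0.3, NA),
#'                  check.names = FALSE)
#' calls <- classifyCohort(ScorePanelSet(sc, reg, c("v1", "v2")))
#' nDeleterious(calls)
#' @export
classifyCohort <- function(panels, registry = panels@registry, k = 10L) {
  tools <- toolNames(registry)
  m <- length(tools)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 1 || k > m)
    stop("config error: k must be an integer in 1..", m)
  k <- as.integer(k)
  n <- length(panels@variantIds)
  votes <- matrix("missing", nrow = n, ncol = m,
                  dimnames = list(panels@variantIds, tools))
  for (tool in intersect(tools, names(panels@scores)))
    votes[, tool] <- binarizeScore(registry, tool, panels@scores[[tool]])
  nDel <- as.integer(rowSums(votes == "deleterious"))
  nTol <- as.integer(rowSums(votes == "tolerated"))
  nMis <- as.integer(rowSums(votes == "missing"))
  call <- as.character(ifelse(nDel >= k, "predicted_pathogenic",
                              "not_predicted_pathogenic"))
  new("ConsensusCalls", variantIds = panels@variantIds, votes = votes,
      nDeleterious = nDel, nTolerated = nTol, nMissing = nMis,
      call = unname(call), k = k)
}

#' @describeIn classifyCohort single-panel convenience wrapper.
#' @export
consensusCall <- classifyCohort

#' Accessors for ConsensusCalls
#'
#' @param object a [ConsensusCalls-class].
#' @return `variantIds`: the keys; `votes`: the variants x tools vote
#'   matrix; `nDeleterious`/`nMissing`: integer tallies;
#'   `consensusCalls`: the aggregate call vector;
#'   `isPredictedPathogenic`: logical vector.
#' @export
consensusCalls <- function(object) object@call

#' @rdname consensusCalls
#' @export
isPredictedPathogenic <- function(object) object@call == "predicted_pathogenic"

#' @rdname consensusCalls
#' @export
nDeleterious <- function(object) object@nDeleterious

#' @rdname consensusCalls
#' @export
nMissing <- function(object) object@nMissing

#' @rdname consensusCalls
#' @export
votes <- function(object) object@votes

#' @rdname consensusCalls
#' @export
variantIds <- function(object) object@variantIds

#' Per-(source, gene) summary of consensus calls
#'
#' @param calls a [ConsensusCalls-class].
#' @param variants a variant table resolving every call's id.
#' @return data.frame with columns `source`, `gene`, `n`,
#'   `n_predicted_pathogenic`, `fraction`.
#' @export
summarizeCalls <- function(calls, variants) {
  i <- match(calls@variantIds, variants$variant_id)
  if (anyNA(i))
    stop("unresolved variant_id(s): ",
         paste(utils::head(calls@variantIds[is.na(i)], 10), collapse = ", "))
  df <- data.frame(source = variants$source[i], gene = variants$gene[i],
                   pred = isPredictedPathogenic(calls))
  agg <- stats::aggregate(pred ~ source + gene, df,
                          function(x) c(n = length(x), k = sum(x)))
  out <- data.frame(source = agg$source, gene = agg$gene,
                    n = agg$pred[, "n"],
                    n_predicted_pathogenic = agg$pred[, "k"])
  out$fraction <- out$n_predicted_pathogenic / out$n
  out[order(out$source, out$gene), , drop = FALSE]
}

setMethod("show", "ConsensusCalls", function(object) {
  n <- length(object@variantIds)
  cat("ConsensusCalls on", n, "variant(s),", ncol(object@votes),
      "tools, k =", object@k, "\n")
  cat("  predicted_pathogenic:", sum(isPredictedPathogenic(object)),
      "/", n, "\n")
})
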