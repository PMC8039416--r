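#' The packaged 12-program predictor registry
#'
#' Returns the registry of the 12 in silico missense pathogenicity
#' predictors the consensus classifier votes over: SIFT,
#' PolyPhen2-HDIV, PolyPhen2-HVAR, MutationAssessor, PROVEAN, LRT,
#' FATHMM, M-CAP, MetaLR, MetaSVM, FATHMM-MKL and MutationTaster.
#'
#' Cutoffs are each tool's own documented recommendation, on its native
#' scale: SIFT calls a variant damaging below 0.05; PolyPhen-2 counts
#' "possibly" plus "probably damaging" (HDIV >= 0.453, HVAR >= 0.447);
#' MutationAssessor uses the medium/high functional-impact boundary
#' (> 1.935); PROVEAN <= -2.5 and FATHMM <= -1.5 on their
#' lower-is-damaging scales; M-CAP > 0.025; MetaLR and FATHMM-MKL
#' > 0.5; MetaSVM > 0. LRT and MutationTaster are categorical: LRT's
#' damaging token is D; MutationTaster's are A (disease causing
#' automatic) and D (disease causing), with severity order
#' P < N < D < A used only where ranks are required.
#'
#' Orientation is metadata; raw scores are never negated in storage, so
#' correlation and ROC analyses see each tool's native scale.
#'
#' @return a [ToolRegistry-class] with 12 rows.
#' @examples
#' reg <- defaultToolRegistry()
#' toolNames(reg)
#' @export
defaultToolRegistry <- function() {
  sp <- data.frame(
    name = c("SIFT", "PolyPhen2-HDIV", "PolyPhen2-HVAR", "MutationAssessor",
             "PROVEAN", "LRT", "FATHMM", "M-CAP", "MetaLR", "MetaSVM",
             "FATHMM-MKL", "MutationTaster"),
    orientation = c("lower_is_damaging", "higher_is_damaging",
                    "higher_is_damaging", "higher_is_damaging",
                    "lower_is_damaging", "categorical",
                    "lower_is_damaging", "higher_is_damaging",
                    "higher_is_damaging", "higher_is_damaging",
                    "higher_is_damaging", "categorical"),
    cutoff = c(0.05, 0.453, 0.447, 1.935, -2.5, NA, -1.5, 0.025,
               0.5, 0, 0.5, NA),
    cutoff_inclusive = c(FALSE, TRUE, TRUE, FALSE, TRUE, NA, TRUE, FALSE,
                         FALSE, FALSE, FALSE, NA),
    damaging_categories = c(NA, NA, NA, NA, NA, "D", NA, NA, NA, NA, NA, "A,D"),
    category_order = c(NA, NA, NA, NA, NA, "N,U,D", NA, NA, NA, NA, NA,
                       "P,N,D,A"),
    range_lo = c(0, 0, 0, -6, -14, NA, -16, 0, 0, -2, 0, NA),
    range_hi = c(1, 1, 1, 6, 14, NA, 17, 1, 1, 3, 1, NA),
    stringsAsFactors = FALSE)
  new("ToolRegistry", specs = sp)
}

#' @describeIn defaultToolRegistry names of the tools in a registry.
#' @param registry a [ToolRegistry-class].
#' @export
toolNames <- function(registry) registry@specs$name

#' Look up one tool's spec
#'
#' @param registry a [ToolRegistry-class].
#' @param name tool name (exact).
#' @return one-row list: name, orientation, cutoff, cutoff_inclusive,
#'   damaging_categories (character vector), category_order (character
#'   vector, least to most severe).
#' @export
toolSpec <- function(registry, name) {
  sp <- registry@specs
  i <- match(name, sp$name)
  if (is.na(i)) stop("unknown tool: ", name)
  list(name = sp$name[i],
       orientation = sp$orientation[i],
       cutoff = sp$cutoff[i],
       cutoff_inclusive = sp$cutoff_inclusive[i],
       damaging_categories = .splitTokens(sp$damaging_categories[i]),
       category_order = .splitTokens(sp$category_order[i]),
       range_lo = sp$range_lo[i],
       range_hi = sp$range_hi[i])
}

.splitTokens <- function(x) {
  if (length(x) != 1 || is.na(x) || x == "") return(character())
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Read / write a tool registry as TSV
#'
#' The registry is an editable flat file so a user can adjust a cutoff
#' or extend the panel; serializing and reloading reproduces identical
#' votes.
#'
#' @param path file path.
#' @return `readToolRegistry` returns a [ToolRegistry-class];
#'   `writeToolRegistry` is called for its side effect.
#' @export
readToolRegistry <- function(path) {
  sp <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  sp$cutoff <- as.numeric(sp$cutoff)
  sp$cutoff_inclusive <- as.logical(sp$cutoff_inclusive)
  new("ToolRegistry", specs = sp)
}

#' @rdname readToolRegistry
#' @param registry a [ToolRegistry-class].
#' @export
writeToolRegistry <- function(registry, path) {
  utils::write.table(registry@specs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(NULL)
}

setMethod("show", "ToolRegistry", function(object) {
  sp <- object@specs
  cat("ToolRegistry with", nrow(sp), "tools\n")
  cat("  numeric:    ",
      paste(sp$name[sp$orientation != "categorical"], collapse = ", "), "\n")
  cat("  categorical:",
      paste(sp$name[sp$orientation == "categorical"], collapse = ", "), "\n")
})
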