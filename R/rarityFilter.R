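#' Rarity filter configuration
#'
#' A variant is categorized as rare when its minor allele frequency in
#' the ethnically matched population is at or below 0.005 (default;
#' chosen from the low prevalence of FSGS and the recessive/dominant/
#' X-linked inheritance of COL4A3/A4/A5 disease). The comparison can be
#' switched to strict `<`, and the population used can be the carrier's
#' matched population, the maximum over all populations, or a global
#' frequency.
#'
#' @param maf_threshold frequency threshold in (0, 0.5); default 0.005.
#' @param comparison `"inclusive"` (<=, default) or `"strict"` (<).
#' @param population_policy `"carrier_matched"` (default; falls back to
#'   the across-population maximum when the carrier population is
#'   unknown), `"global_max"`, or `"global"` (the `af_global` column,
#'   falling back to the maximum when absent).
#' @param keep_consequences consequence classes retained by
#'   [filterRareMissense()]; default `"missense"`.
#' @return a `FilterConfig` list.
#' @export
filterConfig <- function(maf_threshold = 0.005,
                         comparison = c("inclusive", "strict"),
                         population_policy = c("carrier_matched",
                                               "global_max", "global"),
                         keep_consequences = "missense") {
  comparison <- match.arg(comparison)
  population_policy <- match.arg(population_policy)
  if (!is.numeric(maf_threshold) || length(maf_threshold) != 1 ||
      maf_threshold <= 0 || maf_threshold >= 0.5)
    stop("maf_threshold must lie in (0, 0.5)")
  if (!all(keep_consequences %in% CONSEQUENCES))
    stop("unknown consequence class in keep_consequences")
  structure(list(maf_threshold = maf_threshold, comparison = comparison,
                 population_policy = population_policy,
                 keep_consequences = keep_consequences),
            class = "FilterConfig")
}

# frequency selected by the population policy; NA when never observed
.policyFrequency <- function(tab, cfg) {
  afc <- afColumns(tab)
  afm <- if (length(afc)) {
    as.matrix(as.data.frame(lapply(tab[afc], as.numeric)))
  } else {
    matrix(numeric(0), nrow = nrow(tab), ncol = 0)
  }
  gmax <- if (ncol(afm)) apply(afm, 1, function(r)
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)) else
      rep(NA_real_, nrow(tab))
  if (cfg$population_policy == "global_max") return(gmax)
  if (cfg$population_policy == "global") {
    if ("af_global" %in% afc) {
      g <- as.numeric(tab$af_global)
      return(ifelse(is.na(g), gmax, g))
    }
    return(gmax)
  }
  # carrier_matched
  carrier <- if ("carrier_population" %in% names(tab))
    tab$carrier_population else rep(NA_character_, nrow(tab))
  col <- match(paste0("af_", carrier), afc)
  f <- rep(NA_real_, nrow(tab))
  has <- !is.na(col)
  if (any(has))
    f[has] <- afm[cbind(which(has), col[has])]
  fallback <- is.na(col)
  if (any(fallback & !is.na(gmax)))
    message("carrier population unknown for ", sum(fallback),
            " variant(s); falling back to across-population maximum")
  f[fallback] <- gmax[fallback]
  f
}

#' Is a variant rare?
#'
#' Applies the configured minor-allele-frequency rule to each record.
#' A variant absent from every population (no observed frequency) is
#' rare under any policy and threshold.
#'
#' @param tab a validated variant table (one or more rows).
#' @param cfg a [filterConfig()].
#' @return logical vector, one element per row.
#' @export
isRare <- function(tab, cfg = filterConfig()) {
  f <- .policyFrequency(tab, cfg)
  ifelse(is.na(f), TRUE,
         if (cfg$comparison == "inclusive") f <= cfg$maf_threshold
         else f < cfg$maf_threshold)
}

#' Filter a variant table to rare variants of the kept consequences
#'
#' Retains, in input order, the rows that are rare under the configured
#' frequency rule and whose consequence class is in
#' `cfg$keep_consequences` (missense by default; the in silico
#' prediction analyses score missense variants only). A per-gene tally
#' is reported as a message.
#'
#' @inheritParams isRare
#' @return the surviving subset of `tab`.
#' @export
filterRareMissense <- function(tab, cfg = filterConfig()) {
  if (nrow(tab) == 0) return(tab)
  keep <- isRare(tab, cfg) & tab$consequence %in% cfg$keep_consequences
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  tally <- table(factor(out$gene, levels = COL4_GENES))
  message("rare ", paste(cfg$keep_consequences, collapse = "/"),
          " survivors: ", nrow(out), " (",
          paste(sprintf("%s=%d", names(tally), as.integer(tally)),
                collapse = ", "), ")")
  out
}

#' Designate rare missense variants as pathogenic or VUS
#'
#' A rare missense variant is designated pathogenic if it has been
#' reported in other cases of kidney disease (literature or the
#' ClinVar/ARUP/LOVD disease databases); any other rare missense
#' variant is a variant of uncertain significance.
#'
#' @param tab a variant table of rare missense variants.
#' @param reported_in_other_kidney_disease logical vector, one per row.
#' @return character vector of `"pathogenic"` / `"vus"`.
#' @export
designateLabel <- function(tab, reported_in_other_kidney_disease) {
  stopifnot(length(reported_in_other_kidney_disease) == nrow(tab))
  ifelse(reported_in_other_kidney_disease, "pathogenic", "vus")
}
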