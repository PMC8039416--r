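#' Summarize split-luciferase replicates per mutant
#'
#' Arithmetic means of the intracellular and secreted relative light
#' units over a mutant's replicates (the assay is run in triplicate) at
#' the requested construct terminal. Mutants with no replicates at that
#' terminal are excluded with a warning.
#'
#' @param measurements a validated RLU table (see [readRluTable()]).
#' @param terminal `"N"` or `"C"`.
#' @return data.frame with one row per mutant: `mutant_id`, `gene`,
#'   `label`, `terminal`, `mean_intracellular`, `mean_secreted`,
#'   `n_replicates`.
#' @export
summarizeReplicates <- function(measurements, terminal = c("N", "C")) {
  terminal <- match.arg(terminal)
  all_ids <- unique(measurements$mutant_id)
  sub <- measurements[measurements$terminal == terminal, , drop = FALSE]
  absent <- setdiff(all_ids, unique(sub$mutant_id))
  if (length(absent))
    warning("mutant(s) with no replicates at terminal ", terminal,
            " excluded: ", paste(absent, collapse = ", "))
  if (nrow(sub) == 0)
    stop("no measurements at terminal ", terminal)
  pieces <- lapply(split(sub, sub$mutant_id), function(s)
    data.frame(mutant_id = s$mutant_id[1], gene = s$gene[1],
               label = s$label[1], terminal = terminal,
               mean_intracellular = mean(s$intracellular_rlu),
               mean_secreted = mean(s$secreted_rlu),
               n_replicates = nrow(s), stringsAsFactors = FALSE))
  out <- do.call(rbind, pieces[match(intersect(all_ids, names(pieces)),
                                     names(pieces))])
  rownames(out) <- NULL
  out
}

#' Band-rule secretory-defect calls
#'
#' On the wild-type-referenced scatter (X = mean intracellular RLU,
#' Y = mean secreted RLU) a mutant falling under the Y = X - band line
#' is called a significant secretory defect: it can still trimerize
#' intracellularly but is not efficiently secreted. The default band
#' half-width is 50 RLU on the plotted scale. All summaries must be on
#' a common RLU scale with the WT reference present; a dataset whose WT
#' is itself called defective is rejected as miscalibrated.
#'
#' @param summary per-mutant means from [summarizeReplicates()].
#' @param band_offset positive band half-width in RLU (default 50).
#' @param rescale_wt if `TRUE`, rescale the dataset so WT intracellular
#'   equals 100 before applying the band (off by default; the band is
#'   then interpreted on that scale).
#' @return a [DefectCalls-class].
#' @export
callSecretoryDefect <- function(summary, band_offset = 50,
                                rescale_wt = FALSE) {
  if (band_offset <= 0) stop("band_offset must be > 0")
  if (!"WT" %in% summary$mutant_id)
    stop("WT reference absent from summary")
  if (rescale_wt) {
    f <- 100 / summary$mean_intracellular[summary$mutant_id == "WT"][1]
    summary$mean_intracellular <- summary$mean_intracellular * f
    summary$mean_secreted <- summary$mean_secreted * f
  }
  defect <- summary$mean_secreted < summary$mean_intracellular - band_offset
  if (any(defect & summary$mutant_id == "WT"))
    stop("calibration error: WT reference called defective; ",
         "dataset rejected as miscalibrated")
  calls <- cbind(summary, defect = defect)
  rownames(calls) <- NULL
  new("DefectCalls", calls = calls, bandOffset = band_offset)
}

#' Accessors for DefectCalls
#'
#' @param object a [DefectCalls-class].
#' @return `defectCalls`: the per-mutant table; `bandOffset`: the band
#'   half-width in RLU.
#' @export
defectCalls <- function(object) object@calls

#' @rdname defectCalls
#' @export
bandOffset <- function(object) object@bandOffset

setMethod("show", "DefectCalls", function(object) {
  cl <- object@calls
  cat("DefectCalls (band =", object@bandOffset, "RLU):",
      sum(cl$defect), "defect(s) /", nrow(cl), "mutant(s)\n")
})

#' Compare N- and C-terminal defect calls per mutant
#'
#' Heterotrimer assembly initiates at the C-terminal NC1 domain, so
#' C-terminal tagged constructs can luminesce before folding completes
#' and may miss defects the N-terminal constructs reveal. This flags
#' each mutant whose calls at the two terminals disagree.
#'
#' @param calls_N,calls_C [DefectCalls-class] objects over the same
#'   mutant set.
#' @return data.frame per mutant: `mutant_id`, `N_defect`, `C_defect`,
#'   `discordant`.
#' @export
compareTerminals <- function(calls_N, calls_C) {
  n <- calls_N@calls; c_ <- calls_C@calls
  only_n <- setdiff(n$mutant_id, c_$mutant_id)
  only_c <- setdiff(c_$mutant_id, n$mutant_id)
  if (length(only_n) || length(only_c))
    stop("mismatched mutant sets; N-only: {",
         paste(only_n, collapse = ", "), "}, C-only: {",
         paste(only_c, collapse = ", "), "}")
  i <- match(n$mutant_id, c_$mutant_id)
  out <- data.frame(mutant_id = n$mutant_id, N_defect = n$defect,
                    C_defect = c_$defect[i], stringsAsFactors = FALSE)
  out$discordant <- out$N_defect != out$C_defect
  message(sum(out$discordant), " of ", nrow(out),
          " mutant(s) discordant between terminals")
  out
}

#' Congruence of secretory-defect calls with consensus predictions
#'
#' For each (gene, label class) stratum of the functional panel,
#' congruence is the fraction of consensus-predicted-deleterious
#' variants that also show a secretory defect:
#' `n_predicted_with_defect / n_predicted_deleterious`. With no
#' predicted-deleterious variants the congruence is undefined (`NA`),
#' not zero. N-terminal calls are the authoritative functional readout
#' here; pass N-terminal `calls`.
#'
#' @param calls a [DefectCalls-class] (WT is ignored).
#' @param consensus a [ConsensusCalls-class] covering every mutant.
#' @param variants a variant table mapping `variant_id` to gene and
#'   clinical label; mutant ids must match variant ids.
#' @return data.frame per (gene, label_class): `n_variants`,
#'   `n_predicted_deleterious`, `n_with_defect`,
#'   `n_predicted_with_defect`, `congruence`.
#' @export
functionalCongruence <- function(calls, consensus, variants) {
  cl <- calls@calls[calls@calls$mutant_id != "WT", , drop = FALSE]
  i <- match(cl$mutant_id, consensus@variantIds)
  if (anyNA(i))
    stop("mutant(s) without a consensus call: ",
         paste(cl$mutant_id[is.na(i)], collapse = ", "))
  j <- match(cl$mutant_id, variants$variant_id)
  if (anyNA(j))
    stop("mutant(s) not in the variant table: ",
         paste(cl$mutant_id[is.na(j)], collapse = ", "))
  df <- data.frame(gene = variants$gene[j],
                   label_class = variants$clinical_label[j],
                   pred = isPredictedPathogenic(consensus)[i],
                   defect = cl$defect, stringsAsFactors = FALSE)
  pieces <- lapply(split(df, interaction(df$gene, df$label_class,
                                         drop = TRUE)), function(s) {
    npred <- sum(s$pred)
    data.frame(gene = s$gene[1], label_class = s$label_class[1],
               n_variants = nrow(s), n_predicted_deleterious = npred,
               n_with_defect = sum(s$defect),
               n_predicted_with_defect = sum(s$pred & s$defect),
               congruence = if (npred > 0) sum(s$pred & s$defect) / npred
                            else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$gene, out$label_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}
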