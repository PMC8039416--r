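#' Parameters for the synthetic-data generators
#'
#' The generators emulate the three kinds of input the evaluation
#' pipeline consumes: class-conditional predictor score panels,
#' per-population allele-frequency spectra straddling the 0.005 rarity
#' cutoff, and WT-referenced split-luciferase RLU replicates with or
#' without planted secretory defects.
#'
#' @param seed integer seed; every generator is reproducible under it.
#' @param n_per_stratum data.frame (`source`, `gene`, `label_class`,
#'   `n`) for [generateScorePanels()].
#' @param score_model per-tool class-conditional score model, see
#'   [defaultScoreModel()]. All sds must be positive and missing rates
#'   in [0, 1).
#' @param af_model allele-frequency model: a point mass at
#'   never-observed (`p_absent`) mixed with a log-uniform spectrum over
#'   `[lo, hi]`.
#' @param rlu_model RLU model: wild-type intracellular and secreted
#'   means, the secreted-signal drop planted in defective mutants (must
#'   exceed the band half-width by a comfortable margin), the replicate
#'   standard deviation, and the number of replicates (triplicate).
#' @return a validated `GeneratorParams` list.
#' @export
generatorParams <- function(seed = 42L,
                            n_per_stratum = NULL,
                            score_model = defaultScoreModel(),
                            af_model = list(p_absent = 0.3, lo = 1e-6,
                                            hi = 0.05),
                            rlu_model = list(wt_intracellular = 500,
                                             wt_secreted = 500,
                                             defect_drop = 200,
                                             replicate_sd = 10,
                                             n_replicates = 3)) {
  num <- score_model[!is.na(score_model$damaging_sd), ]
  if (any(num$damaging_sd <= 0) || any(num$tolerated_sd <= 0))
    stop("validation error: all score model sds must be > 0")
  if (any(score_model$missing_rate < 0 | score_model$missing_rate > 1))
    stop("validation error: missing_rate must lie in [0, 1]")
  if (rlu_model$replicate_sd <= 0 || rlu_model$defect_drop <= 0 ||
      rlu_model$n_replicates < 1)
    stop("validation error: invalid rlu model")
  if (af_model$lo <= 0 || af_model$hi <= af_model$lo || af_model$hi > 1 ||
      af_model$p_absent < 0 || af_model$p_absent >= 1)
    stop("validation error: invalid af model")
  structure(list(seed = as.integer(seed), n_per_stratum = n_per_stratum,
                 score_model = score_model, af_model = af_model,
                 rlu_model = rlu_model),
            class = "GeneratorParams")
}

#' Default class-conditional score model
#'
#' For each numeric tool, damaging-class and tolerated-class scores are
#' drawn from normal components truncated to the tool's documented
#' native range, with the damaging component placed well inside the
#' damaging side of the recommended cutoff and the tolerated component
#' on the other side (well separated classes). Categorical tools (LRT,
#' MutationTaster) draw tokens from class-conditional category
#' frequencies held internally. Each tool independently withholds its
#' output at `missing_rate` (default 2%).
#'
#' @param registry a [ToolRegistry-class].
#' @param missing_rate shared per-tool missingness probability.
#' @return data.frame with one row per tool: `tool`, `damaging_mean`,
#'   `damaging_sd`, `tolerated_mean`, `tolerated_sd`, `missing_rate`
#'   (means/sds `NA` for categorical tools).
#' @export
defaultScoreModel <- function(registry = defaultToolRegistry(),
                              missing_rate = 0.02) {
  m <- data.frame(
    tool = c("SIFT", "PolyPhen2-HDIV", "PolyPhen2-HVAR", "MutationAssessor",
             "PROVEAN", "LRT", "FATHMM", "M-CAP", "MetaLR", "MetaSVM",
             "FATHMM-MKL", "MutationTaster"),
    damaging_mean = c(0.01, 0.97, 0.95, 4.0, -6.0, NA, -5.0, 0.30, 0.85,
                      1.0, 0.90, NA),
    damaging_sd = c(0.015, 0.05, 0.07, 0.8, 1.5, NA, 1.5, 0.10, 0.10,
                    0.4, 0.08, NA),
    tolerated_mean = c(0.40, 0.15, 0.15, 0.8, -0.5, NA, 1.5, 0.01, 0.15,
                       -0.8, 0.20, NA),
    tolerated_sd = c(0.20, 0.15, 0.15, 0.6, 0.8, NA, 1.2, 0.008, 0.10,
                     0.4, 0.15, NA),
    missing_rate = missing_rate,
    stringsAsFactors = FALSE)
  m[match(toolNames(registry), m$tool), , drop = FALSE]
}

# class-conditional token frequencies for the categorical tools
.CAT_PROBS <- list(
  "LRT" = list(damaging = c(D = 0.95, N = 0.04, U = 0.01),
               tolerated = c(N = 0.85, U = 0.10, D = 0.05)),
  "MutationTaster" = list(damaging = c(A = 0.35, D = 0.62, P = 0.02,
                                       N = 0.01),
                          tolerated = c(P = 0.60, N = 0.35, D = 0.05)))

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) return(rep((lo + hi) / 2, n))
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# draw n scores for `tool` from the class component, truncated to the
# tool's native range; when vote-constrained, truncated to the region
# that binarizes to exactly that vote
.drawScores <- function(registry, model, tool, class, n,
                        constrain_vote = FALSE) {
  if (n == 0) return(if (is.null(.CAT_PROBS[[tool]])) numeric(0)
                     else character(0))
  spec <- toolSpec(registry, tool)
  if (spec$orientation == "categorical") {
    p <- .CAT_PROBS[[tool]][[class]]
    if (constrain_vote) {
      toks <- if (class == "damaging") spec$damaging_categories
      else setdiff(spec$category_order, spec$damaging_categories)
      p <- p[names(p) %in% toks]
      if (!length(p)) p <- stats::setNames(rep(1, length(toks)), toks)
    }
    return(sample(names(p), n, replace = TRUE, prob = p))
  }
  i <- match(tool, model$tool)
  mu <- if (class == "damaging") model$damaging_mean[i] else
    model$tolerated_mean[i]
  sd <- if (class == "damaging") model$damaging_sd[i] else
    model$tolerated_sd[i]
  lo <- spec$range_lo; hi <- spec$range_hi
  if (constrain_vote) {
    damaging_low <- spec$orientation == "lower_is_damaging"
    if ((class == "damaging") == damaging_low) hi <- min(hi, spec$cutoff)
    else lo <- max(lo, spec$cutoff)
  }
  .rtruncnorm(n, mu, sd, lo, hi)
}

.randomProteinChange <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  pos <- sample(20:1680, n, replace = TRUE)
  from <- sample(aa, n, replace = TRUE)
  to <- vapply(from, function(f) sample(setdiff(aa, f), 1), character(1))
  sprintf("p.%s%d%s", from, pos, to)
}

.drawAf <- function(n, af, lo = af$lo, hi = af$hi) {
  exp(stats::runif(n, log(lo), log(hi)))
}

# build a variant table for n synthetic variants of one stratum
.makeVariants <- function(n, source, gene, label, af_model,
                          af_range = c(1e-6, 4e-3)) {
  pops <- sample(GNOMAD_POPULATIONS[1:7], n, replace = TRUE)
  pch <- .randomProteinChange(n)
  tab <- data.frame(variant_id = sprintf("%s:%s:%s", source, gene, pch),
                    gene = gene, protein_change = pch,
                    consequence = "missense",
                    carrier_population = pops,
                    clinical_label = label, source = source,
                    stringsAsFactors = FALSE)
  for (p in GNOMAD_POPULATIONS[1:7]) tab[[paste0("af_", p)]] <- NA_real_
  absent <- stats::runif(n) < af_model$p_absent
  idx <- which(!absent)
  if (length(idx)) {
    f <- .drawAf(length(idx), af_model, af_range[1], af_range[2])
    tab[cbind(idx, match(paste0("af_", pops[idx]), names(tab)))] <- f
  }
  tab
}

#' Generate class-conditional score panels
#'
#' Draws one score panel per variant for each stratum of
#' `params$n_per_stratum`: pathogenic-class variants draw every tool's
#' score from its damaging component, benign-class variants from the
#' tolerated component, and VUS variants from an equal mixture (one
#' latent class per variant). Each tool independently withholds its
#' output at its missing rate. Reproducible under the seed.
#'
#' @param params a [generatorParams()] with `n_per_stratum` set.
#' @param registry a [ToolRegistry-class].
#' @return list with `variants` (a validated variant table) and
#'   `panels` (a [ScorePanelSet-class]).
#' @export
generateScorePanels <- function(params, registry = defaultToolRegistry()) {
  if (is.null(params$n_per_stratum))
    stop("validation error: params$n_per_stratum is required")
  set.seed(params$seed)
  st <- params$n_per_stratum
  model <- params$score_model
  tools <- toolNames(registry)
  var_list <- list(); score_list <- list()
  for (r in seq_len(nrow(st))) {
    n <- st$n[r]
    vt <- .makeVariants(n, st$source[r], st$gene[r], st$label_class[r],
                        params$af_model)
    latent <- switch(st$label_class[r],
                     pathogenic = rep("damaging", n),
                     benign = rep("tolerated", n),
                     sample(c("damaging", "tolerated"), n, replace = TRUE))
    sc <- stats::setNames(vector("list", length(tools)), tools)
    for (tool in tools) {
      cat_tool <- toolSpec(registry, tool)$orientation == "categorical"
      col <- if (cat_tool) rep(NA_character_, n) else rep(NA_real_, n)
      for (cls in c("damaging", "tolerated")) {
        idx <- which(latent == cls)
        col[idx] <- .drawScores(registry, model, tool, cls, length(idx))
      }
      mr <- model$missing_rate[match(tool, model$tool)]
      col[stats::runif(n) < mr] <- NA
      sc[[tool]] <- col
    }
    var_list[[r]] <- vt
    score_list[[r]] <- as.data.frame(sc, check.names = FALSE,
                                     stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, var_list)
  variants$variant_id <- make.unique(variants$variant_id, sep = "_")
  scores <- do.call(rbind, score_list)
  list(variants = validateVariantTable(variants),
       panels = ScorePanelSet(scores, registry, variants$variant_id))
}

#' Load a packaged fixture manifest
#'
#' Three stratum-count manifests ship with the package:
#' `prediction_strata` (cohort and disease-database strata with their
#' target predicted-pathogenic counts), `functional_panel` (the
#' 17-variant functional panel with target prediction and
#' secretory-defect counts per terminal) and `fsgs_cohort` (the 70-SNV
#' cohort composition by gene, rarity and consequence).
#'
#' @param name manifest name.
#' @return data.frame.
#' @export
fixtureManifest <- function(name = c("prediction_strata",
                                     "functional_panel", "fsgs_cohort")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_manifest.tsv"),
                      package = "col4eval", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# vote-exact panel construction for one stratum: exactly n_target
# variants get >= k damaging-side votes, the rest get <= k - 1
.voteExactScores <- function(n, n_target, label, registry, model, k = 10L) {
  tools <- toolNames(registry)
  m <- length(tools)
  predicted <- seq_len(n) %in% sample(n, n_target)
  ndel <- integer(n)
  ndel[predicted] <- k + sample(0:(m - k), sum(predicted), replace = TRUE,
                                prob = c(0.5, rep(0.5 / (m - k), m - k)))
  low <- switch(label,
                pathogenic = 6:(k - 1),
                benign = 0:5,
                0:(k - 1))
  ndel[!predicted] <- sample(low, sum(!predicted), replace = TRUE)
  sc <- stats::setNames(vector("list", m), tools)
  dmat <- matrix(FALSE, n, m)
  for (i in seq_len(n)) dmat[i, sample(m, ndel[i])] <- TRUE
  for (t in seq_len(m)) {
    tool <- tools[t]
    cat_tool <- toolSpec(registry, tool)$orientation == "categorical"
    col <- if (cat_tool) rep(NA_character_, n) else rep(NA_real_, n)
    col[dmat[, t]] <- .drawScores(registry, model, tool, "damaging",
                                  sum(dmat[, t]), constrain_vote = TRUE)
    col[!dmat[, t]] <- .drawScores(registry, model, tool, "tolerated",
                                   sum(!dmat[, t]), constrain_vote = TRUE)
    # light missingness on tolerated votes of unpredicted variants only,
    # which can never change a call
    drop <- !dmat[, t] & !predicted & stats::runif(n) < 0.03
    col[drop] <- NA
    sc[[tool]] <- col
  }
  list(scores = as.data.frame(sc, check.names = FALSE,
                              stringsAsFactors = FALSE),
       predicted = predicted)
}

#' Generate a count-manifest fixture
#'
#' For every stratum row of the manifest, emits `n_total` variants of
#' which exactly `n_target_predicted_pathogenic` receive score vectors
#' with at least `k` of the panel's tools on the damaging side of their
#' cutoffs, and the remainder at most `k - 1`. Before returning, the
#' generator re-runs the consensus classifier on its own output and
#' refuses to emit data that deviates from the manifest.
#'
#' @param manifest data.frame with columns `source`, `gene`,
#'   `label_class`, `n_total`, `n_target_predicted_pathogenic`
#'   (defaults to the packaged `prediction_strata` manifest).
#' @param registry a [ToolRegistry-class].
#' @param seed integer seed.
#' @param params a [generatorParams()] for the score components.
#' @param k consensus threshold the targets are defined against.
#' @return list with `variants` and `panels`, as
#'   [generateScorePanels()].
#' @export
generateFixture <- function(manifest = fixtureManifest("prediction_strata"),
                            registry = defaultToolRegistry(),
                            seed = 42L, params = generatorParams(seed),
                            k = 10L) {
  if (any(manifest$n_target_predicted_pathogenic > manifest$n_total) ||
      any(manifest$n_target_predicted_pathogenic < 0))
    stop("infeasible manifest: need 0 <= n_target <= n_total")
  set.seed(seed)
  model <- params$score_model
  var_list <- list(); score_list <- list()
  for (r in seq_len(nrow(manifest))) {
    n <- manifest$n_total[r]
    vt <- .makeVariants(n, manifest$source[r], manifest$gene[r],
                        manifest$label_class[r], params$af_model)
    vs <- .voteExactScores(n, manifest$n_target_predicted_pathogenic[r],
                           manifest$label_class[r], registry, model, k)
    var_list[[r]] <- vt
    score_list[[r]] <- vs$scores
  }
  variants <- do.call(rbind, var_list)
  variants$variant_id <- make.unique(variants$variant_id, sep = "_")
  scores <- do.call(rbind, score_list)
  panels <- ScorePanelSet(scores, registry, variants$variant_id)
  # self-verification: the emitted fixture must reproduce its manifest
  calls <- classifyCohort(panels, registry, k)
  pred <- isPredictedPathogenic(calls)
  off <- 0L
  for (r in seq_len(nrow(manifest))) {
    sel <- variants$source == manifest$source[r] &
      variants$gene == manifest$gene[r] &
      variants$clinical_label == manifest$label_class[r]
    if (sum(pred[sel]) != manifest$n_target_predicted_pathogenic[r])
      off <- off + 1L
  }
  if (off > 0)
    stop("internal error: fixture failed self-verification on ", off,
         " stratum/strata")
  list(variants = validateVariantTable(variants), panels = panels)
}

#' Generate the annotated FSGS cohort variant table
#'
#' Emits a 70-SNV cohort table matching the packaged `fsgs_cohort`
#' manifest: per gene, the stated numbers of rare missense variants
#' (all population frequencies at or below 0.004, or never observed),
#' rare stop-gains, and common variants (frequencies above 0.005 in
#' every observed population; half missense, half synonymous), with
#' carrier populations drawn from the gnomAD ancestry keys. The rarity
#' filter then recovers the manifest's rare missense counts exactly,
#' under either frequency comparison mode and any population policy;
#' the generator verifies this before returning.
#'
#' @param seed integer seed.
#' @param manifest data.frame, defaults to the packaged `fsgs_cohort`.
#' @param params a [generatorParams()] for the frequency spectrum.
#' @return a validated variant table.
#' @export
generateFsgsCohort <- function(seed = 42L,
                               manifest = fixtureManifest("fsgs_cohort"),
                               params = generatorParams(seed)) {
  set.seed(seed)
  af <- params$af_model
  pieces <- list()
  for (r in seq_len(nrow(manifest))) {
    g <- manifest$gene[r]
    rare_mis <- .makeVariants(manifest$n_rare_missense[r], "FSGS", g,
                              "unlabeled", af, af_range = c(af$lo, 4e-3))
    pieces[[length(pieces) + 1]] <- rare_mis
    if (manifest$n_rare_stopgain[r] > 0) {
      sg <- .makeVariants(manifest$n_rare_stopgain[r], "FSGS", g,
                          "unlabeled", af, af_range = c(af$lo, 4e-3))
      sg$consequence <- "stop_gain"
      sg$protein_change <- sub("[A-Z]$", "*", sg$protein_change)
      sg$variant_id <- sprintf("FSGS:%s:%s", g, sg$protein_change)
      pieces[[length(pieces) + 1]] <- sg
    }
    n_com <- manifest$n_common[r]
    com <- .makeVariants(n_com, "FSGS", g, "unlabeled",
                         list(p_absent = 0, lo = af$lo, hi = af$hi),
                         af_range = c(6e-3, 5e-2))
    com$consequence <- rep_len(c("missense", "synonymous"), n_com)
    pieces[[length(pieces) + 1]] <- com
  }
  tab <- do.call(rbind, pieces)
  rownames(tab) <- NULL
  tab$variant_id <- make.unique(tab$variant_id, sep = "_")
  surv <- suppressMessages(filterRareMissense(tab, filterConfig()))
  got <- table(factor(surv$gene, levels = manifest$gene))
  if (!all(as.integer(got) == manifest$n_rare_missense))
    stop("internal error: cohort fixture failed self-verification")
  validateVariantTable(tab)
}

#' Generate split-luciferase RLU replicates with planted defects
#'
#' Builds replicate measurements per the mutant plan. The wild type
#' sits on the Y = X line of the intracellular/secreted scatter;
#' mutants without a planted defect stay inside the +/- band, and
#' planted-defect mutants have their secreted mean dropped by
#' `defect_drop` RLU below their intracellular mean — far enough below
#' the band that replicate noise cannot lift them back over it.
#' Replicate noise is normal with sd `replicate_sd`, floored at 0 RLU.
#' The generator verifies its own band-rule calls against the plan
#' before returning.
#'
#' @param params a [generatorParams()] (the `rlu_model` component).
#' @param plan data.frame with columns `mutant_id`, `gene`, `terminal`,
#'   `label`, `plant_defect`; one WT row per (gene, terminal) dataset
#'   is required.
#' @param seed integer seed.
#' @param band_offset band half-width the plants are verified against.
#' @return a validated RLU measurement table.
#' @export
generateRlu <- function(params, plan, seed = params$seed,
                        band_offset = 50) {
  rm_ <- params$rlu_model
  if (rm_$defect_drop <= band_offset + 3 * rm_$replicate_sd)
    stop("validation error: defect_drop must exceed band_offset + 3 sd")
  for (g in unique(plan$gene)) for (tm in unique(plan$terminal[plan$gene == g]))
    if (sum(plan$mutant_id[plan$gene == g & plan$terminal == tm] == "WT") != 1)
      stop("plan must include exactly one WT per (gene, terminal) dataset")
  set.seed(seed)
  nrep <- rm_$n_replicates
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    wt <- plan$mutant_id[i] == "WT"
    ic_mean <- if (wt) rm_$wt_intracellular else
      rm_$wt_intracellular * stats::runif(1, 0.7, 1.1)
    sec_mean <- if (wt) rm_$wt_secreted else if (plan$plant_defect[i])
      ic_mean - rm_$defect_drop else ic_mean + stats::runif(1, -15, 15)
    data.frame(mutant_id = plan$mutant_id[i], gene = plan$gene[i],
               terminal = plan$terminal[i], replicate = seq_len(nrep),
               intracellular_rlu = pmax(0, stats::rnorm(nrep, ic_mean,
                                                        rm_$replicate_sd)),
               secreted_rlu = pmax(0, stats::rnorm(nrep, sec_mean,
                                                   rm_$replicate_sd)),
               label = plan$label[i], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  for (g in unique(plan$gene)) for (tm in unique(plan$terminal[plan$gene == g])) {
    sub <- tab[tab$gene == g & tab$terminal == tm, , drop = FALSE]
    calls <- callSecretoryDefect(summarizeReplicates(sub, tm), band_offset)
    want <- plan[plan$gene == g & plan$terminal == tm, ]
    got <- defectCalls(calls)
    if (!identical(got$defect[match(want$mutant_id, got$mutant_id)],
                   want$plant_defect))
      stop("internal error: RLU fixture failed self-verification (", g,
           ", ", tm, ")")
  }
  validateRluTable(tab)
}

#' Generate the complete functional-panel fixture
#'
#' Bundles everything the functional-congruence analysis needs, built
#' from the packaged `functional_panel` manifest: the 17-variant panel
#' (pathogenic and VUS strata in COL4A3 and COL4A5) with vote-exact
#' score panels, plus N- and C-terminal RLU datasets whose planted
#' secretory defects match the manifest. Within each stratum, planted
#' defects are assigned to consensus-predicted variants first, so the
#' manifest's predicted-and-defective overlap is reproduced exactly.
#'
#' @param registry a [ToolRegistry-class].
#' @param seed integer seed.
#' @param params a [generatorParams()].
#' @param manifest data.frame, defaults to the packaged
#'   `functional_panel` manifest.
#' @return list: `variants`, `panels`, `rlu` (both terminals,
#'   row-bound), `plan` (per-mutant plant decisions per terminal).
#' @export
generateFunctionalFixture <- function(registry = defaultToolRegistry(),
                                      seed = 42L,
                                      params = generatorParams(seed),
                                      manifest =
                                        fixtureManifest("functional_panel")) {
  set.seed(seed)
  model <- params$score_model
  var_list <- list(); score_list <- list(); plan_list <- list()
  for (r in seq_len(nrow(manifest))) {
    n <- manifest$n_total[r]
    vt <- .makeVariants(n, "FSGS", manifest$gene[r],
                        manifest$label_class[r], params$af_model)
    vt$variant_id <- sprintf("%s:%s", vt$gene, vt$protein_change)
    vs <- .voteExactScores(n, manifest$n_target_predicted_pathogenic[r],
                           manifest$label_class[r], registry, model)
    # plant defects on predicted variants first (then unpredicted ones),
    # reproducing the manifest's predicted-and-defective overlap
    ord <- order(!vs$predicted)
    defect_n <- defect_c <- rep(FALSE, n)
    defect_n[ord[seq_len(manifest$n_target_defect_N[r])]] <- TRUE
    defect_c[ord[seq_len(manifest$n_target_defect_C[r])]] <- TRUE
    var_list[[r]] <- vt
    score_list[[r]] <- vs$scores
    plan_list[[r]] <- data.frame(mutant_id = vt$variant_id, gene = vt$gene,
                                 label = vt$clinical_label,
                                 plant_defect_N = defect_n,
                                 plant_defect_C = defect_c,
                                 stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, var_list)
  variants$variant_id <- make.unique(variants$variant_id, sep = "_")
  panels <- ScorePanelSet(do.call(rbind, score_list), registry,
                          variants$variant_id)
  calls <- classifyCohort(panels, registry)
  pred <- isPredictedPathogenic(calls)
  for (r in seq_len(nrow(manifest))) {
    sel <- variants$gene == manifest$gene[r] &
      variants$clinical_label == manifest$label_class[r]
    if (sum(pred[sel]) != manifest$n_target_predicted_pathogenic[r])
      stop("internal error: functional fixture failed self-verification")
  }
  plan <- do.call(rbind, plan_list)
  plan$mutant_id <- variants$variant_id  # positional, survives deduplication
  wt <- do.call(rbind, lapply(unique(plan$gene), function(g)
    data.frame(mutant_id = "WT", gene = g, label = "wild_type",
               plant_defect_N = FALSE, plant_defect_C = FALSE,
               stringsAsFactors = FALSE)))
  plan <- rbind(plan, wt)
  long <- do.call(rbind, lapply(c("N", "C"), function(tm)
    data.frame(mutant_id = plan$mutant_id, gene = plan$gene, terminal = tm,
               label = plan$label,
               plant_defect = plan[[paste0("plant_defect_", tm)]],
               stringsAsFactors = FALSE)))
  rlu <- generateRlu(params, long, seed = seed + 1L)
  list(variants = validateVariantTable(variants), panels = panels,
       rlu = rlu, plan = plan)
}
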