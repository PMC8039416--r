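# shared builders for the unit and property tests; everything is
# generated in code, no fixture files

REG <- defaultToolRegistry()
NUMERIC_TOOLS <- Filter(function(t) toolSpec(REG, t)$orientation != "categorical",
                        toolNames(REG))
CATEGORICAL_TOOLS <- setdiff(toolNames(REG), NUMERIC_TOOLS)

# a score strictly realizing `vote` for `tool` (on/off the damaging side)
voteScore <- function(tool, vote) {
  spec <- toolSpec(REG, tool)
  if (spec$orientation == "categorical") {
    if (vote == "deleterious") return(spec$damaging_categories[1])
    return(setdiff(spec$category_order, spec$damaging_categories)[1])
  }
  delta <- if (spec$orientation == "lower_is_damaging") -1 else 1
  if (vote == "deleterious") spec$cutoff + delta else spec$cutoff - delta
}

# build a ScorePanelSet realizing an n x 12 logical matrix of
# deleterious votes (TRUE = deleterious, FALSE = tolerated, NA = missing)
panelsFromVotes <- function(dmat) {
  tools <- toolNames(REG)
  sc <- lapply(seq_along(tools), function(t) {
    spec <- toolSpec(REG, tools[t])
    del <- voteScore(tools[t], "deleterious")
    tol <- voteScore(tools[t], "tolerated")
    col <- ifelse(dmat[, t], del, tol)
    if (spec$orientation == "categorical") {
      col <- as.character(col)
      col[is.na(dmat[, t])] <- NA_character_
    } else {
      col <- as.numeric(col)
      col[is.na(dmat[, t])] <- NA_real_
    }
    col
  })
  names(sc) <- tools
  ScorePanelSet(as.data.frame(sc, check.names = FALSE),
                REG, sprintf("v%04d", seq_len(nrow(dmat))))
}

# random numeric-and-categorical panels over each tool's native scale
randomPanels <- function(n, seed, missing_rate = 0.1) {
  set.seed(seed)
  sc <- lapply(toolNames(REG), function(tool) {
    spec <- toolSpec(REG, tool)
    col <- if (spec$orientation == "categorical")
      sample(spec$category_order, n, replace = TRUE)
    else runif(n, spec$range_lo, spec$range_hi)
    col[runif(n) < missing_rate] <- NA
    col
  })
  names(sc) <- toolNames(REG)
  ScorePanelSet(as.data.frame(sc, check.names = FALSE),
                REG, sprintf("r%05d", seq_len(n)))
}

# minimal variant table around a set of ids
variantsFor <- function(ids, gene = "COL4A3", label = "pathogenic",
                        source = "synthetic") {
  data.frame(variant_id = ids, gene = gene,
             protein_change = sprintf("p.G%dR", seq_along(ids) + 100),
             consequence = "missense", carrier_population = "nfe",
             clinical_label = label, source = source,
             af_nfe = 1e-4, stringsAsFactors = FALSE)
}

# per-mutant summary engineered to produce the given defect pattern
# (band 50): defect -> (200, 100), no defect -> (200, 200); WT on Y=X
summaryFromPattern <- function(defect, gene = "COL4A3", terminal = "N") {
  n <- length(defect)
  data.frame(mutant_id = c("WT", sprintf("m%02d", seq_len(n))),
             gene = gene, label = c("wild_type", rep("vus", n)),
             terminal = terminal,
             mean_intracellular = c(200, rep(200, n)),
             mean_secreted = c(200, ifelse(defect, 100, 200)),
             n_replicates = 3, stringsAsFactors = FALSE)
}
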