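#' Read an annotated variant table
#'
#' The canonical dialect is a tab-separated UTF-8 table with columns
#' `variant_id`, `gene`, `protein_change`, `consequence`,
#' `carrier_population`, `clinical_label`, `source` and any number of
#' per-population allele-frequency columns `af_<pop>` (gnomAD top-level
#' ancestry keys; an empty cell means the variant was not observed in
#' that population). A VCF 4.x dialect is accepted via `dialect =
#' "vcf_info"`, mapping INFO keys `GENE`, `CSQ_CLASS`, `AF_<pop>`,
#' `CLNLBL`, `SRC` (and optional `PCHANGE`, `CARRIER_POP`) onto the
#' same schema, with the VCF `ID` column as `variant_id`.
#'
#' @param path path to an existing file.
#' @param dialect `"tsv"` (default) or `"vcf_info"`.
#' @return a validated data.frame of variant records (see
#'   [validateVariantTable()] for the rules).
#' @export
readVariantTable <- function(path, dialect = c("tsv", "vcf_info")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- switch(dialect,
                tsv = utils::read.delim(path, stringsAsFactors = FALSE,
                                        check.names = FALSE,
                                        na.strings = c("NA", "")),
                vcf_info = .readVariantVcf(path))
  validateVariantTable(tab)
}

.readVariantVcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- body[1]
  if (!startsWith(hdr, "#CHROM")) stop("schema error: not a VCF (no #CHROM header)")
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  fields <- strsplit(rows, "\t", fixed = TRUE)
  info <- lapply(fields, function(f) {
    kv <- strsplit(strsplit(f[8], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(kv, function(p) if (length(p) > 1) p[2] else "TRUE",
                           character(1)),
                    vapply(kv, `[`, character(1), 1))
  })
  getk <- function(key) vapply(info, function(x)
    unname(x[key]), character(1))
  id <- vapply(fields, `[`, character(1), 3)
  noid <- id == "."
  if (any(noid))
    id[noid] <- vapply(fields[noid], function(f)
      paste(f[1], f[2], f[4], f[5], sep = ":"), character(1))
  tab <- data.frame(variant_id = id,
                    gene = getk("GENE"),
                    protein_change = getk("PCHANGE"),
                    consequence = getk("CSQ_CLASS"),
                    carrier_population = getk("CARRIER_POP"),
                    clinical_label = getk("CLNLBL"),
                    source = getk("SRC"),
                    stringsAsFactors = FALSE)
  afkeys <- unique(unlist(lapply(info, function(x)
    grep("^AF_", names(x), value = TRUE))))
  for (k in afkeys)
    tab[[paste0("af_", tolower(sub("^AF_", "", k)))]] <- as.numeric(getk(k))
  tab
}

#' Validate a variant table
#'
#' Checks the schema and value domains of an annotated variant table:
#' required columns present, genes in COL4A3/A4/A5, consequences and
#' labels in their vocabularies, every allele frequency in [0, 1], and
#' `vus` labels restricted to the FSGS and synthetic sources (disease
#' databases supply pathogenic/benign/unlabeled). Failures are reported
#' with row indices. Unknown population keys in `carrier_population`
#' are accepted with a warning.
#'
#' @param tab data.frame of variant records.
#' @return the table, invisibly unchanged, if valid; otherwise an error.
#' @export
validateVariantTable <- function(tab) {
  required <- c("variant_id", "gene", "protein_change", "consequence",
                "clinical_label", "source")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!"carrier_population" %in% names(tab))
    tab$carrier_population <- NA_character_
  bad_rows <- function(ok, what) {
    if (!all(ok))
      stop("validation error: ", what, " at row(s) ",
           paste(utils::head(which(!ok), 10), collapse = ", "))
  }
  bad_rows(tab$gene %in% COL4_GENES, "gene not in COL4A3/COL4A4/COL4A5")
  bad_rows(tab$consequence %in% CONSEQUENCES, "invalid consequence")
  bad_rows(tab$clinical_label %in% CLINICAL_LABELS, "invalid clinical_label")
  bad_rows(tab$source %in% VARIANT_SOURCES, "invalid source")
  bad_rows(!(tab$clinical_label == "vus" &
               !tab$source %in% c("FSGS", "synthetic")),
           "vus label outside FSGS/synthetic sources")
  for (col in afColumns(tab)) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      if (any(is.na(v) & !is.na(tab[[col]])))
        stop("validation error: non-numeric frequency in ", col)
      tab[[col]] <- v
    }
    bad_rows(is.na(v) | (v >= 0 & v <= 1),
             paste0("allele frequency outside [0,1] in ", col))
  }
  known <- tab$carrier_population %in% c(GNOMAD_POPULATIONS, "global") |
    is.na(tab$carrier_population)
  if (!all(known))
    warning("unknown carrier_population key(s): ",
            paste(unique(tab$carrier_population[!known]), collapse = ", "))
  tab
}

#' Population frequency columns of a variant table
#'
#' @param tab a variant table.
#' @return character vector of `af_<pop>` column names.
#' @export
afColumns <- function(tab) grep("^af_", names(tab), value = TRUE)

#' Write a variant table (canonical TSV dialect)
#'
#' @param tab a validated variant table.
#' @param path output path.
#' @export
writeVariantTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(NULL)
}

#' Construct a score panel set
#'
#' @param scores data.frame, one column per tool (names must resolve in
#'   the registry), one row per variant.
#' @param registry a [ToolRegistry-class].
#' @param variantIds character vector of unique keys, one per row.
#' @return a [ScorePanelSet-class].
#' @export
ScorePanelSet <- function(scores, registry, variantIds) {
  for (nm in names(scores)) {
    if (toolSpec(registry, nm)$orientation == "categorical") {
      scores[[nm]] <- as.character(scores[[nm]])
    } else {
      scores[[nm]] <- as.numeric(scores[[nm]])
    }
  }
  new("ScorePanelSet", variantIds = as.character(variantIds),
      scores = scores, registry = registry)
}

#' Read a wide predictor score table
#'
#' Expects a dbNSFP-style wide TSV: a `variant_id` column plus one
#' column per predictor. Header names are resolved against the registry
#' case-insensitively, with `-`, `_`, `.` and spaces interchangeable
#' (so `Polyphen2_HDIV` matches `PolyPhen2-HDIV`). Unknown columns are
#' dropped with a warning; blank and NA cells become missing scores;
#' categorical tools keep their tokens verbatim.
#'
#' @param path file path.
#' @param registry a [ToolRegistry-class].
#' @return a [ScorePanelSet-class].
#' @export
readScoreTable <- function(path, registry = defaultToolRegistry()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", ""),
                           colClasses = "character")
  if (!"variant_id" %in% names(raw))
    stop("schema error: missing required column(s): variant_id")
  if (anyDuplicated(raw$variant_id))
    stop("duplicate variant_id: ",
         paste(unique(raw$variant_id[duplicated(raw$variant_id)]),
               collapse = ", "))
  canon <- function(x) tolower(gsub("[-_. ]", "", x))
  reg_names <- toolNames(registry)
  cols <- setdiff(names(raw), "variant_id")
  hit <- match(canon(cols), canon(reg_names))
  if (any(is.na(hit)))
    warning("ignoring unknown tool column(s): ",
            paste(cols[is.na(hit)], collapse = ", "))
  keep <- cols[!is.na(hit)]
  scores <- raw[keep]
  names(scores) <- reg_names[hit[!is.na(hit)]]
  for (nm in names(scores)) {
    if (toolSpec(registry, nm)$orientation != "categorical") {
      v <- suppressWarnings(as.numeric(scores[[nm]]))
      bad <- is.na(v) & !is.na(scores[[nm]])
      if (any(bad))
        stop("type error: non-numeric score for numeric tool ", nm,
             " at row(s) ", paste(utils::head(which(bad), 10), collapse = ", "))
      scores[[nm]] <- v
    }
  }
  ScorePanelSet(scores, registry, raw$variant_id)
}

#' Write a score panel set as wide TSV
#'
#' @param panels a [ScorePanelSet-class].
#' @param path output path.
#' @export
writeScoreTable <- function(panels, path) {
  out <- cbind(data.frame(variant_id = panels@variantIds,
                          stringsAsFactors = FALSE),
               panels@scores)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(NULL)
}

#' Read a split-luciferase RLU measurement table
#'
#' Columns: `mutant_id` (with `WT` reserved for the wild-type
#' reference), `gene` (COL4A3 or COL4A5), `terminal` (N or C),
#' `replicate` (positive integer), `intracellular_rlu`, `secreted_rlu`
#' (both >= 0, relative light units) and `label` (pathogenic, vus or
#' wild_type). Every (gene, terminal) dataset must contain exactly one
#' WT mutant.
#'
#' @param path file path.
#' @return a validated data.frame of replicate measurements.
#' @export
readRluTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  validateRluTable(tab)
}

#' @rdname readRluTable
#' @param tab data.frame of RLU measurements.
#' @export
validateRluTable <- function(tab) {
  required <- c("mutant_id", "gene", "terminal", "replicate",
                "intracellular_rlu", "secreted_rlu", "label")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!all(tab$gene %in% c("COL4A3", "COL4A5")))
    stop("validation error: gene must be COL4A3 or COL4A5")
  if (!all(tab$terminal %in% c("N", "C")))
    stop("validation error: terminal must be N or C")
  if (!all(tab$replicate >= 1 & tab$replicate == round(tab$replicate)))
    stop("validation error: replicate must be a positive integer")
  if (!all(tab$intracellular_rlu >= 0 & tab$secreted_rlu >= 0))
    stop("validation error: RLU values must be >= 0")
  if (!all(tab$label %in% c("pathogenic", "vus", "wild_type")))
    stop("validation error: label must be pathogenic, vus or wild_type")
  for (g in unique(tab$gene)) for (tm in unique(tab$terminal[tab$gene == g])) {
    sub <- tab[tab$gene == g & tab$terminal == tm, ]
    if (sum(unique(sub$mutant_id) == "WT") != 1)
      stop("validation error: dataset (", g, ", ", tm,
           ") must contain exactly one WT reference")
  }
  tab
}

#' Write / read a stratified evaluation report
#'
#' Reports are written with a deterministic column order and a
#' (source, gene, label class) row sort. Fractions carry numerator and
#' denominator alongside the percentage, in the `k/n (p%)` style, so a
#' row for a 317-of-327 stratum contains `317`, `327` and `97.0`.
#'
#' @param report an [EvaluationReport-class].
#' @param path output path.
#' @param format `"tsv"` or `"json"`. The JSON format round-trips the
#'   confusion table as well; the TSV carries the strata.
#' @export
writeReport <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  st <- report@strata
  st <- st[order(st$source, st$gene, st$label_class), , drop = FALSE]
  rownames(st) <- NULL
  # percentages in the reports follow the k/n (p%) presentation style:
  # whole-percent rounding, printed with one decimal
  st$percent <- sprintf("%.1f", ifelse(st$n > 0,
                                       round(100 * st$n_concordant / st$n),
                                       NA))
  st$display <- sprintf("%d/%d (%s%%)", st$n_concordant, st$n, st$percent)
  if (format == "tsv") {
    out <- st[c("source", "gene", "label_class", "n_concordant", "n",
                "percent", "display")]
    ok <- tryCatch({
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
      TRUE
    }, error = function(e) stop("I/O error writing report: ",
                                conditionMessage(e)))
  } else {
    jsonlite::write_json(list(strata = st[c("source", "gene", "label_class",
                                            "n_concordant", "n", "fraction")],
                              confusion = report@confusion),
                         path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(NULL)
}

#' @rdname writeReport
#' @return `readReport` returns the [EvaluationReport-class] re-read
#'   from disk.
#' @export
readReport <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    st <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(st)) st$fraction <- st$n_concordant / st$n
    else st$fraction <- numeric(0)
    st <- st[c("source", "gene", "label_class", "n_concordant", "n",
               "fraction")]
    conf <- data.frame()
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    st <- as.data.frame(obj$strata, stringsAsFactors = FALSE)
    conf <- as.data.frame(obj$confusion, stringsAsFactors = FALSE)
  }
  new("EvaluationReport", strata = st, confusion = conf)
}
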