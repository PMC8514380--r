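sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))
    tp53_stop("tp53sig_empty_input", paste0("empty input file: ", path))
  if (grepl("\t", first)) "\t" else ","
}

#' Read and validate a samples-by-genes expression table
#'
#' TSV or CSV (delimiter sniffed from the header line): first column
#' \code{sample_id}, remaining columns one gene each, cells non-negative
#' numbers in linear units. Duplicate gene columns, duplicate sample ids,
#' non-numeric cells and negative values are rejected with the offending
#' row/column named.
#'
#' @param path input file path.
#' @return A numeric matrix, samples in rows (rownames = sample ids), genes
#'   in columns.
#' @export
readExpressionTable <- function(path) {
  if (!file.exists(path))
    tp53_stop("tp53sig_io_error", paste0("file not found: ", path))
  delim <- sniff_delim(path)
  tab <- read.delim(path, sep = delim, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!nrow(tab))
    tp53_stop("tp53sig_empty_input", paste0("no data rows in ", path))
  if (names(tab)[1] != "sample_id")
    tp53_stop("tp53sig_parse_error",
              "first column of an expression table must be 'sample_id'")
  genes <- names(tab)[-1]
  if (anyDuplicated(genes))
    tp53_stop("tp53sig_parse_error",
              paste0("duplicate gene column(s): ",
                     paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  ids <- as.character(tab$sample_id)
  if (anyDuplicated(ids))
    tp53_stop("tp53sig_duplicate_id",
              paste0("duplicate sample id(s): ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  mat <- matrix(NA_real_, nrow(tab), length(genes),
                dimnames = list(ids, genes))
  for (j in seq_along(genes)) {
    col <- tab[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & col != "NA")
    if (length(bad))
      tp53_stop("tp53sig_parse_error",
                sprintf("non-numeric cell at row %d (sample '%s'), column '%s': '%s'",
                        bad[1], ids[bad[1]], genes[j], col[bad[1]]))
    neg <- which(!is.na(num) & num < 0)
    if (length(neg))
      tp53_stop("tp53sig_invalid_input",
                sprintf("negative expression at row %d (sample '%s'), column '%s'",
                        neg[1], ids[neg[1]], genes[j]))
    mat[, j] <- num
  }
  mat
}

#' Write an expression matrix as a TSV table
#'
#' Inverse of [readExpressionTable()]: first column \code{sample_id}, one
#' column per gene.
#'
#' @param mat samples-by-genes numeric matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(mat, path) {
  out <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

clinical_vocab <- list(
  p_stage = c("I", "IIA", "IIB"),
  p_ln = c("positive", "negative"),
  er = c("positive", "negative"),
  pgr = c("positive", "negative"),
  her2 = c("positive", "negative"),
  adj_chemo = c("yes", "no"),
  adj_endocrine = c("yes", "no"),
  tp53_status = c("mutant", "wild")
)

#' Read and validate a clinical cohort table
#'
#' TSV or CSV with one row per patient. Expected columns (any subset beyond
#' \code{sample_id} is allowed; analyses check for what they need):
#' \describe{
#'   \item{sample_id}{unique patient identifier}
#'   \item{age}{years}
#'   \item{p_stage}{pathological stage: I, IIA or IIB}
#'   \item{p_ln}{pathological lymph-node status: positive/negative}
#'   \item{tumor_size_cm}{pathological tumour size in cm}
#'   \item{grade}{histological grade 1, 2 or 3; "NA" allowed}
#'   \item{er, pgr, her2}{receptor status: positive/negative}
#'   \item{ki67_pct}{Ki-67 labelling index, percent; "NA" allowed}
#'   \item{adj_chemo, adj_endocrine}{adjuvant therapy: yes/no}
#'   \item{tp53_status}{mutant/wild (optional; the pipeline derives it from
#'     expression when absent)}
#'   \item{rfs_time, os_time, bcss_time}{endpoint times in years}
#'   \item{rfs_event, os_event, bcss_event}{1 = event, 0 = censored}
#' }
#' Categorical levels are validated against this vocabulary; an unknown
#' level is an error listing the allowed values.
#'
#' @param path input file path.
#' @return A validated data.frame.
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path))
    tp53_stop("tp53sig_io_error", paste0("file not found: ", path))
  delim <- sniff_delim(path)
  tab <- read.delim(path, sep = delim, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  if (!nrow(tab))
    tp53_stop("tp53sig_empty_input", paste0("no data rows in ", path))
  if (!"sample_id" %in% names(tab))
    tp53_stop("tp53sig_parse_error", "clinical table needs a 'sample_id' column")
  if (anyDuplicated(tab$sample_id))
    tp53_stop("tp53sig_duplicate_id",
              paste0("duplicate sample id(s): ",
                     paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
                           collapse = ", ")))
  for (col in intersect(names(clinical_vocab), names(tab))) {
    bad <- setdiff(unique(stats::na.omit(tab[[col]])), clinical_vocab[[col]])
    if (length(bad))
      tp53_stop("tp53sig_vocabulary_error",
                sprintf("column '%s': unknown level(s) %s; allowed: %s", col,
                        paste(sQuote(bad), collapse = ", "),
                        paste(clinical_vocab[[col]], collapse = ", ")))
  }
  if ("grade" %in% names(tab)) {
    g <- suppressWarnings(as.integer(tab$grade))
    if (any(!is.na(g) & !g %in% 1:3))
      tp53_stop("tp53sig_vocabulary_error",
                "column 'grade': allowed values are 1, 2, 3 or NA")
    tab$grade <- g
  }
  for (col in intersect(c("age", "tumor_size_cm", "ki67_pct",
                          paste0(ENDPOINTS, "_time")), names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (any(is.na(v) & !is.na(tab[[col]])))
      tp53_stop("tp53sig_parse_error",
                paste0("column '", col, "' must be numeric"))
    if (col != "age" && any(!is.na(v) & v < 0))
      tp53_stop("tp53sig_invalid_record",
                paste0("column '", col, "' has negative value(s)"))
    tab[[col]] <- v
  }
  for (col in intersect(paste0(ENDPOINTS, "_event"), names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (!all(stats::na.omit(v) %in% c(0, 1)))
      tp53_stop("tp53sig_invalid_flag",
                paste0("column '", col, "' must be 0 (censored) or 1 (event)"))
    tab[[col]] <- as.integer(v)
  }
  tab
}

#' Write a clinical cohort table as TSV
#'
#' Inverse of [readClinicalTable()]; a round trip reproduces identical
#' in-memory values.
#'
#' @param records cohort data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClinicalTable <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end signature pipeline
#'
#' Scores and classifies every sample, joins the calls to the clinical
#' table, and runs the full prognostic analysis: per-endpoint log-rank and
#' Kaplan-Meier by signature status, the univariate/multivariate Cox table
#' for RFS, the subgroup RFS analysis, and the baseline-characteristics
#' comparison. Endpoints whose columns are absent are skipped with a
#' message.
#'
#' @param expression a samples-by-genes matrix or a path readable by
#'   [readExpressionTable()].
#' @param clinical a cohort data.frame or a path readable by
#'   [readClinicalTable()].
#' @param panel a [GenePanel-class]; default [defaultPanel()].
#' @param cutoff classification cutoff; default [TP53_CUTOFF].
#' @param endpoints endpoints to analyse; default all of rfs, os, bcss.
#' @param entryP multivariate entry threshold for [runTable3()].
#' @param inputScale passed to [scoreCohort()].
#' @param outputDir optional directory; when given, writes
#'   \code{signature_calls.tsv}, \code{summary.json} and
#'   \code{pipeline_config.yaml} there.
#' @param seed seed recorded in the provenance stamp (the analysis itself is
#'   deterministic).
#' @return A list with elements \code{calls}, \code{endpoints} (per-endpoint
#'   log-rank + curves), \code{table3}, \code{subgroups},
#'   \code{characteristics}, and \code{provenance} (cutoff, entry p, seed,
#'   config hash, cohort counts).
#' @export
runPipeline <- function(expression, clinical, panel = defaultPanel(),
                        cutoff = TP53_CUTOFF,
                        endpoints = c("rfs", "os", "bcss"),
                        entryP = 0.05,
                        inputScale = c("linear", "log2"),
                        outputDir = NULL, seed = NA_integer_) {
  inputScale <- match.arg(inputScale)
  endpoints <- match.arg(endpoints, ENDPOINTS, several.ok = TRUE)
  if (is.character(expression) && length(expression) == 1L)
    expression <- readExpressionTable(expression)
  if (is.character(clinical) && length(clinical) == 1L)
    clinical <- readClinicalTable(clinical)

  calls <- scoreCohort(expression, panel, cutoff, inputScale = inputScale)
  unmatched <- c(setdiff(calls$sample_id, clinical$sample_id),
                 setdiff(clinical$sample_id, calls$sample_id))
  if (length(unmatched))
    tp53_stop("tp53sig_alignment_error",
              paste0("expression/clinical sample ids do not match: ",
                     paste(unique(unmatched), collapse = ", ")))
  records <- clinical[match(calls$sample_id, clinical$sample_id), ,
                      drop = FALSE]
  records$tp53_status <- as.character(calls$tp53_status)
  message("cohort: ", nrow(records), " patients; ",
          sum(records$tp53_status == "mutant"), " mutant / ",
          sum(records$tp53_status == "wild"), " wild signature at cutoff ",
          cutoff)

  ep_res <- list()
  for (ep in endpoints) {
    cols <- ep_cols(ep)
    if (!all(cols %in% names(records))) {
      message("endpoint '", ep, "': columns absent; skipped")
      next
    }
    ep_res[[ep]] <- list(
      log_rank = logRank(records, ep, "tp53_status"),
      km = kaplanMeier(records, ep, "tp53_status"))
  }

  has_t3 <- all(vapply(cox_variable_registry(), function(v)
    v$column %in% names(records), logical(1))) &&
    all(ep_cols("rfs") %in% names(records))
  table3 <- if (has_t3) runTable3(records, "rfs", entryP) else {
    message("Cox covariates incomplete; Table-3 analysis skipped"); NULL
  }
  subgroups <- if (all(ep_cols("rfs") %in% names(records)))
    subgroupRFS(records) else NULL
  characteristics <- characteristicsTable(records)

  result <- list(
    calls = calls,
    endpoints = ep_res,
    table3 = table3,
    subgroups = subgroups,
    characteristics = characteristics,
    provenance = list(
      cutoff = cutoff, entry_p = entryP, input_scale = inputScale,
      seed = seed, n = nrow(records),
      n_mutant = sum(records$tp53_status == "mutant"),
      n_wild = sum(records$tp53_status == "wild"),
      config_hash = config_hash(list(cutoff, entryP, inputScale, endpoints,
                                     panelGenes(panel)))))
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    writeSignatureCalls(calls, file.path(outputDir, "signature_calls.tsv"))
    jsonlite::write_json(pipeline_summary(result),
                         file.path(outputDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(result$provenance,
                     file.path(outputDir, "pipeline_config.yaml"))
  }
  result
}

# flatten the pipeline result into JSON-friendly scalars/tables
pipeline_summary <- function(result) {
  list(
    provenance = result$provenance,
    classification = list(
      n_mutant = result$provenance$n_mutant,
      n_wild = result$provenance$n_wild),
    log_rank = lapply(result$endpoints, function(e)
      list(statistic = e$log_rank$statistic, df = e$log_rank$df,
           p_value = e$log_rank$p_value)),
    table3 = if (!is.null(result$table3)) list(
      univariate = result$table3$univariate,
      selected = as.list(result$table3$selected),
      multivariate = result$table3$multivariate),
    subgroups = if (!is.null(result$subgroups)) result$subgroups$summary,
    characteristics = result$characteristics$summary)
}
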