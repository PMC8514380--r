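#' Compute the TP53 signature score
#'
#' The score of a sample is the ratio of the summed expression of the
#' panel's up-regulated genes to the summed expression of its down-regulated
#' genes. It is dimensionless and invariant to any per-sample rescaling of
#' the expression values, which is why the internal-control genes never
#' enter it: a per-sample normalisation constant cancels in the ratio.
#' Controls are used only as a QC gate (see \code{controlFloor}).
#'
#' @param x expression values: a named numeric vector (one sample), a
#'   numeric matrix with samples in rows and genes in columns (column names
#'   are gene identifiers), or a \code{SummarizedExperiment} with genes in
#'   rows and samples in columns (first assay used).
#' @param panel a [GenePanel-class]; default [defaultPanel()].
#' @param inputScale \code{"linear"} (raw non-negative values, default) or
#'   \code{"log2"} (values are log2 expression and are exponentiated before
#'   summation).
#' @param controlFloor detection floor for the control genes; if any control
#'   value falls below it a warning names the sample and gene. \code{NULL}
#'   (default) disables the gate.
#' @return A named numeric vector of scores, one per sample, in input order.
#' @examples
#' panel <- defaultPanel()
#' v <- setNames(c(rep(7, 16), rep(16, 7), rep(100, 3)), panelGenes(panel))
#' signatureScore(v, panel)  # 112/112 = 1
#' @export
signatureScore <- function(x, panel = defaultPanel(),
                           inputScale = c("linear", "log2"),
                           controlFloor = NULL) {
  inputScale <- match.arg(inputScale)
  mat <- as_sample_matrix(x)
  if (inputScale == "log2") mat <- 2^mat
  if (anyNA(mat))
    tp53_stop("tp53sig_invalid_input", "expression values contain NA")
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    tp53_stop("tp53sig_invalid_input",
              sprintf("negative expression value at sample '%s', gene '%s'",
                      rownames(mat)[bad[1]], colnames(mat)[bad[2]]))
  }
  miss <- setdiff(c(upGenes(panel), downGenes(panel)), colnames(mat))
  if (length(miss))
    tp53_stop("tp53sig_missing_gene",
              paste0("panel gene(s) missing from expression data: ",
                     paste(miss, collapse = ", ")),
              genes = miss)
  up_sum <- rowSums(mat[, upGenes(panel), drop = FALSE])
  dn_sum <- rowSums(mat[, downGenes(panel), drop = FALSE])
  if (any(dn_sum <= 0)) {
    off <- rownames(mat)[dn_sum <= 0]
    tp53_stop("tp53sig_degenerate_profile",
              paste0("sum of down-gene expression is zero for sample(s): ",
                     paste(off, collapse = ", ")))
  }
  if (!is.null(controlFloor) && length(controlGenes(panel))) {
    ctrl <- intersect(controlGenes(panel), colnames(mat))
    if (length(ctrl)) {
      low <- which(mat[, ctrl, drop = FALSE] < controlFloor, arr.ind = TRUE)
      if (nrow(low))
        warning(sprintf(
          "control gene below detection floor (%g): %s",
          controlFloor,
          paste(sprintf("%s/%s", rownames(mat)[low[, 1]], ctrl[low[, 2]]),
                collapse = ", ")), call. = FALSE)
    }
  }
  setNames(up_sum / dn_sum, rownames(mat))
}

# coerce the accepted input shapes to a samples x genes numeric matrix
as_sample_matrix <- function(x) {
  if (inherits(x, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      tp53_stop("tp53sig_invalid_input",
                "SummarizedExperiment input requires the SummarizedExperiment package")
    x <- t(SummarizedExperiment::assay(x))  # genes x samples -> samples x genes
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (is.null(names(x)))
      tp53_stop("tp53sig_invalid_input", "a single-sample vector must be named by gene")
    x <- matrix(x, nrow = 1, dimnames = list("sample1", names(x)))
  }
  if (!is.numeric(x))
    tp53_stop("tp53sig_invalid_input", "expression values must be numeric")
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
  if (anyDuplicated(colnames(x)))
    tp53_stop("tp53sig_parse_error",
              paste0("duplicate gene column(s): ",
                     paste(unique(colnames(x)[duplicated(colnames(x))]),
                           collapse = ", ")))
  x
}

#' Classify a signature score as mutant or wild
#'
#' A sample is called TP53 mutant signature when its score is strictly
#' greater than the cutoff; a score exactly equal to the cutoff is wild.
#'
#' @param score numeric vector of positive, finite signature scores.
#' @param cutoff positive classification threshold; default the published
#'   constant [TP53_CUTOFF] (1.11).
#' @return A factor with levels \code{c("wild", "mutant")}, same length and
#'   names as \code{score}.
#' @examples
#' classifyScore(c(0.1707, 4.0595, 1.11))  # wild, mutant, wild
#' @export
classifyScore <- function(score, cutoff = TP53_CUTOFF) {
  if (!is.numeric(score) || any(!is.finite(score)))
    tp53_stop("tp53sig_invalid_input", "scores must be finite numbers")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff <= 0)
    tp53_stop("tp53sig_invalid_input", "cutoff must be a single finite positive number")
  factor(ifelse(score > cutoff, "mutant", "wild"),
         levels = c("wild", "mutant"))
}

#' Score and classify a cohort
#'
#' Applies [signatureScore()] and [classifyScore()] to every sample of an
#' expression table. Each sample's call depends only on its own profile:
#' adding or removing other samples never changes a call.
#'
#' @inheritParams signatureScore
#' @inheritParams classifyScore
#' @return A data.frame with columns \code{sample_id},
#'   \code{tp53_signature_score}, \code{tp53_status} (factor wild/mutant) and
#'   \code{cutoff_used}, one row per sample in input order.
#' @export
scoreCohort <- function(x, panel = defaultPanel(), cutoff = TP53_CUTOFF,
                        inputScale = c("linear", "log2"),
                        controlFloor = NULL) {
  mat <- as_sample_matrix(x)
  if (anyDuplicated(rownames(mat)))
    tp53_stop("tp53sig_duplicate_id",
              paste0("duplicate sample id(s): ",
                     paste(unique(rownames(mat)[duplicated(rownames(mat))]),
                           collapse = ", ")))
  score <- signatureScore(mat, panel, inputScale = match.arg(inputScale),
                          controlFloor = controlFloor)
  data.frame(sample_id = rownames(mat),
             tp53_signature_score = unname(score),
             tp53_status = classifyScore(score, cutoff),
             cutoff_used = cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a cohort's signature calls to TSV
#'
#' Scores are printed with six significant digits; the file carries the
#' cutoff used for every call.
#'
#' @param calls the data.frame returned by [scoreCohort()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSignatureCalls <- function(calls, path) {
  out <- calls
  out$tp53_signature_score <- signif(out$tp53_signature_score, 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
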