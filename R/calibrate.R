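#' RocResult: ROC analysis of signature scores against a reference status
#'
#' Holds the empirical ROC of signature scores against a binary reference
#' TP53 status (mutant = positive class, higher score = more mutant-like):
#' the Mann-Whitney AUC, the candidate thresholds with their sensitivity and
#' specificity, and the Youden-optimal cutoff.
#'
#' @slot auc Mann-Whitney AUC in [0, 1].
#' @slot thresholds ordered candidate cutoffs (midpoints between adjacent
#'   distinct scores, with -Inf/+Inf sentinels).
#' @slot sensitivity,specificity per-threshold operating characteristics.
#' @slot selectedCutoff the threshold maximising Youden's J.
#' @slot youdenJ max of sensitivity + specificity - 1 over thresholds.
#' @seealso [selectCutoff()], [rocAuc()]
#' @export
setClass("RocResult", slots = c(
  auc = "numeric",
  thresholds = "numeric",
  sensitivity = "numeric",
  specificity = "numeric",
  selectedCutoff = "numeric",
  youdenJ = "numeric"
))

setValidity("RocResult", function(object) {
  msgs <- character()
  if (object@auc < 0 || object@auc > 1) msgs <- c(msgs, "auc must lie in [0, 1]")
  n <- length(object@thresholds)
  if (length(object@sensitivity) != n || length(object@specificity) != n)
    msgs <- c(msgs, "sensitivity/specificity must align with thresholds")
  if (any(object@sensitivity < 0 | object@sensitivity > 1) ||
      any(object@specificity < 0 | object@specificity > 1))
    msgs <- c(msgs, "sensitivity and specificity must lie in [0, 1]")
  if (object@youdenJ < -1 || object@youdenJ > 1)
    msgs <- c(msgs, "youdenJ must lie in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RocResult", function(object) {
  cat("RocResult:", length(object@thresholds), "thresholds\n")
  cat(sprintf("  AUC            %.4f\n", object@auc))
  cat(sprintf("  selected cutoff %.4g (Youden's J = %.4f)\n",
              object@selectedCutoff, object@youdenJ))
  invisible(NULL)
})

#' @describeIn RocResult-class the Mann-Whitney AUC
#' @param x a \code{RocResult}
#' @export
auc <- function(x) x@auc

#' @describeIn RocResult-class the Youden-optimal cutoff
#' @export
selectedCutoff <- function(x) x@selectedCutoff

#' @describeIn RocResult-class Youden's J at the selected cutoff
#' @export
youdenJ <- function(x) x@youdenJ

check_labels <- function(status) {
  status <- as.character(status)
  bad <- setdiff(unique(status), c("mutant", "wild"))
  if (length(bad))
    tp53_stop("tp53sig_vocabulary_error",
              paste0("reference status must be 'mutant' or 'wild'; got: ",
                     paste(bad, collapse = ", ")))
  if (length(unique(status)) < 2L)
    tp53_stop("tp53sig_degenerate_labels",
              "both reference classes (mutant and wild) must be present")
  status
}

#' Empirical ROC AUC of scores against a reference status
#'
#' The area under the empirical ROC curve, computed as the Mann-Whitney
#' probability that a randomly chosen mutant-reference sample scores above a
#' randomly chosen wild-reference sample, with half credit for ties:
#' \deqn{AUC = (\#\{(w,m): s_m > s_w\} + \tfrac12 \#ties) / (n_w n_m).}
#' Mutant is the positive class; the AUC is invariant under any strictly
#' increasing transform of the scores.
#'
#' @param score numeric vector of signature scores.
#' @param status reference TP53 status aligned to \code{score}; values
#'   \code{"mutant"} / \code{"wild"} (factor or character). This is the
#'   external ground truth, never the score-derived call.
#' @return The AUC, a number in [0, 1].
#' @examples
#' fx <- table1Fixture()
#' rocAuc(fx$tp53_signature_score, fx$status_by_microarray)  # 0.993
#' @export
rocAuc <- function(score, status) {
  status <- check_labels(status)
  if (length(score) != length(status))
    tp53_stop("tp53sig_alignment_error", "score and status lengths differ")
  if (!is.numeric(score) || any(!is.finite(score)))
    tp53_stop("tp53sig_invalid_input", "scores must be finite numbers")
  m <- score[status == "mutant"]
  w <- score[status == "wild"]
  # rank formulation of the Mann-Whitney statistic; midranks give half
  # credit to tied pairs
  r <- rank(c(m, w))
  u <- sum(r[seq_along(m)]) - length(m) * (length(m) + 1) / 2
  u / (length(m) * length(w))
}

#' Select a classification cutoff by ROC analysis
#'
#' Scans all candidate thresholds -- midpoints between adjacent distinct
#' sorted scores plus -Inf/+Inf sentinels -- and selects the one maximising
#' Youden's J (sensitivity + specificity - 1). Ties are broken toward the
#' lower threshold, i.e. toward higher sensitivity. This is a recalibration
#' tool: the published constant [TP53_CUTOFF] remains the classification
#' default and is never silently overridden by this function.
#'
#' @inheritParams rocAuc
#' @param strategy cutoff-selection rule; only \code{"youden"} is
#'   implemented.
#' @return A [RocResult-class].
#' @examples
#' fx <- table1Fixture()
#' selectCutoff(fx$tp53_signature_score, fx$status_by_microarray)
#' @export
selectCutoff <- function(score, status, strategy = c("youden")) {
  strategy <- match.arg(strategy)
  status <- check_labels(status)
  if (length(score) != length(status))
    tp53_stop("tp53sig_alignment_error", "score and status lengths differ")
  s <- sort(unique(score))
  thresholds <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  is_m <- status == "mutant"
  sens <- vapply(thresholds, function(t) mean(score[is_m] > t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(score[!is_m] <= t), numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)  # which.max takes the first maximum = lowest threshold
  if (max(j) <= 0)
    warning("scores do not separate the classes (Youden's J <= 0)",
            call. = FALSE)
  new("RocResult",
      auc = rocAuc(score, status),
      thresholds = thresholds,
      sensitivity = sens,
      specificity = spec,
      selectedCutoff = thresholds[best],
      youdenJ = j[best])
}

#' Agreement between signature calls and a reference status
#'
#' @param call score-derived status per sample (\code{"mutant"}/\code{"wild"});
#'   either a vector aligned to \code{reference} or a data.frame from
#'   [scoreCohort()] with \code{sample_id} and \code{tp53_status} columns.
#' @param reference reference status; either a vector or a data.frame with
#'   \code{sample_id} and a status column. When both arguments carry sample
#'   ids the rows are joined on them and any mismatch is an error naming the
#'   unmatched ids.
#' @return A list with \code{rate} (matches / total), \code{table} (2x2
#'   call-by-reference contingency table) and \code{n}.
#' @examples
#' fx <- table1Fixture()
#' agreementRate(fx$status_by_score, fx$status_by_microarray)$rate  # 0.971
#' @export
agreementRate <- function(call, reference) {
  get_status <- function(x, cols) {
    if (is.data.frame(x)) {
      col <- intersect(cols, names(x))[1]
      if (is.na(col))
        tp53_stop("tp53sig_parse_error",
                  paste0("data.frame needs one of columns: ",
                         paste(cols, collapse = ", ")))
      setNames(as.character(x[[col]]), x$sample_id)
    } else as.character(x)
  }
  cl <- get_status(call, c("tp53_status", "status_by_score", "status"))
  rf <- get_status(reference, c("reference_status", "status_by_microarray",
                                "status"))
  if (!is.null(names(cl)) && !is.null(names(rf))) {
    unmatched <- c(setdiff(names(cl), names(rf)), setdiff(names(rf), names(cl)))
    if (length(unmatched))
      tp53_stop("tp53sig_alignment_error",
                paste0("sample ids do not match: ",
                       paste(unique(unmatched), collapse = ", ")))
    rf <- rf[names(cl)]
  } else if (length(cl) != length(rf)) {
    tp53_stop("tp53sig_alignment_error", "call and reference lengths differ")
  }
  lv <- c("wild", "mutant")
  tab <- table(call = factor(cl, lv), reference = factor(rf, lv))
  list(rate = sum(diag(tab)) / sum(tab), table = tab, n = sum(tab))
}
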