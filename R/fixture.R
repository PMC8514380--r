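#' The 34-sample development-cohort fixture
#'
#' The development cohort used to calibrate the
#' signature-score cutoff: 34 breast tumours with the multiplex RT-PCR
#' signature score, the score-derived TP53 status at cutoff 1.11, and the
#' reference TP53 status from the original microarray signature. One sample
#' (BR013, score 1.4350) is called mutant by score but wild by microarray --
#' the single discordance behind the published 97.1% agreement -- and the
#' scores span 0.1707 to 4.0595.
#'
#' @return A data.frame with 34 rows and columns \code{sample_id},
#'   \code{tp53_signature_score}, \code{status_by_score} and
#'   \code{status_by_microarray} (both status columns lower-case factors with
#'   levels wild/mutant).
#' @examples
#' fx <- table1Fixture()
#' nrow(fx)                      # 34
#' table(fx$status_by_microarray)  # 18 wild, 16 mutant
#' @export
table1Fixture <- function() {
  path <- system.file("extdata", "table1_dev_cohort.tsv", package = "tp53sig",
                      mustWork = TRUE)
  fx <- read.delim(path, stringsAsFactors = FALSE)
  lv <- c("wild", "mutant")
  fx$status_by_score <- factor(tolower(fx$status_by_score), lv)
  fx$status_by_microarray <- factor(tolower(fx$status_by_microarray), lv)
  fx
}
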