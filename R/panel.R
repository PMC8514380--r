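#' GenePanel: the up/down/control partition of signature genes
#'
#' An S4 class holding the gene panel that defines the TP53 signature score:
#' the genes up-regulated in TP53-mutant tumours (numerator), the genes
#' down-regulated (denominator), and internal-control genes that never enter
#' the score and serve only as a detection QC gate. The published panel has
#' 16 up, 7 down and 3 control genes (26 in total); the class accepts any
#' non-empty, pairwise-disjoint partition so the gene identifiers can be
#' swapped in from a configuration file without code change.
#'
#' @slot upGenes character vector of up-regulated gene identifiers.
#' @slot downGenes character vector of down-regulated gene identifiers.
#' @slot controlGenes character vector of internal-control gene identifiers
#'   (may be empty).
#'
#' @seealso [GenePanel()], [defaultPanel()], [readPanel()]
#' @export
setClass("GenePanel", slots = c(
  upGenes = "character",
  downGenes = "character",
  controlGenes = "character"
))

setValidity("GenePanel", function(object) {
  up <- object@upGenes; dn <- object@downGenes; ct <- object@controlGenes
  all_genes <- c(up, dn, ct)
  msgs <- character()
  if (length(up) < 1L) msgs <- c(msgs, "panel needs at least one up-regulated gene")
  if (length(dn) < 1L) msgs <- c(msgs, "panel needs at least one down-regulated gene")
  if (anyDuplicated(all_genes)) {
    dup <- unique(all_genes[duplicated(all_genes)])
    msgs <- c(msgs, paste0("gene(s) appear in more than one role or twice: ",
                           paste(dup, collapse = ", ")))
  }
  if (any(is.na(all_genes)) || any(!nzchar(all_genes)))
    msgs <- c(msgs, "gene identifiers must be non-empty and non-NA")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenePanel
#'
#' @param upGenes character vector of up-regulated genes (score numerator).
#' @param downGenes character vector of down-regulated genes (denominator).
#' @param controlGenes character vector of internal-control genes; default
#'   none. Controls never enter the score.
#' @return A validated [GenePanel-class] object.
#' @examples
#' GenePanel(c("g1", "g2"), "g3")
#' @export
GenePanel <- function(upGenes, downGenes, controlGenes = character()) {
  new("GenePanel",
      upGenes = as.character(upGenes),
      downGenes = as.character(downGenes),
      controlGenes = as.character(controlGenes))
}

#' @describeIn GenePanel-class up-regulated genes
#' @param x,object a \code{GenePanel}
#' @export
upGenes <- function(x) x@upGenes

#' @describeIn GenePanel-class down-regulated genes
#' @export
downGenes <- function(x) x@downGenes

#' @describeIn GenePanel-class internal-control genes
#' @export
controlGenes <- function(x) x@controlGenes

#' @describeIn GenePanel-class all panel genes, up then down then controls
#' @export
panelGenes <- function(x) c(x@upGenes, x@downGenes, x@controlGenes)

setMethod("show", "GenePanel", function(object) {
  cat("GenePanel with", length(object@upGenes), "up /",
      length(object@downGenes), "down /",
      length(object@controlGenes), "control genes\n")
  cat("  up:      ", paste(head(object@upGenes, 8), collapse = " "),
      if (length(object@upGenes) > 8) "...", "\n")
  cat("  down:    ", paste(object@downGenes, collapse = " "), "\n")
  if (length(object@controlGenes))
    cat("  control: ", paste(object@controlGenes, collapse = " "), "\n")
  invisible(NULL)
})

#' The default 26-gene placeholder panel
#'
#' The published panel's gene identities live in assay documentation rather
#' than in code; this package ships a positionally equivalent placeholder
#' panel (UP01..UP16, DN01..DN07, CTRL1..CTRL3) so every operation is
#' testable. Substitute real identifiers with [GenePanel()] or
#' [readPanel()] -- nothing else changes.
#'
#' @return A [GenePanel-class] with 16 up, 7 down and 3 control genes.
#' @examples
#' defaultPanel()
#' @export
defaultPanel <- function() {
  GenePanel(sprintf("UP%02d", 1:16), sprintf("DN%02d", 1:7),
            sprintf("CTRL%d", 1:3))
}

#' Read a gene panel from a TSV or YAML file
#'
#' TSV format: columns \code{gene_id} and \code{role}, role one of
#' \code{up}, \code{down}, \code{control}. YAML format: top-level keys
#' \code{up}, \code{down}, \code{control}, each a list of identifiers.
#'
#' @param path path to the panel file; format detected from the extension
#'   (\code{.yml}/\code{.yaml} vs anything else = TSV).
#' @return A validated [GenePanel-class].
#' @export
readPanel <- function(path) {
  if (!file.exists(path))
    tp53_stop("tp53sig_io_error", paste0("panel file not found: ", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    return(GenePanel(unlist(y$up), unlist(y$down),
                     as.character(unlist(y$control))))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "role")
  if (!all(need %in% names(tab)))
    tp53_stop("tp53sig_parse_error",
              paste0("panel TSV must have columns ", paste(need, collapse = ", ")))
  bad <- setdiff(unique(tab$role), c("up", "down", "control"))
  if (length(bad))
    tp53_stop("tp53sig_vocabulary_error",
              paste0("unknown panel role(s): ", paste(bad, collapse = ", "),
                     "; allowed: up, down, control"))
  GenePanel(tab$gene_id[tab$role == "up"],
            tab$gene_id[tab$role == "down"],
            tab$gene_id[tab$role == "control"])
}
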