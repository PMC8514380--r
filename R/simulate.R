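#' Configuration for the synthetic-cohort simulator
#'
#' Bundles every parameter of the cohort generator. The defaults emulate a
#' 189-patient stage I-II breast-cancer validation cohort: 89/189 mutant
#' signature, class-conditional covariate frequencies matching the published
#' characteristics table, a proportional-hazards recurrence process with a
#' true TP53 hazard ratio of 3.96 plus direct stage (HR 2.60) and nodal
#' (HR 2.55) effects, and administrative censoring uniform over a 10.18-year
#' accrual window. Per-class score distributions are log-normal with medians
#' 0.60 (wild) and 2.0 (mutant), chosen from the development cohort's score
#' spread so that classification at cutoff 1.11 has a small (~2-3%)
#' crossover and a large-sample AUC near 0.99.
#'
#' @param nPatients cohort size; default 189.
#' @param fracMutant probability a patient is truly mutant-signature;
#'   default 89/189.
#' @param scoreMeanlog,scoreSdlog named numerics (\code{wild},
#'   \code{mutant}): log-normal parameters of the per-sample true score.
#' @param sampleScaleSdlog sdlog of the per-sample global expression scale
#'   factor (the score is invariant to it); default 0.5.
#' @param geneNoiseSdlog per-gene multiplicative log-normal noise; default
#'   0.25.
#' @param covariateProbs class-conditional covariate probabilities; see the
#'   default for the structure. Categorical entries are lists with
#'   \code{mutant}/\code{wild} probability vectors; binary entries are named
#'   numerics \code{c(mutant=, wild=)} giving P(positive-level).
#' @param trueLogHR true log hazard ratio of mutant vs wild signature for
#'   recurrence; default log(3.96).
#' @param covariateLogHR named numeric of direct log-HR covariate effects on
#'   the recurrence hazard; default stage II vs I log(2.60) and node-positive
#'   log(2.55). Set to \code{c()} for a signature-only hazard.
#' @param baselineHazard recurrence hazard (events/year) for a wild-type,
#'   stage I, node-negative patient; default 0.0035, giving roughly 15-25
#'   recurrences in the default cohort over the follow-up window.
#' @param postRecurrenceRate rate (1/years) of breast-cancer death after
#'   recurrence; default 0.5 (mean two years from recurrence to death).
#' @param otherCauseRate hazard of death from other causes; default 0.01.
#' @param censorTimeMax upper bound of the uniform censoring time, years;
#'   default 10.18.
#' @param seed default random seed used when none is passed to a generator.
#' @return A validated list of class \code{"tp53sig_sim_config"}.
#' @export
simConfig <- function(nPatients = 189L,
                      fracMutant = 89 / 189,
                      scoreMeanlog = c(wild = log(0.60), mutant = log(2.0)),
                      scoreSdlog = c(wild = 0.28, mutant = 0.32),
                      sampleScaleSdlog = 0.5,
                      geneNoiseSdlog = 0.25,
                      covariateProbs = defaultCovariateProbs(),
                      trueLogHR = log(3.96),
                      covariateLogHR = c(p_stage = log(2.60), p_ln = log(2.55)),
                      baselineHazard = 0.0035,
                      postRecurrenceRate = 0.5,
                      otherCauseRate = 0.01,
                      censorTimeMax = 10.18,
                      seed = 1L) {
  cfg <- list(nPatients = as.integer(nPatients), fracMutant = fracMutant,
              scoreMeanlog = scoreMeanlog, scoreSdlog = scoreSdlog,
              sampleScaleSdlog = sampleScaleSdlog,
              geneNoiseSdlog = geneNoiseSdlog,
              covariateProbs = covariateProbs, trueLogHR = trueLogHR,
              covariateLogHR = covariateLogHR,
              baselineHazard = baselineHazard,
              postRecurrenceRate = postRecurrenceRate,
              otherCauseRate = otherCauseRate,
              censorTimeMax = censorTimeMax, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "tp53sig_sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(msg) tp53_stop("tp53sig_config_error", msg)
  if (cfg$nPatients < 2L) fail("nPatients must be at least 2")
  if (cfg$fracMutant <= 0 || cfg$fracMutant >= 1)
    fail("fracMutant must lie in (0, 1)")
  for (nm in c("wild", "mutant")) {
    if (!nm %in% names(cfg$scoreMeanlog) || !nm %in% names(cfg$scoreSdlog))
      fail("scoreMeanlog/scoreSdlog need named 'wild' and 'mutant' entries")
  }
  if (any(cfg$scoreSdlog < 0) || cfg$sampleScaleSdlog < 0 ||
      cfg$geneNoiseSdlog < 0)
    fail("log-normal sd parameters must be non-negative")
  if (cfg$baselineHazard <= 0) fail("baselineHazard must be positive")
  if (cfg$postRecurrenceRate <= 0 || cfg$otherCauseRate < 0)
    fail("event-process rates must be positive")
  if (cfg$censorTimeMax <= 0) fail("censorTimeMax must be positive")
  p <- cfg$covariateProbs
  flat <- unlist(p[c("er_pos", "pgr_pos", "her2_pos", "pln_pos",
                     "ki67_high", "chemo", "endo")], use.names = FALSE)
  flat <- c(flat, unlist(p$stage), unlist(p$size), unlist(p$grade),
            p$grade_na, p$ki67_na)
  if (any(flat < 0 | flat > 1)) fail("covariate probabilities must lie in [0, 1]")
  invisible(cfg)
}

#' Default class-conditional covariate probabilities
#'
#' Frequencies of the clinical covariates given true signature class,
#' matching the published validation-cohort characteristics (e.g.
#' ER-positivity 55\% among mutant vs 89\% among wild-type signature
#' tumours). Covariates are drawn independently given class; correlations
#' among ER/PgR/grade beyond the shared class are not modelled.
#'
#' @return A named list consumed by [simConfig()].
#' @export
defaultCovariateProbs <- function() {
  list(
    er_pos   = c(mutant = 0.55, wild = 0.89),
    pgr_pos  = c(mutant = 0.38, wild = 0.67),
    her2_pos = c(mutant = 0.15, wild = 0.05),
    pln_pos  = c(mutant = 0.35, wild = 0.26),
    stage = list(mutant = c(I = 0.46, IIA = 0.37, IIB = 0.17),
                 wild   = c(I = 0.54, IIA = 0.32, IIB = 0.14)),
    size = list(mutant = c(0.66, 0.32, 0.02),   # <=2 / >2,<=5 / >5 cm
                wild   = c(0.66, 0.33, 0.01)),
    grade = list(mutant = c(0.09, 0.33, 0.58),
                 wild   = c(0.40, 0.55, 0.05)),
    grade_na = 0.03,
    ki67_high = c(mutant = 0.87, wild = 0.49),
    ki67_na = 0.08,
    chemo = c(mutant = 0.61, wild = 0.32),
    endo  = c(mutant = 0.55, wild = 0.88),
    age_median = c(mutant = 59, wild = 56),
    age_sd = 12
  )
}

# fixed per-gene baseline expression levels (arbitrary linear units spanning
# the dynamic range of a multiplex assay)
sim_gene_baselines <- function(panel) {
  up <- exp(seq(log(40), log(600), length.out = length(upGenes(panel))))
  dn <- exp(seq(log(60), log(400), length.out = length(downGenes(panel))))
  ct <- rep(250, length(controlGenes(panel)))
  setNames(c(up, dn, ct), panelGenes(panel))
}

#' Simulate expression profiles with known signature class
#'
#' Per patient: draw the true class (mutant with probability
#' \code{fracMutant}), draw a target signature score from the class's
#' log-normal, draw per-gene expression around fixed gene baselines with
#' multiplicative log-normal noise, rescale the up-gene block so the sample's
#' score equals its target exactly, and apply a per-sample global scale
#' factor (to which the score is invariant). The class score distributions
#' overlap slightly, so classification at the published cutoff is
#' imperfect -- as in real data.
#'
#' @param config a [simConfig()].
#' @param panel a [GenePanel-class]; default [defaultPanel()].
#' @param seed integer seed; default \code{config$seed}. Identical
#'   (config, seed) give bit-identical output.
#' @return A list: \code{expression} (nPatients x 26 matrix, samples in
#'   rows), \code{labels} (factor wild/mutant, the true class) and
#'   \code{trueScore} (the per-sample target score).
#' @export
simulateExpression <- function(config = simConfig(), panel = defaultPanel(),
                               seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  n <- config$nPatients
  cls <- ifelse(runif(n) < config$fracMutant, "mutant", "wild")
  labels <- factor(cls, levels = c("wild", "mutant"))
  score <- rlnorm(n, config$scoreMeanlog[cls], config$scoreSdlog[cls])
  base <- sim_gene_baselines(panel)
  genes <- names(base)
  mat <- matrix(rlnorm(n * length(genes), 0, config$geneNoiseSdlog),
                nrow = n) * rep(base, each = n)
  colnames(mat) <- genes
  rownames(mat) <- sprintf("S%04d", seq_len(n))
  up <- upGenes(panel); dn <- downGenes(panel)
  up_sum <- rowSums(mat[, up, drop = FALSE])
  dn_sum <- rowSums(mat[, dn, drop = FALSE])
  mat[, up] <- mat[, up, drop = FALSE] * (score * dn_sum / up_sum)
  mat <- mat * rlnorm(n, 0, config$sampleScaleSdlog)
  list(expression = mat, labels = setNames(labels, rownames(mat)),
       trueScore = setNames(score, rownames(mat)))
}

# indicator of the at-risk level for each covariate effect name
cov_effect_indicator <- function(name, rec) {
  switch(name,
         p_stage = as.numeric(rec$p_stage != "I"),
         p_ln = as.numeric(rec$p_ln == "positive"),
         tumor_size = as.numeric(rec$tumor_size_cm > 2),
         grade = as.numeric(!is.na(rec$grade) & rec$grade == 3),
         er = as.numeric(rec$er == "negative"),
         pgr = as.numeric(rec$pgr == "negative"),
         her2 = as.numeric(rec$her2 == "positive"),
         ki67 = as.numeric(!is.na(rec$ki67_pct) & rec$ki67_pct >= 10),
         adj_chemo = as.numeric(rec$adj_chemo == "yes"),
         adj_endocrine = as.numeric(rec$adj_endocrine == "yes"),
         tp53_stop("tp53sig_config_error",
                   paste0("unknown covariateLogHR entry: ", name)))
}

#' Simulate clinical covariates and survival endpoints
#'
#' Given true class labels, draws the clinical covariates from the
#' class-conditional probabilities and generates consistent RFS/OS/BCSS
#' endpoints from a proportional-hazards process: exponential recurrence
#' times with hazard \eqn{h_0 \exp(\beta_{TP53} 1[mutant] + \sum_k \beta_k
#' x_k)}, breast-cancer death following recurrence after an exponential lag,
#' an independent other-cause death process, and uniform censoring on
#' (0, censorTimeMax]. By construction \code{rfs_time <= os_time} and a
#' breast-cancer death is always a death.
#'
#' @param labels factor of true classes from [simulateExpression()].
#' @param config a [simConfig()]; \code{nPatients} must equal
#'   \code{length(labels)}.
#' @param seed integer seed; default \code{config$seed + 1} so that a cohort
#'   built from the same base seed does not reuse the expression draws.
#' @return A cohort data.frame, one row per patient: \code{sample_id},
#'   \code{age} (years), \code{p_stage} (I/IIA/IIB), \code{p_ln},
#'   \code{tumor_size_cm}, \code{grade} (1/2/3, NA possible), \code{er},
#'   \code{pgr}, \code{her2}, \code{ki67_pct} (NA possible),
#'   \code{adj_chemo}, \code{adj_endocrine}, \code{tp53_status} (the true
#'   class), and \code{rfs_/os_/bcss_time} (years) with matching
#'   \code{_event} flags (1 = event, 0 = censored).
#' @export
simulateClinical <- function(labels, config = simConfig(),
                             seed = config$seed + 1L) {
  validate_sim_config(config)
  n <- length(labels)
  if (n != config$nPatients)
    tp53_stop("tp53sig_alignment_error",
              sprintf("labels (%d) do not match config$nPatients (%d)",
                      n, config$nPatients))
  set.seed(seed)
  cls <- as.character(labels)
  p <- config$covariateProbs
  pick <- function(probs) unname(probs[cls])
  draw_bin <- function(probs, yes, no)
    ifelse(runif(n) < pick(probs), yes, no)
  # inverse-CDF draw so each patient consumes exactly one uniform,
  # independent of the class mix
  draw_cat <- function(probs, levels_) {
    u <- runif(n)
    out <- character(n)
    for (k in c("wild", "mutant")) {
      idx <- cls == k
      breaks <- cumsum(probs[[k]])[-length(probs[[k]])]
      out[idx] <- levels_[findInterval(u[idx], breaks, left.open = TRUE) + 1L]
    }
    out
  }
  age <- pmin(98, pmax(26, round(rnorm(n, pick(p$age_median), p$age_sd))))
  p_stage <- draw_cat(p$stage, c("I", "IIA", "IIB"))
  size_class <- draw_cat(p$size, c("small", "medium", "large"))
  tumor_size_cm <- round(ifelse(size_class == "small", runif(n, 0.4, 2.0),
                         ifelse(size_class == "medium", runif(n, 2.05, 5.0),
                                runif(n, 5.05, 9.0))), 1)
  grade <- as.integer(draw_cat(p$grade, c("1", "2", "3")))
  grade[runif(n) < p$grade_na] <- NA
  ki67_high <- runif(n) < pick(p$ki67_high)
  ki67_pct <- round(ifelse(ki67_high, runif(n, 10, 60), runif(n, 1, 9.5)), 1)
  ki67_pct[runif(n) < p$ki67_na] <- NA
  rec <- data.frame(
    sample_id = if (!is.null(names(labels))) names(labels) else
      sprintf("S%04d", seq_len(n)),
    age = age, p_stage = p_stage,
    p_ln = draw_bin(p$pln_pos, "positive", "negative"),
    tumor_size_cm = tumor_size_cm, grade = grade,
    er = draw_bin(p$er_pos, "positive", "negative"),
    pgr = draw_bin(p$pgr_pos, "positive", "negative"),
    her2 = draw_bin(p$her2_pos, "positive", "negative"),
    ki67_pct = ki67_pct,
    adj_chemo = draw_bin(p$chemo, "yes", "no"),
    adj_endocrine = draw_bin(p$endo, "yes", "no"),
    tp53_status = cls,
    row.names = NULL, stringsAsFactors = FALSE)

  lp <- config$trueLogHR * as.numeric(cls == "mutant")
  for (nm in names(config$covariateLogHR))
    lp <- lp + config$covariateLogHR[[nm]] * cov_effect_indicator(nm, rec)
  t_rec <- rexp(n, config$baselineHazard * exp(lp))
  t_bc_death <- t_rec + rexp(n, config$postRecurrenceRate)
  t_oth_death <- rexp(n, max(config$otherCauseRate, 1e-12))
  t_cens <- runif(n, 0, config$censorTimeMax)

  rec$rfs_time <- pmin(t_rec, t_oth_death, t_cens)
  rec$rfs_event <- as.integer(t_rec <= pmin(t_oth_death, t_cens))
  t_death <- pmin(t_bc_death, t_oth_death)
  rec$os_time <- pmin(t_death, t_cens)
  rec$os_event <- as.integer(t_death <= t_cens)
  rec$bcss_time <- pmin(t_bc_death, t_oth_death, t_cens)
  rec$bcss_event <- as.integer(t_bc_death <= pmin(t_oth_death, t_cens))
  rec
}

#' Simulate a full expression-plus-clinical cohort
#'
#' Convenience wrapper: [simulateExpression()] then [simulateClinical()] on
#' the same labels, deterministically derived from one base seed.
#'
#' @inheritParams simulateExpression
#' @return A list: \code{expression}, \code{clinical}, \code{labels},
#'   \code{trueScore}, \code{config}, \code{seed}.
#' @examples
#' cohort <- simulateCohort(simConfig(nPatients = 50), seed = 7)
#' head(scoreCohort(cohort$expression))
#' @export
simulateCohort <- function(config = simConfig(), panel = defaultPanel(),
                           seed = config$seed) {
  ex <- simulateExpression(config, panel, seed = seed)
  cl <- simulateClinical(ex$labels, config, seed = seed + 1L)
  list(expression = ex$expression, clinical = cl, labels = ex$labels,
       trueScore = ex$trueScore, config = config, seed = seed)
}
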