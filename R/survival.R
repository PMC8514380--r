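#' @importFrom survival Surv survfit survdiff coxph coxph.control
NULL

ENDPOINTS <- c("rfs", "os", "bcss")

ep_cols <- function(endpoint) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  c(time = paste0(endpoint, "_time"), event = paste0(endpoint, "_event"))
}

# pull and validate the (time, event) pair for one endpoint
ep_surv <- function(records, endpoint) {
  cols <- ep_cols(endpoint)
  miss <- setdiff(cols, names(records))
  if (length(miss))
    tp53_stop("tp53sig_missing_column",
              paste0("endpoint '", endpoint, "' needs column(s): ",
                     paste(miss, collapse = ", ")))
  time <- records[[cols["time"]]]
  event <- records[[cols["event"]]]
  if (any(!is.na(time) & time < 0))
    tp53_stop("tp53sig_invalid_record",
              paste0("negative ", cols["time"], " at row(s): ",
                     paste(which(!is.na(time) & time < 0), collapse = ", ")))
  if (!all(stats::na.omit(event) %in% c(0, 1)))
    tp53_stop("tp53sig_invalid_record",
              paste0(cols["event"], " must be 0 (censored) or 1 (event)"))
  data.frame(time = time, event = event)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate of the survivor function for one endpoint,
#' optionally per group. Censored subjects leave the risk set without a drop
#' in the curve; event times produce the usual multiplicative steps
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}.
#'
#' @param records a cohort data.frame (see [readClinicalTable()] or
#'   [simulateCohort()]) with \code{<endpoint>_time} / \code{<endpoint>_event}
#'   columns; times in years.
#' @param endpoint one of \code{"rfs"}, \code{"os"}, \code{"bcss"}.
#' @param groupBy optional name of a grouping column (e.g.
#'   \code{"tp53_status"}); \code{NULL} for a single pooled curve.
#' @return A list with \code{curves}, a data.frame of columns \code{group},
#'   \code{time}, \code{n_risk}, \code{n_event}, \code{n_censor},
#'   \code{survival}; and \code{fit}, the underlying
#'   \code{\link[survival]{survfit}} object (usable with \code{plot()},
#'   censor ticks included).
#' @export
kaplanMeier <- function(records, endpoint = "rfs", groupBy = NULL) {
  if (!NROW(records))
    tp53_stop("tp53sig_empty_input", "no records")
  sv <- ep_surv(records, endpoint)
  if (is.null(groupBy)) {
    grp <- factor(rep("all", nrow(sv)))
  } else {
    if (!groupBy %in% names(records))
      tp53_stop("tp53sig_missing_column", paste0("no column '", groupBy, "'"))
    grp <- factor(records[[groupBy]])
  }
  keep <- complete.cases(sv) & !is.na(grp)
  d <- data.frame(sv[keep, ], group = droplevels(grp[keep]))
  fit <- survfit(Surv(time, event) ~ group, data = d)
  sm <- summary(fit, censored = TRUE)
  group <- if (is.null(sm$strata)) levels(d$group)[1] else
    sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = group, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, n_censor = sm$n.censor,
                       survival = sm$surv, row.names = NULL)
  list(curves = curves, fit = fit)
}

#' Log-rank test between survival curves
#'
#' Standard (unweighted) log-rank chi-squared comparing the event
#' experience of two or more groups, with degrees of freedom one less than
#' the number of groups and the p-value from the chi-squared upper tail.
#'
#' @inheritParams kaplanMeier
#' @param groupBy name of the grouping column; default \code{"tp53_status"}.
#' @return A list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{n} (per-group sizes) and \code{observed}/\code{expected} event
#'   counts per group.
#' @export
logRank <- function(records, endpoint = "rfs", groupBy = "tp53_status") {
  sv <- ep_surv(records, endpoint)
  if (!groupBy %in% names(records))
    tp53_stop("tp53sig_missing_column", paste0("no column '", groupBy, "'"))
  grp <- factor(records[[groupBy]])
  keep <- complete.cases(sv) & !is.na(grp)
  d <- data.frame(sv[keep, ], group = droplevels(grp[keep]))
  if (nlevels(d$group) < 2L)
    tp53_stop("tp53sig_degenerate_grouping",
              "log-rank needs at least two non-empty groups")
  sd <- survdiff(Surv(time, event) ~ group, data = d)
  df <- nlevels(d$group) - 1L
  stat <- unname(sd$chisq)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       n = setNames(as.numeric(sd$n), levels(d$group)),
       observed = setNames(as.numeric(sd$obs), levels(d$group)),
       expected = setNames(as.numeric(sd$exp), levels(d$group)))
}

# registry of the prognostic variables: how each clinical column is
# dichotomised for the Cox models and which level is the reference
cox_variable_registry <- function() {
  bin <- function(col, ref, alt, f) list(column = col, reference = ref,
                                         contrast = alt, build = f)
  lv2 <- function(x, ref, alt) factor(as.character(x), levels = c(ref, alt))
  list(
    p_stage = bin("p_stage", "I", "II",
                  function(r) factor(ifelse(r$p_stage == "I", "I", "II"),
                                     levels = c("I", "II"))),
    p_ln = bin("p_ln", "negative", "positive",
               function(r) lv2(r$p_ln, "negative", "positive")),
    tumor_size = bin("tumor_size_cm", "T1", ">T1",
                     function(r) factor(ifelse(r$tumor_size_cm <= 2, "T1", ">T1"),
                                        levels = c("T1", ">T1"))),
    grade = bin("grade", "1-2", "3",
                function(r) factor(ifelse(r$grade %in% c(1, 2), "1-2", "3"),
                                   levels = c("1-2", "3"))),
    er = bin("er", "positive", "negative",
             function(r) lv2(r$er, "positive", "negative")),
    pgr = bin("pgr", "positive", "negative",
              function(r) lv2(r$pgr, "positive", "negative")),
    her2 = bin("her2", "negative", "positive",
               function(r) lv2(r$her2, "negative", "positive")),
    ki67 = bin("ki67_pct", "<10", ">=10",
               function(r) factor(ifelse(r$ki67_pct < 10, "<10", ">=10"),
                                  levels = c("<10", ">=10"))),
    adj_chemo = bin("adj_chemo", "no", "yes",
                    function(r) lv2(r$adj_chemo, "no", "yes")),
    adj_endocrine = bin("adj_endocrine", "no", "yes",
                        function(r) lv2(r$adj_endocrine, "no", "yes")),
    tp53_status = bin("tp53_status", "wild", "mutant",
                      function(r) lv2(r$tp53_status, "wild", "mutant"))
  )
}

build_cox_terms <- function(records, variables) {
  reg <- cox_variable_registry()
  unknown <- setdiff(variables, names(reg))
  if (length(unknown))
    tp53_stop("tp53sig_vocabulary_error",
              paste0("unknown Cox variable(s): ", paste(unknown, collapse = ", "),
                     "; known: ", paste(names(reg), collapse = ", ")))
  missing_col <- variables[vapply(variables, function(v)
    !reg[[v]]$column %in% names(records), logical(1))]
  if (length(missing_col))
    tp53_stop("tp53sig_missing_column",
              paste0("cohort lacks column(s) for variable(s): ",
                     paste(missing_col, collapse = ", ")))
  terms <- lapply(variables, function(v) reg[[v]]$build(records))
  names(terms) <- variables
  as.data.frame(terms, optional = TRUE)
}

cox_one_fit <- function(d, variables, model_type) {
  reg <- cox_variable_registry()
  for (v in variables) {
    if (all(is.na(d[[v]])))
      tp53_stop("tp53sig_missingness_error",
                paste0("variable '", v, "' is missing for every record"))
    if (length(unique(stats::na.omit(d[[v]]))) < 2L)
      tp53_stop("tp53sig_degenerate_variable",
                paste0("variable '", v, "' has a single level among complete cases"))
  }
  cc <- complete.cases(d)
  d <- d[cc, , drop = FALSE]
  if (sum(d$event) < 1L)
    tp53_stop("tp53sig_invalid_record", "no events among complete cases")
  fml <- as.formula(paste("Surv(time, event) ~",
                          paste(variables, collapse = " + ")))
  fit <- withCallingHandlers(
    coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("did not converge|infinite|beta may be infinite",
                conditionMessage(w)))
        tp53_stop("tp53sig_convergence_error",
                  paste0("Cox fit failed to converge: ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  data.frame(
    variable = variables,
    reference = vapply(variables, function(v) reg[[v]]$reference, character(1)),
    contrast = vapply(variables, function(v) reg[[v]]$contrast, character(1)),
    hazard_ratio = unname(co[, "exp(coef)"]),
    ci_low = unname(ci[, "lower .95"]),
    ci_high = unname(ci[, "upper .95"]),
    p_value = unname(co[, "Pr(>|z|)"]),
    model_type = model_type,
    n = s$n, events = s$nevent,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Cox proportional-hazards models for prognostic variables
#'
#' Fits Cox models (partial likelihood, Efron tie handling) for one
#' endpoint. With \code{modelType = "univariate"} each variable is fitted in
#' its own model; with \code{"multivariate"} all variables enter one joint
#' model on complete cases (exclusion counts reported via message). Each
#' variable is dichotomised per the package's prognostic codings: stage II
#' vs I, node-positive vs negative, tumour >2 cm vs T1, grade 3 vs 1-2, ER/
#' PgR negative vs positive, HER2 positive vs negative, Ki-67 >=10% vs <10%,
#' adjuvant therapy vs none, TP53 mutant vs wild signature.
#'
#' @inheritParams kaplanMeier
#' @param variables character vector of variable names from the registry
#'   (see Details of [runTable3()]); default all eleven.
#' @param modelType \code{"univariate"} or \code{"multivariate"}.
#' @return A data.frame with one row per variable: \code{variable},
#'   \code{reference}, \code{contrast}, \code{hazard_ratio}, \code{ci_low},
#'   \code{ci_high} (Wald 95\% CI), \code{p_value} (Wald), \code{model_type},
#'   \code{n}, \code{events}.
#' @export
coxFit <- function(records, endpoint = "rfs",
                   variables = names(cox_variable_registry()),
                   modelType = c("univariate", "multivariate")) {
  modelType <- match.arg(modelType)
  sv <- ep_surv(records, endpoint)
  terms <- build_cox_terms(records, variables)
  base <- cbind(sv, terms)
  if (modelType == "univariate") {
    do.call(rbind, lapply(variables, function(v)
      cox_one_fit(base[, c("time", "event", v)], v, "univariate")))
  } else {
    n_excl <- sum(!complete.cases(base))
    if (n_excl) message(n_excl, " record(s) excluded from the multivariate ",
                        "model for missing data")
    cox_one_fit(base, variables, "multivariate")
  }
}

#' Univariate-then-multivariate Cox analysis of recurrence-free survival
#'
#' Reproduces the standard two-stage prognostic-factor table: univariate Cox
#' models for all eleven clinicopathological variables (stage, nodal status,
#' tumour size, grade, ER, PgR, HER2, Ki-67, adjuvant chemo/endocrine
#' therapy, TP53 signature status), then one multivariate model containing
#' the variables whose univariate Wald p-value is at most \code{entryP}.
#' A variable never enters the multivariate model without univariate
#' significance, by construction.
#'
#' @inheritParams kaplanMeier
#' @param entryP univariate p-value threshold for multivariate entry;
#'   default 0.05 (inclusive, so a variable printing exactly p = 0.05
#'   enters).
#' @return A list with \code{univariate} (11-row data.frame; a variable
#'   whose own model is degenerate -- e.g. no events at one level, so the
#'   partial likelihood is monotone -- gets NA estimates and a \code{note}
#'   and cannot be selected), \code{selected} (variables entering the
#'   multivariate model) and \code{multivariate} (data.frame, or \code{NULL}
#'   with a message when fewer than one variable is selected or the joint
#'   fit does not converge).
#' @export
runTable3 <- function(records, endpoint = "rfs", entryP = 0.05) {
  if (length(unique(stats::na.omit(records$tp53_status))) < 2L)
    tp53_stop("tp53sig_degenerate_variable",
              "tp53_status has a single level; nothing to compare")
  vars <- names(cox_variable_registry())
  uni <- do.call(rbind, lapply(vars, function(v) {
    row <- tryCatch(coxFit(records, endpoint, v, "univariate"),
                    tp53sig_error = function(e) {
                      data.frame(variable = v, reference = NA, contrast = NA,
                                 hazard_ratio = NA_real_, ci_low = NA_real_,
                                 ci_high = NA_real_, p_value = NA_real_,
                                 model_type = "univariate", n = NA_integer_,
                                 events = NA_integer_,
                                 stringsAsFactors = FALSE)
                    })
    row$note <- if (is.na(row$hazard_ratio)) "fit degenerate; excluded" else ""
    row
  }))
  selected <- uni$variable[!is.na(uni$p_value) & uni$p_value <= entryP]
  multi <- NULL
  if (length(selected) >= 1L) {
    multi <- tryCatch(
      coxFit(records, endpoint, variables = selected,
             modelType = "multivariate"),
      tp53sig_convergence_error = function(e) {
        message("multivariate fit did not converge: ", conditionMessage(e))
        NULL
      })
  } else {
    message("no variable reached univariate p <= ", entryP,
            "; multivariate step skipped")
  }
  list(univariate = uni, selected = selected, multivariate = multi)
}

#' Molecular subtype from receptor status and Ki-67
#'
#' Operational subtype definitions: luminal A-like = ER-positive with
#' Ki-67 < 10\%; luminal B-like = ER-positive with Ki-67 >= 10\% (the
#' boundary value 10 goes high); TNBC = ER-, PgR- and HER2-negative.
#' ER-positive tumours with missing Ki-67 and tumours fitting none of the
#' definitions return NA.
#'
#' @param records cohort data.frame with \code{er}, \code{pgr}, \code{her2},
#'   \code{ki67_pct} columns.
#' @return Character vector: \code{"LuminalA"}, \code{"LuminalB"},
#'   \code{"TNBC"} or NA per record.
#' @examples
#' assignSubtype(data.frame(er = "positive", pgr = "negative",
#'                          her2 = "negative", ki67_pct = 8))  # LuminalA
#' @export
assignSubtype <- function(records) {
  er_pos <- records$er == "positive"
  sub <- rep(NA_character_, NROW(records))
  sub[er_pos & !is.na(records$ki67_pct) & records$ki67_pct < 10] <- "LuminalA"
  sub[er_pos & !is.na(records$ki67_pct) & records$ki67_pct >= 10] <- "LuminalB"
  sub[records$er == "negative" & records$pgr == "negative" &
        records$her2 == "negative"] <- "TNBC"
  sub
}

#' Recurrence-free survival by TP53 signature within subgroups
#'
#' Runs the TP53-signature log-rank comparison of RFS inside each of eight
#' subgroups: ER-positive, ER-negative, luminal A-like, luminal B-like,
#' TNBC, and histological grades 1, 2 and 3. Records missing the
#' subgroup-defining field are excluded per subgroup. A subgroup with fewer
#' than two TP53 classes, or with zero events overall, is reported with a
#' note instead of a p-value rather than a degenerate test.
#'
#' @inheritParams kaplanMeier
#' @return A list with \code{summary}, a data.frame of columns
#'   \code{subgroup}, \code{n}, \code{n_mutant}, \code{n_wild},
#'   \code{events}, \code{statistic}, \code{p_value}, \code{note}; and
#'   \code{curves}, a named list of [kaplanMeier()] results for the testable
#'   subgroups.
#' @export
subgroupRFS <- function(records, endpoint = "rfs") {
  subtype <- assignSubtype(records)
  defs <- list(
    "ER+"      = records$er == "positive",
    "ER-"      = records$er == "negative",
    "LuminalA" = subtype == "LuminalA",
    "LuminalB" = subtype == "LuminalB",
    "TNBC"     = subtype == "TNBC",
    "Grade1"   = records$grade == 1,
    "Grade2"   = records$grade == 2,
    "Grade3"   = records$grade == 3
  )
  cols <- ep_cols(endpoint)
  curves <- list()
  rows <- lapply(names(defs), function(nm) {
    keep <- !is.na(defs[[nm]]) & defs[[nm]]
    sub <- records[keep, , drop = FALSE]
    n_mut <- sum(sub$tp53_status == "mutant", na.rm = TRUE)
    n_wld <- sum(sub$tp53_status == "wild", na.rm = TRUE)
    ev <- sum(sub[[cols["event"]]], na.rm = TRUE)
    out <- data.frame(subgroup = nm, n = nrow(sub), n_mutant = n_mut,
                      n_wild = n_wld, events = ev, statistic = NA_real_,
                      p_value = NA_real_, note = "", stringsAsFactors = FALSE)
    if (nrow(sub) == 0L) {
      out$note <- "empty subgroup; skipped"
      message("subgroup ", nm, ": empty; skipped")
    } else if (n_mut == 0L || n_wld == 0L) {
      out$note <- "single TP53 class; test not carried out"
      message("subgroup ", nm, ": single TP53 class; test not carried out")
    } else if (ev == 0L) {
      out$note <- "zero events; log-rank degenerate"
    } else {
      lr <- logRank(sub, endpoint, "tp53_status")
      out$statistic <- lr$statistic
      out$p_value <- lr$p_value
      curves[[nm]] <<- kaplanMeier(sub, endpoint, "tp53_status")
    }
    out
  })
  list(summary = do.call(rbind, rows), curves = curves)
}

#' Baseline-characteristics comparison between signature classes
#'
#' Tests each baseline variable for association with TP53 signature status:
#' Kruskal-Wallis for age, chi-squared (no continuity correction) on the
#' contingency table over non-missing records for every categorical
#' variable. Missing values are excluded from the tests but reported as NA
#' counts.
#'
#' @inheritParams kaplanMeier
#' @param groupBy grouping column, default \code{"tp53_status"}.
#' @return A list with \code{summary}, a data.frame of \code{variable},
#'   \code{test}, \code{statistic}, \code{df}, \code{p_value},
#'   \code{n_missing}; and \code{tables}, the per-variable contingency
#'   tables (group x level, non-missing records).
#' @export
characteristicsTable <- function(records, groupBy = "tp53_status") {
  grp <- factor(records[[groupBy]])
  if (nlevels(droplevels(grp[!is.na(grp)])) < 2L)
    tp53_stop("tp53sig_degenerate_grouping",
              "characteristics table needs at least two groups")
  cat_var <- function(col, f = identity) {
    if (!col %in% names(records)) return(NULL)
    factor(f(records[[col]]))
  }
  vars <- list(
    p_stage = cat_var("p_stage"),
    er = cat_var("er"), pgr = cat_var("pgr"), her2 = cat_var("her2"),
    tumor_size = cat_var("tumor_size_cm", function(x)
      cut(x, c(0, 2, 5, Inf), labels = c("<=2", ">2, <=5", ">5"))),
    p_ln = cat_var("p_ln"),
    grade = cat_var("grade"),
    ki67 = cat_var("ki67_pct", function(x)
      ifelse(is.na(x), NA, ifelse(x < 10, "<10", ">=10"))),
    adj_chemo = cat_var("adj_chemo"),
    adj_endocrine = cat_var("adj_endocrine")
  )
  vars <- Filter(Negate(is.null), vars)
  tables <- list()
  rows <- list()
  if ("age" %in% names(records)) {
    kw <- kruskal.test(records$age, grp)
    rows[["age"]] <- data.frame(
      variable = "age", test = "kruskal-wallis",
      statistic = unname(kw$statistic), df = unname(kw$parameter),
      p_value = kw$p.value, n_missing = sum(is.na(records$age)),
      stringsAsFactors = FALSE)
  }
  for (nm in names(vars)) {
    v <- vars[[nm]]
    ok <- !is.na(v) & !is.na(grp)
    tab <- table(group = droplevels(grp[ok]), level = droplevels(v[ok]))
    tables[[nm]] <- tab
    if (ncol(tab) < 2L || nrow(tab) < 2L || any(rowSums(tab) == 0) ||
        any(colSums(tab) == 0)) {
      warning("variable '", nm, "': degenerate contingency table, ",
              "chi-squared skipped", call. = FALSE)
      rows[[nm]] <- data.frame(variable = nm, test = "chi-squared",
                               statistic = NA_real_, df = NA_real_,
                               p_value = NA_real_, n_missing = sum(is.na(v)),
                               stringsAsFactors = FALSE)
      next
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    rows[[nm]] <- data.frame(variable = nm, test = "chi-squared",
                             statistic = unname(ct$statistic),
                             df = unname(ct$parameter),
                             p_value = ct$p.value,
                             n_missing = sum(is.na(v)),
                             stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       tables = tables)
}
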