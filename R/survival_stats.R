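# Kaplan-Meier estimation and Mantel-Cox log-rank comparison for arbitrary
# patient stratifications. Estimation is delegated to the survival package;
# this module owns the grouping contracts and the tabular interfaces.

#' Kaplan-Meier product-limit curve for one group
#'
#' Right-censoring is honored; at tied times deaths precede censorings (the
#' standard convention). S(0) = 1 and the estimate is non-increasing.
#'
#' @param times Non-negative event/censoring times (months).
#' @param events Logical (or 0/1) vector, `TRUE` = death; same length as
#'   `times`.
#' @return `data.frame` with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` — one row per distinct observed time.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0L) stop("domain error: empty group")
  if (length(times) != length(events)) {
    stop("times and events must have equal length")
  }
  if (any(times < 0)) stop("domain error: negative survival time")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Mantel-Cox log-rank test across groups
#'
#' Observed-minus-expected chi-square statistic with `length(groups) - 1`
#' degrees of freedom; two-sided p from the upper chi-square tail, no
#' continuity correction.
#'
#' @param groups Named list of >= 2 groups, each a list with `times` and
#'   `events`.
#' @return List with `chisq`, `df`, `p`, `n` (total subjects), `n_events`,
#'   and `table` (per-group observed and expected event counts).
#' @export
logrank <- function(groups) {
  if (length(groups) < 2L) stop("domain error: need at least 2 groups")
  sizes <- vapply(groups, function(g) length(g$times), integer(1))
  if (any(sizes == 0L)) stop("domain error: empty group")
  times <- unlist(lapply(groups, `[[`, "times"))
  events <- as.integer(unlist(lapply(groups, `[[`, "events")))
  if (sum(events) == 0L) stop("domain error: no events in any group")
  label <- factor(rep(names(groups), sizes), levels = names(groups))
  sd <- survival::survdiff(survival::Surv(times, events) ~ label, rho = 0)
  df <- length(groups) - 1L
  chisq <- unname(sd$chisq)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df = df, lower.tail = FALSE),
       n = length(times), n_events = sum(events),
       table = data.frame(group = names(groups), n = as.integer(sizes),
                          observed = as.numeric(sd$obs),
                          expected = as.numeric(sd$exp),
                          stringsAsFactors = FALSE))
}

#' Stratify a cohort by an upstream labeling and compare survival
#'
#' Builds survival groups from any patient -> label assignment (DDR burden
#' categories, gene or hotspot carrier status, amplification status, ...),
#' drops labeled patients without clinical data (tallied), drops empty
#' strata with a warning, and runs the log-rank test over what remains.
#'
#' @param clinical Clinical table ([read_clinical()]).
#' @param stratification Named character vector: names are patient ids,
#'   values stratum labels. Alternatively a `data.frame` with columns
#'   `patient_id` and `label`.
#' @return List with `groups` (named list of `times`/`events` per stratum),
#'   `test` (see [logrank()]), and `n_missing_clinical`.
#' @export
stratify_and_compare <- function(clinical, stratification) {
  if (is.data.frame(stratification)) {
    stratification <- stats::setNames(as.character(stratification$label),
                                      stratification$patient_id)
  }
  idx <- match(names(stratification), clinical$patient_id)
  missing_clin <- is.na(idx)
  if (any(missing_clin)) {
    stratification <- stratification[!missing_clin]
    idx <- idx[!missing_clin]
  }
  labels <- sort(unique(stratification))
  groups <- lapply(stats::setNames(labels, labels), function(l) {
    i <- idx[stratification == l]
    list(times = clinical$os_months[i], events = clinical$os_event[i])
  })
  empty <- vapply(groups, function(g) length(g$times) == 0L, logical(1))
  if (any(empty)) {
    warning("dropping empty stratum(a): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  if (length(groups) < 2L) {
    stop("domain error: fewer than 2 non-empty strata")
  }
  list(groups = groups, test = logrank(groups),
       n_missing_clinical = sum(missing_clin))
}

#' Per-group KM tables plus the test summary, written as TSVs
#'
#' @param comparison Output of [stratify_and_compare()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_survival_tables <- function(comparison, dir, prefix = "survival") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (l in names(comparison$groups)) {
    g <- comparison$groups[[l]]
    km <- km_curve(g$times, g$events)
    p <- file.path(dir, paste0(prefix, "_km_", gsub("[^A-Za-z0-9_.-]", "_", l),
                               ".tsv"))
    utils::write.table(km, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  test <- comparison$test
  summ <- data.frame(chisq = test$chisq, df = test$df, p = test$p,
                     n = test$n, n_events = test$n_events)
  p <- file.path(dir, paste0(prefix, "_logrank.tsv"))
  utils::write.table(summ, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p))
}
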