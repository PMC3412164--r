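#' Construct a survival cohort
#'
#' Per-patient follow-up time, event indicator (1 = death/recurrence,
#' 0 = censored) and signature score. The score is whatever per-sample
#' signature value the expression pipeline produced (set-average centered
#' log2 expression).
#'
#' @param time non-negative follow-up times (unit declared by the caller)
#' @param event 0/1 event indicators
#' @param score per-patient signature scores
#' @param patient_id optional ids (default `P1..Pn`)
#' @return data.frame classed `SurvivalCohort` with columns `patient_id`,
#'   `time`, `event`, `score`
#' @export
survival_cohort <- function(time, event, score,
                            patient_id = paste0("P", seq_along(time))) {
  time <- as.numeric(time)
  event <- as.integer(event)
  score <- as.numeric(score)
  if (length(unique(c(length(time), length(event), length(score),
                      length(patient_id)))) != 1L)
    stop("time, event, score and patient_id must have equal length")
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be finite and >= 0")
  if (!all(event %in% c(0L, 1L))) stop("event indicators must be 0 or 1")
  if (any(!is.finite(score))) stop("scores must be finite")
  structure(data.frame(patient_id = as.character(patient_id), time = time,
                       event = event, score = score, stringsAsFactors = FALSE),
            class = c("SurvivalCohort", "data.frame"))
}

#' Read a survival cohort TSV (patient_id, time, event, score)
#' @param path file path
#' @return a [survival_cohort()]
#' @export
read_survival_cohort <- function(path) {
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  need <- c("patient_id", "time", "event", "score")
  if (!all(need %in% names(d)))
    stop("cohort file needs columns: ", paste(need, collapse = ", "))
  survival_cohort(d$time, d$event, d$score, d$patient_id)
}

#' Write a survival cohort TSV
#' @param cohort a [survival_cohort()]
#' @param path output path
#' @export
write_survival_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort)[c("patient_id", "time", "event",
                                             "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dichotomize a cohort by signature score
#'
#' `mean_split`: high = score strictly above the cohort mean ("splitting at
#' the average score"); `zero_split`: high = score strictly above 0 (the
#' sign of relative average expression). A score exactly at the split point
#' goes to "low". Both published readings are implemented; neither is
#' privileged.
#'
#' @param cohort a [survival_cohort()] with >= 2 patients
#' @param mode `"mean_split"` or `"zero_split"`
#' @return the cohort with an added factor column `group` (levels
#'   `low`, `high`)
#' @export
dichotomize_by_score <- function(cohort, mode = c("mean_split", "zero_split")) {
  mode <- match.arg(mode)
  if (nrow(cohort) < 2L) stop("need >= 2 patients")
  cut <- if (mode == "mean_split") mean(cohort$score) else 0
  grp <- factor(ifelse(cohort$score > cut, "high", "low"),
                levels = c("low", "high"))
  if (any(table(grp) == 0L)) {
    other <- setdiff(c("mean_split", "zero_split"), mode)
    stop("'", mode, "' leaves the '", names(which(table(grp) == 0L))[1],
         "' group empty; consider mode = '", other, "'")
  }
  message(sprintf("dichotomize_by_score (%s): %d low, %d high",
                  mode, sum(grp == "low"), sum(grp == "high")))
  cohort$group <- grp
  cohort
}

#' Kaplan-Meier product-limit estimator
#'
#' Steps down at each distinct event time; censored observations leave the
#' risk set without a step. Patients censored exactly at an event time are
#' counted at risk at that time (censored-after-events convention).
#'
#' @param cohort a [survival_cohort()], optionally with a `group` column
#' @param group if given, estimate for that group only
#' @return object of class `KMEstimate`: data.frame with columns `time`,
#'   `n_risk`, `n_event`, `survival` (one row per distinct event time;
#'   survival starts at 1 and is non-increasing)
#' @export
kaplan_meier <- function(cohort, group = NULL) {
  d <- as.data.frame(cohort)
  if (!is.null(group)) {
    if (is.null(d$group)) stop("cohort has no 'group' column; dichotomize first")
    d <- d[d$group == group, , drop = FALSE]
    if (!nrow(d)) stop("no patient in group '", group, "'")
  }
  ev_times <- sort(unique(d$time[d$event == 1L]))
  n_risk <- n_event <- surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[[i]]
    n_risk[i] <- sum(d$time >= t)
    n_event[i] <- sum(d$time == t & d$event == 1L)
    s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  out <- data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
                    survival = surv)
  structure(out, class = c("KMEstimate", "data.frame"))
}

#' Two-group log-rank test
#'
#' Standard Mantel-Haenszel log-rank statistic: at each distinct event time
#' the observed events in group 1 are contrasted with their hypergeometric
#' expectation and variance given the risk sets; the squared standardized sum
#' is chi-square with 1 df under the null. Requires a `group` column with
#' exactly two non-empty levels and at least one event overall.
#'
#' @param cohort a dichotomized [survival_cohort()] (see
#'   [dichotomize_by_score()])
#' @return object of class `LogRankResult`: list with `chisq`, `p_value`,
#'   `n` (group sizes), `observed` and `expected` event counts per group
#' @export
logrank_test <- function(cohort) {
  d <- as.data.frame(cohort)
  if (is.null(d$group)) stop("cohort has no 'group' column; dichotomize first")
  g <- factor(d$group)
  lev <- levels(droplevels(g))
  if (length(lev) != 2L) stop("log-rank test requires exactly 2 groups")
  if (any(table(g)[lev] == 0L)) stop("both groups must be non-empty")
  if (sum(d$event) < 1L) stop("no events in the cohort")
  in1 <- g == lev[[1L]]
  ev_times <- sort(unique(d$time[d$event == 1L]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at_risk <- d$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in1)
    dt <- sum(d$time == t & d$event == 1L)
    d1 <- sum(d$time == t & d$event == 1L & in1)
    O1 <- O1 + d1
    E1 <- E1 + dt * n1 / n
    if (n > 1L)
      V <- V + dt * (n1 / n) * (1 - n1 / n) * (n - dt) / (n - 1)
  }
  chisq <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chisq, df = 1L, lower.tail = FALSE) else 1
  D <- sum(d$event)
  structure(list(chisq = chisq, p_value = p,
                 n = stats::setNames(as.integer(table(g)[lev]), lev),
                 observed = stats::setNames(c(O1, D - O1), lev),
                 expected = stats::setNames(c(E1, D - E1), lev)),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4f (1 df), p = %.4g; n = %s\n",
              x$chisq, x$p_value,
              paste(sprintf("%s: %d", names(x$n), x$n), collapse = ", ")))
  invisible(x)
}
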