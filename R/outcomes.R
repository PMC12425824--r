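#' Label ERG status from the fraction of ERG-positive tumor cells
#'
#' A sample is ERG-positive iff strictly more than half of its tumor cells
#' are ERG-positive.
#'
#' @param fraction Per-sample fraction in \code{[0, 1]}.
#' @return Character vector, "positive" or "negative".
#' @export
label_erg_status <- function(fraction) {
  if (any(is.na(fraction)) || any(fraction < 0) || any(fraction > 1))
    stop_input("'fraction' must lie in [0, 1]")
  ifelse(fraction > 0.5, "positive", "negative")
}

#' Score bulk samples against a gene signature
#'
#' Per sample, the mean over signature genes of the per-gene z-score of
#' log-scale expression across samples (zero-variance genes contribute 0).
#'
#' @param expr Genes x samples expression matrix.
#' @param signature A [signature_set()].
#' @param log_transform Apply log1p first (set FALSE when \code{expr} is
#'   already on a log scale).
#' @return Named score per sample.
#' @export
score_bulk_signature <- function(expr, signature, log_transform = TRUE) {
  if (log_transform) expr <- log1p(as.matrix(expr)) else expr <- as.matrix(expr)
  score_signature(expr, signature)
}

#' Stratify samples into signature-score quartiles
#'
#' Top = scores at or above the 75th percentile, bottom = scores at or below
#' the 25th percentile (linear-interpolation quantiles), remainder middle.
#' Ties sitting exactly on a cutoff are all included on that side and their
#' count is reported via a message. Constant scores cannot be stratified.
#'
#' @param scores Numeric scores, at least 8.
#' @return Factor per sample with levels bottom, middle, top.
#' @export
quartile_stratify <- function(scores) {
  if (length(scores) < 8L) stop_input("need at least 8 samples")
  if (anyNA(scores)) stop_input("scores must not contain NA")
  q <- quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2]) stop_input("no stratification possible: scores too tied")
  lab <- rep("middle", length(scores))
  lab[scores <= q[1]] <- "bottom"
  lab[scores >= q[2]] <- "top"
  n_tie <- sum(scores == q[1]) + sum(scores == q[2])
  if (n_tie > 0)
    message(n_tie, " score(s) tie a quartile cutoff; included on the ",
            "extreme side in stable sample order")
  factor(lab, levels = c("bottom", "middle", "top"))
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param times Positive survival times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Object of class \code{"survival_curve"}: data frame with time,
#'   n_risk, n_event, n_censor, survival, starting at time 0 with survival 1.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop_input("need at least one sample")
  if (any(times <= 0)) stop_input("survival times must be positive")
  if (!all(events %in% c(0, 1))) stop_input("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = c(0, fit$time),
                    n_risk = c(length(times), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    n_censor = c(0, fit$n.censor),
                    survival = c(1, fit$surv))
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' At each distinct event time, the observed minus hypergeometric-expected
#' events in group A are summed, squared and divided by the summed variance;
#' the p value is chi-square with 1 degree of freedom.
#'
#' @param times_a,events_a,times_b,events_b Survival data for the two
#'   groups; both non-empty, with at least one event in total.
#' @return List: \code{statistic} (chi-square), \code{p}.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop_input("both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0)
    stop_input("log-rank test undefined with zero events")
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = unname(sd_$chisq),
       p = pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Quartile survival comparison within ERG strata
#'
#' Stratifies samples into signature-score quartiles and compares
#' progression-free survival of the top versus bottom quartile with a
#' log-rank test, by default separately within ERG-positive and ERG-negative
#' samples (quartiles computed within each stratum).
#'
#' @param cohort Data frame with columns score, time, event, erg_status (see
#'   [generate_cohort()] / [read_cohort()]).
#' @param by_erg_status Analyze within ERG strata (default) or jointly.
#' @return Data frame, one row per stratum: stratum, n, n_top, n_bottom,
#'   statistic, p.
#' @export
survival_by_quartile <- function(cohort, by_erg_status = TRUE) {
  need <- c("score", "time", "event")
  if (!all(need %in% names(cohort)))
    stop_input("cohort needs columns ", paste(need, collapse = ", "))
  strata <- if (by_erg_status) split(cohort, cohort$erg_status)
            else list(all = cohort)
  rows <- lapply(names(strata), function(s) {
    d <- strata[[s]]
    lab <- suppressMessages(quartile_stratify(d$score))
    top <- d[lab == "top", ]; bot <- d[lab == "bottom", ]
    lr <- logrank_test(top$time, top$event, bot$time, bot$event)
    data.frame(stratum = s, n = nrow(d), n_top = nrow(top),
               n_bottom = nrow(bot), statistic = lr$statistic, p = lr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
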