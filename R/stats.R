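#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval by beta-quantile inversion of the binomial
#' tails: lower = qbeta(alpha/2, k, n - k + 1) (0 when k = 0), upper =
#' qbeta(1 - alpha/2, k + 1, n - k) (1 when k = n). Reproduces the
#' printed intervals of small-cohort sensitivity/specificity estimates,
#' e.g. 6/6 -> (0.541, 1) and 5/7 -> (0.290, 0.963) at 95%.
#'
#' @param k number of successes (0 <= k <= n)
#' @param n number of trials (>= 1)
#' @param conf confidence level in (0, 1)
#' @return named numeric c(lower, upper)
#' @export
clopperPearson <- function(k, n, conf = 0.95) {
  if (n < 1 || k < 0 || k > n) stop("domain error: need 0 <= k <= n, n >= 1")
  if (conf <= 0 || conf >= 1) stop("conf must be in (0, 1)")
  a <- 1 - conf
  lower <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Sensitivity and specificity with exact confidence intervals
#'
#' Cross-tabulates predicted against actual class labels and reports
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) with
#' Clopper-Pearson intervals. A class absent from `actual` yields an NA
#' metric flagged in `flags` rather than a silent 0.
#'
#' @param predicted,actual logical vectors (TRUE = positive) or vectors
#'   coercible to logical, equal length
#' @param conf confidence level
#' @return list with counts (tp, fp, tn, fn), sensitivity, specificity,
#'   ciSens, ciSpec and flags
#' @export
sensSpec <- function(predicted, actual, conf = 0.95) {
  predicted <- as.logical(predicted); actual <- as.logical(actual)
  if (length(predicted) != length(actual) || length(actual) < 1)
    stop("predicted and actual must have equal length >= 1")
  tp <- sum(predicted & actual); fn <- sum(!predicted & actual)
  tn <- sum(!predicted & !actual); fp <- sum(predicted & !actual)
  flags <- character(0)
  sens <- ciS <- NA
  if (tp + fn > 0) {
    sens <- tp / (tp + fn); ciS <- clopperPearson(tp, tp + fn, conf)
  } else flags <- c(flags, "no positives in actual: sensitivity undefined")
  spec <- ciP <- NA
  if (tn + fp > 0) {
    spec <- tn / (tn + fp); ciP <- clopperPearson(tn, tn + fp, conf)
  } else flags <- c(flags, "no negatives in actual: specificity undefined")
  list(tp = tp, fp = fp, tn = tn, fn = fn, sensitivity = sens,
       specificity = spec, ciSens = ciS, ciSpec = ciP, conf = conf,
       n = length(actual), flags = flags)
}

# exact null distribution of the signed-rank statistic for given
# (mid)ranks: masses over all 2^n sign assignments
signedRankNull <- function(ranks) {
  n <- length(ranks)
  # dynamic programming over achievable sums; midranks may be half-integers,
  # so work on doubled ranks to stay on an integer lattice
  r2 <- round(ranks * 2)
  total <- sum(r2)
  mass <- numeric(total + 1)  # index = doubled statistic + 1
  mass[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), mass[seq_len(total + 1 - r)])
    mass <- mass + shifted
  }
  list(support2 = 0:total, mass = mass / 2^n)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-tailed signed-rank test on the nonzero paired differences, using
#' midranks for tied absolute differences. For n <= `exactMax` nonzero
#' pairs the p-value comes from exact enumeration of the null
#' distribution over all 2^n sign assignments (valid under ties); larger
#' samples use the normal approximation with tie correction and
#' continuity correction. All-zero differences give a degenerate result
#' (p = 1, flagged).
#'
#' @param x,y paired samples, equal length >= 2
#' @param exactMax largest n for exact enumeration
#' @return list (statistic V, p_value, method, n, flags)
#' @export
wilcoxonSignedRank <- function(x, y, exactMax = 12) {
  if (length(x) != length(y) || length(x) < 2)
    stop("paired samples of equal length >= 2 required")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1,
                method = "wilcoxon signed-rank (degenerate)", n = 0L,
                flags = "all differences zero"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exactMax) {
    null <- signedRankNull(r)
    v2 <- round(V * 2)
    pLo <- sum(null$mass[null$support2 <= v2])
    pHi <- sum(null$mass[null$support2 >= v2])
    p <- min(1, 2 * min(pLo, pHi))
    method <- "wilcoxon signed-rank (exact enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "wilcoxon signed-rank (normal approximation)"
  }
  list(statistic = V, p_value = p, method = method, n = as.integer(n),
       flags = character(0))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate (via `survival::survfit`); censored subjects
#' leave the risk set without a drop, and at tied times deaths precede
#' censorings.
#'
#' @param times survival/censoring times (> 0)
#' @param events event flags (1 = death, 0 = censored)
#' @return list with time, surv (probability after each time), nRisk,
#'   nEvent, nCensor, and the underlying survfit object as `fit`
#' @export
kmCurve <- function(times, events) {
  if (length(times) == 0) stop("empty-sample: no subjects")
  if (any(times <= 0)) stop("times must be > 0")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  list(time = fit$time, surv = fit$surv, nRisk = fit$n.risk,
       nEvent = fit$n.event, nCensor = fit$n.censor, fit = fit)
}

#' Two-group log-rank test
#'
#' Standard observed-vs-expected chi-square statistic with 1 degree of
#' freedom (via `survival::survdiff`); the two-sided p-value is the
#' upper chi-square tail, floored at the smallest representable
#' positive double. If neither group has an event the test is undefined
#' and flagged (p = NA).
#'
#' @param timesA,eventsA first group's times and event flags
#' @param timesB,eventsB second group's times and event flags
#' @return list (statistic, p_value, method, n, flags)
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (length(timesA) == 0 || length(timesB) == 0)
    stop("both groups must be non-empty")
  if (sum(eventsA) + sum(eventsB) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                method = "log-rank", n = length(timesA) + length(timesB),
                flags = "undefined-test: no events in either group"))
  tt <- c(timesA, timesB)
  ee <- c(eventsA, eventsB)
  gg <- rep(c("A", "B"), c(length(timesA), length(timesB)))
  sd <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  p <- max(stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
           .Machine$double.xmin)
  list(statistic = unname(sd$chisq), p_value = p, method = "log-rank",
       n = length(tt), flags = character(0))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors, equal length >= 3, non-constant
#' @return correlation coefficient in \[-1, 1\]
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("equal-length samples of size >= 3 required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation: constant input")
  stats::cor(x, y, method = "pearson")
}

#' Group x timepoint x region summary of a cohort
#'
#' Mean +/- standard error (sd/sqrt(n)) of tumour and normal-brain
#' Lac/Bic at baseline and 48 hours, and of tumour volumes, per group --
#' the layout of the study-style summary tables. Groups of size 1 get
#' an NA standard error and a flag.
#'
#' @param cohort cohort data.frame from [makeCohort()]
#' @return data.frame with columns group, region, timepoint, variable,
#'   mean, se, n, flag
#' @export
summarizeCohort <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort")
  cols <- list(
    c("lacbic", "tumor",  "baseline", "pre_lacbic_tumor"),
    c("lacbic", "tumor",  "48h",      "post_lacbic_tumor"),
    c("lacbic", "normal", "baseline", "pre_lacbic_normal"),
    c("lacbic", "normal", "48h",      "post_lacbic_normal"),
    c("volume", "tumor",  "baseline", "vol_pre_mm3"),
    c("volume", "tumor",  "48h",      "vol_post_mm3"))
  rows <- list()
  for (g in unique(cohort$group)) {
    sub <- cohort[cohort$group == g, ]
    for (cc in cols) {
      v <- sub[[cc[4]]]
      n <- length(v)
      se <- if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        group = g, region = cc[2], timepoint = cc[3], variable = cc[1],
        mean = mean(v), se = se, n = n,
        flag = if (n == 1) "SE undefined for group of size 1" else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
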