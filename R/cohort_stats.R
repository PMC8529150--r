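# Cohort-level analyses of ELVAR: synthetic two-group cohorts, ROC with
# Youden-optimal cutoff, and Kaplan-Meier stratification at a cutoff.

#' Construct a synthetic cohort specification
#'
#' Defaults emulate a two-group structure of early-death vs early-survival
#' patients: group A draws ELVAR from a logit-normal matched to median
#' 0.7973 (IQR 0.7458-0.8338) with a high early hazard, group B from
#' median 0.8685 (IQR 0.8155-0.8956) with a low constant hazard; group
#' sizes default to 16 and 39 with 12 months of follow-up.
#'
#' @param nPerGroup integer, one value for both groups or c(nA, nB).
#' @param elvarA,elvarB list(median, iqr = c(q25, q75)) on (0, 1).
#' @param hazardA,hazardB list(breaks, rates): piecewise-constant hazard
#'   (events/month); \code{rates} has one more element than \code{breaks}.
#' @param followUpMonths administrative censoring horizon.
#' @param seed integer RNG seed.
#' @return a \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nPerGroup = c(16L, 39L),
                       elvarA = list(median = 0.7973, iqr = c(0.7458, 0.8338)),
                       elvarB = list(median = 0.8685, iqr = c(0.8155, 0.8956)),
                       hazardA = list(breaks = 3, rates = c(1.2, 0)),
                       hazardB = list(breaks = numeric(0), rates = 0.003),
                       followUpMonths = 12, seed = 1L) {
  if (length(nPerGroup) == 1L) nPerGroup <- rep(nPerGroup, 2L)
  new("CohortSpec", nPerGroup = as.integer(nPerGroup), elvarA = elvarA,
      elvarB = elvarB, hazardA = hazardA, hazardB = hazardB,
      followUpMonths = followUpMonths, seed = as.integer(seed))
}

# Draw n event times from a piecewise-constant hazard by inversion of the
# cumulative hazard; zero-rate tails yield Inf (censored later).
.rpch <- function(n, breaks, rates) {
  breaks <- as.numeric(breaks); rates <- as.numeric(rates)
  stopifnot(length(rates) == length(breaks) + 1L, all(rates >= 0))
  edges <- c(0, breaks)
  widths <- diff(c(edges, Inf))
  cumH <- c(0, cumsum(utils::head(rates, -1) * utils::head(widths, -1)))
  e <- stats::rexp(n)
  t <- rep(Inf, n)
  for (j in rev(seq_along(rates))) {
    sel <- e >= cumH[j]
    t[sel] <- if (rates[j] > 0) edges[j] + (e[sel] - cumH[j]) / rates[j]
              else Inf
    e[sel] <- -1  # assigned
  }
  t
}

# Logit-normal parameters matched to a stated median and IQR.
.logitNormalPars <- function(el) {
  mu <- stats::qlogis(el$median)
  sigma <- (stats::qlogis(el$iqr[2]) - stats::qlogis(el$iqr[1])) /
    (2 * stats::qnorm(0.75))
  c(mu = mu, sigma = max(sigma, 1e-8))
}

#' Generate a synthetic two-group cohort table
#'
#' ELVAR values are logit-normal draws matched to each group's stated
#' median and IQR (the logit-normal median reproduces the stated median
#' exactly in expectation); event times follow the group's
#' piecewise-constant hazard, censored administratively at follow-up.
#'
#' @param cs a \linkS4class{CohortSpec}.
#' @return data.frame with columns id, group, elvar, event_time_months,
#'   event_flag.
#' @export
generateCohort <- function(cs = cohortSpec()) {
  stopifnot(is(cs, "CohortSpec"))
  .withSeed(cs@seed, {
    out <- list()
    groups <- list(A = list(n = cs@nPerGroup[1], el = cs@elvarA, hz = cs@hazardA),
                   B = list(n = cs@nPerGroup[2], el = cs@elvarB, hz = cs@hazardB))
    for (g in names(groups)) {
      gi <- groups[[g]]
      p <- .logitNormalPars(gi$el)
      elvar <- stats::plogis(stats::rnorm(gi$n, p["mu"], p["sigma"]))
      t <- .rpch(gi$n, gi$hz$breaks, gi$hz$rates)
      out[[g]] <- data.frame(
        group = g, elvar = elvar,
        event_time_months = pmin(t, cs@followUpMonths),
        event_flag = t <= cs@followUpMonths,
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, out)
    tab <- data.frame(id = sprintf("S%03d", seq_len(nrow(tab))), tab,
                      row.names = NULL, stringsAsFactors = FALSE)
    tab
  })
}

#' Empirical ROC analysis with Youden-optimal cutoff
#'
#' Candidate cutoffs are the midpoints between consecutive distinct scores,
#' with one sentinel below and above the observed range. The AUC is the
#' trapezoidal area under the empirical curve (ties contribute half). The
#' best cutoff maximizes Youden's J = sensitivity + specificity - 1;
#' ties are broken toward higher specificity, then toward the lower cutoff.
#'
#' @param scores numeric scores (e.g. ELVAR values).
#' @param labels logical (TRUE = positive class, e.g. death) or a 2-level
#'   factor whose second level is positive.
#' @param direction \code{"low-positive"} if low scores indicate the
#'   positive class (the ELVAR convention), else \code{"high-positive"}.
#' @return a \linkS4class{RocResult}.
#' @export
rocAnalysis <- function(scores, labels,
                        direction = c("low-positive", "high-positive")) {
  direction <- match.arg(direction)
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (!any(labels) || all(labels))
    stop("both classes must be present for ROC analysis")
  lowPos <- direction == "low-positive"
  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else numeric(0)
  gap <- if (length(u) > 1) min(diff(u)) / 2 else max(abs(u[1]), 1) / 2
  cuts <- c(u[1] - gap, mids, u[length(u)] + gap)
  nPos <- sum(labels); nNeg <- sum(!labels)
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    predPos <- if (lowPos) scores < cuts[i] else scores > cuts[i]
    sens[i] <- sum(predPos & labels) / nPos
    spec[i] <- sum(!predPos & !labels) / nNeg
  }
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  J <- sens + spec - 1
  eps <- 1e-12
  best <- which(J >= max(J) - eps)
  if (length(best) > 1) best <- best[spec[best] >= max(spec[best]) - eps]
  if (length(best) > 1) best <- best[which.min(cuts[best])]
  new("RocResult", thresholds = cuts, sensitivity = sens, specificity = spec,
      auc = auc, bestCutoff = cuts[best], youdenJ = J[best],
      direction = direction)
}

#' Kaplan-Meier stratification at an ELVAR cutoff
#'
#' Splits the cohort into a below-cutoff and an at/above-cutoff stratum and
#' fits the product-limit estimator per stratum (standard right-censoring
#' handling), reporting the step-function curves and survival and mortality
#' at the requested horizons. Mortality within a horizon uses the closed
#' boundary (event time <= horizon).
#'
#' @param table cohort data.frame with columns elvar, event_time_months,
#'   event_flag.
#' @param cutoff ELVAR cutoff in (0, 1).
#' @param horizons months at which survival is reported (default c(3, 12)).
#' @param confInt add log-log confidence bands (default FALSE; the default
#'   display shows none).
#' @return list with elements \code{fit} (survfit object), \code{curves}
#'   (data.frame: stratum, time, n_risk, n_event, survival),
#'   \code{survivalAtHorizons} (strata x horizons matrix) and
#'   \code{cutoff}.
#' @export
kmStratify <- function(table, cutoff, horizons = c(3, 12), confInt = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("elvar", "event_time_months", "event_flag") %in%
                  names(table)))
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  stratum <- ifelse(table$elvar < cutoff, "below", "above")
  for (s in c("below", "above"))
    if (!any(stratum == s))
      stop("empty stratum: no subjects ", s, " the cutoff ", cutoff)
  df <- data.frame(time = table$event_time_months,
                   event = as.integer(table$event_flag),
                   stratum = factor(stratum, levels = c("below", "above")))
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = df,
                           conf.type = if (confInt) "log-log" else "none")
  sm <- summary(fit)
  strataNames <- sub("^stratum=", "", as.character(sm$strata))
  curves <- data.frame(stratum = strataNames, time = sm$time,
                       n_risk = sm$n.risk, n_event = sm$n.event,
                       survival = sm$surv, stringsAsFactors = FALSE)
  sh <- summary(fit, times = horizons, extend = TRUE)
  shStrata <- sub("^stratum=", "", as.character(sh$strata))
  surv <- matrix(NA_real_, 2, length(horizons),
                 dimnames = list(c("below", "above"), paste0("m", horizons)))
  for (s in c("below", "above"))
    surv[s, ] <- sh$surv[shStrata == s]
  list(fit = fit, curves = curves, survivalAtHorizons = surv,
       mortalityAtHorizons = 1 - surv, cutoff = cutoff)
}

#' Plot an ROC curve
#'
#' @param roc a \linkS4class{RocResult}.
#' @param file optional PNG path; plots to the active device when NULL.
#' @export
plotRoc <- function(roc, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  fpr <- 1 - roc@specificity
  o <- order(fpr, roc@sensitivity)
  graphics::plot(fpr[o], roc@sensitivity[o], type = "l", lwd = 2,
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f, cutoff = %.4g)",
                                roc@auc, roc@bestCutoff))
  graphics::abline(0, 1, lty = 3)
  invisible(NULL)
}

#' Plot Kaplan-Meier curves from a stratification
#'
#' @param strat result of \code{kmStratify}.
#' @param file optional PNG path.
#' @export
plotKM <- function(strat, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(strat$fit, col = c(2, 4), lwd = 2, xlab = "months",
                 ylab = "survival",
                 main = sprintf("Kaplan-Meier by ELVAR cutoff %.3f",
                                strat$cutoff))
  graphics::legend("bottomleft", legend = c("below cutoff", "at/above cutoff"),
                   col = c(2, 4), lwd = 2, bty = "n")
  invisible(NULL)
}
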