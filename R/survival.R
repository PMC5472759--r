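#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator per stratum: censored times reduce the risk set
#' without producing a step. Survival starts at 1 and is non-increasing
#' within each stratum.
#'
#' @param records A clinical data frame with columns `time` (positive) and
#'   `event` (1 = death observed, 0 = censored).
#' @param group Optional name of a stratum column in `records`.
#' @return A `km_estimate` tibble: `stratum`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, with the underlying `survfit` object as an
#'   attribute.
#' @export
km_estimate <- function(records, group = NULL) {
  records <- validate_survival_records(records)
  if (is.null(group)) {
    records$.stratum <- "all"
    group <- ".stratum"
  }
  stopifnot(group %in% names(records))
  fit <- survival::survfit(
    survival::Surv(time, event) ~ stratum,
    data = data.frame(time = records$time, event = records$event,
                      stratum = as.character(records[[group]])))
  s <- summary(fit, censored = TRUE)
  stratum <- if (is.null(s$strata)) {
    rep(unique(as.character(records[[group]])), length(s$time))
  } else {
    sub("^stratum=", "", as.character(s$strata))
  }
  out <- tibble::tibble(stratum = stratum, time = s$time, n_risk = s$n.risk,
                        n_event = s$n.event, n_censor = s$n.censor,
                        survival = s$surv)
  class(out) <- c("km_estimate", class(out))
  attr(out, "survfit") <- fit
  out
}

#' Log-rank comparison of survival between groups
#'
#' Unweighted log-rank test over the pooled event times;
#' df = number of groups - 1.
#'
#' @param records A clinical data frame with `time`, `event` and the
#'   grouping column.
#' @param group Name of the grouping column (>= 2 groups).
#' @return A tibble: `statistic`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(records, group) {
  records <- validate_survival_records(records)
  stopifnot(group %in% names(records))
  g <- as.character(records[[group]])
  if (length(unique(g)) < 2) stop("need >= 2 groups", call. = FALSE)
  if (sum(records$event) == 0) {
    stop("no events observed in any group", call. = FALSE)
  }
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ g,
    data = data.frame(time = records$time, event = records$event, g = g))
  df <- length(sd$n) - 1
  tibble::tibble(statistic = sd$chisq, df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 n_groups = length(sd$n))
}

#' Cox proportional-hazards fit with V as the genotype reference
#'
#' Maximizes the partial likelihood with the Efron approximation for tied
#' event times. Genotype enters as indicator covariates against the
#' reference level (default `"V"`); stage and grade, when requested, enter
#' as ordinal integers.
#'
#' @param records A clinical data frame with `time`, `event` and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names; character
#'   or factor columns become indicators, numeric columns enter as given.
#' @param reference Reference level for the `genotype` column if present
#'   (default `"V"`).
#' @return An `rcc_cox` object wrapping the `coxph` fit; see
#'   [tidy.rcc_cox()] and [glance.rcc_cox()].
#' @export
cox_fit <- function(records, covariates, reference = "V") {
  records <- validate_survival_records(records)
  miss <- setdiff(covariates, names(records))
  if (length(miss)) {
    stop("covariate column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dat <- data.frame(time = records$time, event = records$event)
  for (cv in covariates) {
    x <- records[[cv]]
    if (is.character(x) || is.factor(x)) {
      x <- as.character(x)
      levels <- unique(x)
      if (reference %in% levels) levels <- c(reference, setdiff(levels, reference))
      x <- factor(x, levels = levels)
    }
    if (length(unique(stats::na.omit(records[[cv]]))) < 2) {
      stop("constant covariate: ", cv, call. = FALSE)
    }
    dat[[cv]] <- x
  }
  if (length(unique(records$time[records$event == 1])) < 2) {
    stop("need >= 2 distinct event times", call. = FALSE)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  converged <- is.finite(fit$loglik[2]) && all(is.finite(stats::coef(fit))) &&
    fit$iter < 50 && all(sqrt(diag(fit$var)) < 1e3)
  structure(list(fit = fit, covariates = covariates, reference = reference,
                 converged = converged, iterations = fit$iter,
                 n = fit$n, n_events = fit$nevent),
            class = "rcc_cox")
}

#' @export
print.rcc_cox <- function(x, ...) {
  cat(sprintf("<rcc_cox> n = %d, events = %d, converged = %s (%d iterations)\n",
              x$n, x$n_events, x$converged, x$iterations))
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x An `rcc_cox` object.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate` (log hazard ratio), `hazard_ratio`,
#'   `std_error`, `statistic` (Wald z), `p_value`.
#' @export
#' @method tidy rcc_cox
tidy.rcc_cox <- function(x, ...) {
  co <- stats::coef(x$fit)
  se <- sqrt(diag(x$fit$var))
  z <- co / se
  tibble::tibble(term = names(co), estimate = unname(co),
                 hazard_ratio = unname(exp(co)), std_error = unname(se),
                 statistic = unname(z),
                 p_value = unname(2 * stats::pnorm(abs(z), lower.tail = FALSE)))
}

#' One-row summary of a Cox fit
#'
#' @param x An `rcc_cox` object.
#' @param ... Unused.
#' @return A tibble: `n`, `n_events`, `loglik`, `converged`, `iterations`.
#' @export
#' @method glance rcc_cox
glance.rcc_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 loglik = x$fit$loglik[2], converged = x$converged,
                 iterations = x$iterations)
}

validate_survival_records <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("time", "event")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(records)) stop("no records", call. = FALSE)
  if (anyNA(records$time) || any(records$time <= 0)) {
    stop("survival times must be positive and non-missing", call. = FALSE)
  }
  if (!all(records$event %in% c(0, 1))) {
    stop("`event` must be 0 or 1", call. = FALSE)
  }
  records
}
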