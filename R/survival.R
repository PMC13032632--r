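# Weibull proportional-hazards survival for the disease-risk window, and
# maximum-likelihood fitting to right-censored patient records.

lin_pred <- function(stage, sp) {
  sp$beta0$mean + sp$beta_advanced$mean * (stage == "advanced")
}

#' Weibull proportional-hazards survival function
#'
#' All-cause survival during the disease-risk window, parameterised through
#' the cumulative hazard \eqn{H(t) = \exp(\beta_0 + \beta_{adv} I[advanced])
#' \, t^{\gamma}} with \eqn{t} in months, so that
#' \eqn{S(t) = \exp(-H(t))}.
#'
#' @param t time since diagnosis, months (vectorised); must be `>= 0`.
#' @param stage `"limited"` or `"advanced"`.
#' @param sp survival parameters (`cfg$survival`): `beta0`, `beta_advanced`,
#'   `gamma`, each a `(mean, se)` pair.
#' @return Survival probabilities in `[0, 1]`.
#' @export
#' @examples
#' sp <- bl_default_config()$survival
#' survival_at(24, "limited", sp)   # ~0.72
#' survival_at(24, "advanced", sp)  # ~0.43
survival_at <- function(t, stage, sp) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  stage <- match.arg(stage, c("limited", "advanced"))
  exp(-exp(lin_pred(stage, sp)) * t^sp$gamma$mean)
}

#' Per-cycle disease death probabilities
#'
#' Converts the Weibull survival function into conditional per-cycle death
#' probabilities \eqn{q_k = 1 - S(t_{k+1}) / S(t_k)} over cycle boundaries
#' \eqn{t_k = k \cdot cycle\_len} up to `horizon`. If the horizon is not an
#' exact multiple of the cycle length (e.g. 1-week cycles over a 24-month
#' window), the final cycle is truncated at the horizon so the telescoping
#' identity \eqn{\prod_k (1 - q_k) = S(horizon)} holds exactly.
#'
#' @param cycle_len cycle length, months.
#' @param horizon disease-risk horizon, months.
#' @inheritParams survival_at
#' @return Numeric vector of per-cycle death probabilities.
#' @export
cycle_death_probs <- function(cycle_len, horizon, stage, sp) {
  stopifnot(cycle_len > 0, horizon > 0)
  b <- seq(0, horizon, by = cycle_len)
  if (horizon - b[length(b)] > 1e-9 * horizon) b <- c(b, horizon)
  s <- survival_at(b, stage, sp)
  if (any(s[-length(s)] == 0))
    stop("degenerate survival: S(t) reached 0 before the horizon", call. = FALSE)
  1 - s[-1] / s[-length(s)]
}

#' Fit the Weibull proportional-hazards model to right-censored records
#'
#' Maximum-likelihood estimation of `(beta0, beta_advanced, gamma)` under
#' right censoring, with standard errors from the observed information
#' (inverted Hessian at the optimum; delta method for the shape, which is
#' optimised on the log scale).
#'
#' @param records data.frame with columns `stage` (`"limited"`/`"advanced"`),
#'   `time` (months, `> 0`) and `event` (`TRUE` for an observed death,
#'   `FALSE` for censoring), e.g. from [simulate_patients()].
#' @return An object of class `weibull_ph` with `coef`, `vcov`, `logLik`,
#'   `print`, `summary` and `predict` methods; `$params` holds the estimates
#'   in the `(mean, se)` layout accepted as `cfg$survival`.
#' @export
fit_weibull_ph <- function(records) {
  stopifnot(all(c("stage", "time", "event") %in% names(records)))
  if (any(records$time <= 0)) stop("all times must be > 0", call. = FALSE)
  adv <- as.numeric(records$stage == "advanced")
  ev <- as.logical(records$event)
  if (sum(ev & adv == 0) < 2 || sum(ev & adv == 1) < 2)
    stop("need at least 2 observed events per stage", call. = FALSE)
  tt <- records$time
  lt <- log(tt)

  nll <- function(th) {
    lp <- th[1] + th[2] * adv
    g <- exp(th[3])
    h <- exp(lp) * tt^g
    -(sum((lp + th[3] + (g - 1) * lt)[ev]) - sum(h))
  }
  # exponential-rate start
  start <- c(log(sum(ev) / sum(tt)), 0, 0)
  fit <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) {
    gr <- tryCatch(sqrt(sum(numDeriv_grad(nll, fit$par)^2)), error = function(e) NA)
    stop("Weibull MLE did not converge (code ", fit$convergence,
         ", |grad| = ", format(gr), ")", call. = FALSE)
  }
  vc <- tryCatch(solve(fit$hessian), error = function(e)
    stop("observed information is singular", call. = FALSE))
  se <- sqrt(pmax(diag(vc), 0))
  g_hat <- exp(fit$par[3])
  out <- list(
    coef = c(beta0 = fit$par[1], beta_advanced = fit$par[2], gamma = g_hat),
    se = c(beta0 = se[1], beta_advanced = se[2], gamma = g_hat * se[3]),
    vcov = vc,                 # on (beta0, beta_advanced, log gamma) scale
    logLik = -fit$value,
    n = length(tt), n_events = sum(ev),
    params = list(
      beta0 = par_ms(fit$par[1], se[1]),
      beta_advanced = par_ms(fit$par[2], se[2]),
      gamma = par_ms(g_hat, g_hat * se[3]),
      time_unit = "months"
    )
  )
  class(out) <- "weibull_ph"
  out
}

# small central-difference gradient, used only for convergence diagnostics
numDeriv_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, eps)
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

#' @export
print.weibull_ph <- function(x, ...) {
  cat("Weibull proportional-hazards fit (right-censored MLE)\n")
  cat(sprintf("  n = %d, events = %d, logLik = %.3f\n", x$n, x$n_events, x$logLik))
  tab <- data.frame(estimate = x$coef, se = x$se)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.weibull_ph <- function(object, ...) object$coef

#' @export
vcov.weibull_ph <- function(object, ...) object$vcov

#' @export
logLik.weibull_ph <- function(object, ...) {
  structure(object$logLik, df = 3, nobs = object$n, class = "logLik")
}

#' @export
summary.weibull_ph <- function(object, ...) {
  z <- object$coef / object$se
  tab <- data.frame(estimate = object$coef, se = object$se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  structure(list(table = tab, n = object$n, n_events = object$n_events,
                 logLik = object$logLik),
            class = "summary.weibull_ph")
}

#' @export
print.summary.weibull_ph <- function(x, ...) {
  cat("Weibull PH model, right-censored maximum likelihood\n")
  cat(sprintf("n = %d (%d events), logLik = %.3f\n\n", x$n, x$n_events, x$logLik))
  print(round(x$table, 4))
  invisible(x)
}

#' @export
predict.weibull_ph <- function(object, times, stage = "limited", ...) {
  survival_at(times, stage, object$params)
}
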