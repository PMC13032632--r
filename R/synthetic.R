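# Generators for inputs the analysis needs but that are not tabulated
# anywhere: patient-level right-censored survival records with the Weibull
# proportional-hazards structure (for parameter-recovery testing), the
# calibrated background life-table fixture, and an adverse-event table
# stub. Everything here is explicitly synthetic.

#' Simulate right-censored patient survival records
#'
#' Draws stage by Bernoulli(`p_limited`), event times by inverse-transform
#' sampling from the Weibull proportional-hazards survival function for the
#' drawn stage, and applies uniform early-dropout censoring plus
#' administrative censoring at `censor_admin_months` (matching a 24-month
#' analysis window). Reproducible under `seed`.
#'
#' @param n number of patients.
#' @param p_limited probability of limited stage (study analogue: 34/86).
#' @param sp survival parameters (`cfg$survival` layout).
#' @param censor_admin_months administrative censoring time, months.
#' @param dropout_window_months uniform early-dropout window `(0, w]`,
#'   months; `Inf` disables dropout.
#' @param p_rituximab probability a patient received rituximab (recorded
#'   but not used by the base model; hook for stratified re-estimation).
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return data.frame with columns `stage`, `time` (months), `event`
#'   (death observed), `rituximab`, `treatment_cycles`.
#' @export
#' @examples
#' rec <- simulate_patients(86, 34 / 86, bl_default_config()$survival, seed = 1)
#' table(rec$stage, rec$event)
simulate_patients <- function(n, p_limited, sp,
                              censor_admin_months = 24,
                              dropout_window_months = 72,
                              p_rituximab = 0.5, seed = NULL) {
  stopifnot(n >= 1, p_limited >= 0, p_limited <= 1,
            censor_admin_months > 0, dropout_window_months > 0)
  if (!is.null(seed)) set.seed(seed)
  stage <- ifelse(runif(n) < p_limited, "limited", "advanced")
  # inverse transform: S(T) = U  =>  T = (-log(U) / exp(lp))^(1/gamma)
  u <- runif(n)
  lp <- sp$beta0$mean + sp$beta_advanced$mean * (stage == "advanced")
  t_event <- (-log(u) / exp(lp))^(1 / sp$gamma$mean)
  cens <- pmin(if (is.finite(dropout_window_months))
                 runif(n, 0, dropout_window_months) else Inf,
               censor_admin_months)
  time <- pmin(t_event, cens)
  event <- t_event <= cens
  # guard against zero times from numerically tiny draws
  time <- pmax(time, 1e-9)
  data.frame(stage = stage, time = time, event = event,
             rituximab = runif(n) < p_rituximab,
             treatment_cycles = pmax(1L, stats::rpois(n, 5)))
}

#' Read / write patient-record CSVs
#'
#' Columns: `stage`, `time` (months), `event`, `rituximab`,
#' `treatment_cycles`.
#' @param records data.frame of patient records.
#' @param path CSV file path.
#' @return `read_patient_records`: the records data.frame.
#' @export
write_patient_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patient_records
#' @export
read_patient_records <- function(path) {
  rec <- utils::read.csv(path)
  need <- c("stage", "time", "event")
  if (!all(need %in% names(rec)))
    stop("patient records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  rec$event <- as.logical(rec$event)
  rec
}

#' Generate the calibrated synthetic life table
#'
#' Builds an abridged (5-year band) all-cause mortality schedule with
#' near-constant child and young-adult mortality and a Gompertz-shaped
#' adult tail, then scales the whole schedule by a single factor (found by
#' one-dimensional root finding) so that remaining life expectancy at age
#' 10 equals `target_e10`. Background disability weights rise
#' monotonically with age, emulating population all-cause morbidity. The
#' table is a synthetic stand-in for national mortality/morbidity data,
#' calibrated only to the life-expectancy anchor.
#'
#' @param target_e10 target remaining life expectancy at age 10, years.
#' @param max_age life-table horizon cap, years.
#' @return Life table data.frame (`age_start`, `q_annual`,
#'   `disability_weight`).
#' @export
#' @examples
#' lt <- make_life_table_fixture(65, 100)
#' remaining_life_expectancy(10, lt)
make_life_table_fixture <- function(target_e10 = 65, max_age = 100) {
  if (target_e10 >= max_age - 10)
    stop("calibration error: target_e10 must be < max_age - 10", call. = FALSE)
  age_start <- seq(0, 95, by = 5)
  # unscaled shape: elevated under-5 mortality, low child/young-adult
  # rates, Gompertz tail from age 30
  q_base <- c(0.0095, 0.0012, 0.0010, 0.0015, 0.0020, 0.0025,
              0.0030 * exp(0.08 * (seq(30, 95, by = 5) - 30)))
  dw <- c(0.045, 0.050, 0.055, 0.075, 0.090, 0.095, 0.100, 0.105,
          0.110, 0.120, 0.130, 0.145, 0.160, 0.180, 0.200, 0.220,
          0.245, 0.270, 0.295, 0.320)
  build <- function(s) data.frame(age_start = age_start,
                                  q_annual = pmin(s * q_base, 1),
                                  disability_weight = dw)
  f <- function(s) remaining_life_expectancy(10, build(s), max_age) - target_e10
  if (f(1e-6) < 0)
    stop("calibration error: target_e10 unachievable under max_age",
         call. = FALSE)
  s_hat <- uniroot(f, c(1e-6, 50), tol = 1e-10)$root
  lt <- build(s_hat)
  attr(lt, "scale_factor") <- s_hat
  lt
}

#' Adverse-event table stub
#'
#' The base case carries no adverse-event table (both arms incur
#' adverse-event costs through the same mechanism, so the incremental
#' effect is second order). `level = "nominal"` returns a small
#' illustrative table -- invented values, not estimates from any study --
#' for exercising the adverse-event code path and sensitivity analyses.
#'
#' @param level `"zero"` (empty table, the default) or `"nominal"`.
#' @return data.frame with columns `event`, `p_limited`, `p_advanced`,
#'   `unit_cost` (TZS per incident).
#' @export
make_ae_stub <- function(level = c("zero", "nominal")) {
  level <- match.arg(level)
  if (level == "zero")
    return(data.frame(event = character(0), p_limited = numeric(0),
                      p_advanced = numeric(0), unit_cost = numeric(0)))
  data.frame(
    event = c("febrile_neutropenia", "tumour_lysis_syndrome"),
    p_limited = c(0.20, 0.05),
    p_advanced = c(0.30, 0.10),
    unit_cost = c(150000, 250000)
  )
}
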