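# Background mortality and morbidity: abridged life table with age-band
# annual death probabilities and background disability weights.

lt_band_index <- function(lt, age) {
  i <- findInterval(age, lt$age_start)
  pmin(pmax(i, 1L), nrow(lt))
}

lt_q_annual <- function(lt, age) lt$q_annual[lt_band_index(lt, age)]
lt_bg_weight <- function(lt, age) lt$disability_weight[lt_band_index(lt, age)]

#' Per-cycle background death probability
#'
#' Converts the annual all-cause death probability for the age band
#' containing `age` into a per-cycle probability,
#' \eqn{q_c = 1 - (1 - q_{annual})^{cycle\_len / 12}}. Ages beyond the last
#' band are clamped to it.
#'
#' @param age age in years (vectorised).
#' @param cycle_len cycle length in months.
#' @param lt life table: data.frame with columns `age_start`, `q_annual`,
#'   `disability_weight`.
#' @return Per-cycle death probabilities.
#' @export
background_cycle_prob <- function(age, cycle_len, lt) {
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  1 - (1 - lt_q_annual(lt, age))^(cycle_len / 12)
}

#' Remaining life expectancy from the life table
#'
#' Standard life-table \eqn{e(a)}: yearly survivorship from the age-band
#' annual death probabilities, person-years by trapezoidal integration
#' (deaths mid-year), horizon capped at `max_age`. Fractional ages are
#' linearly interpolated between integer-age values.
#'
#' @param age age in years (vectorised); clamped to `[0, max_age]`.
#' @param lt life table (see [background_cycle_prob()]).
#' @param max_age horizon cap in years (default 100).
#' @return Remaining life expectancy in years.
#' @export
#' @examples
#' lt <- bl_packaged_life_table()
#' remaining_life_expectancy(10, lt)  # ~65 by calibration
remaining_life_expectancy <- function(age, lt, max_age = 100) {
  ages_int <- 0:max_age
  qv <- lt_q_annual(lt, ages_int[-length(ages_int)])      # q for age a -> a+1
  e_int <- numeric(max_age + 1)                           # e at integer ages
  # backward recursion: PY(a) = (l_a + l_{a+1})/2 + l_{a+1}/l_a * ... done
  # directly: e(a) = (1 + (1-q_a)) / 2 + (1-q_a) * e(a+1)
  e_int[max_age + 1] <- 0
  for (a in (max_age - 1):0) {
    p <- 1 - qv[a + 1]
    e_int[a + 1] <- (1 + p) / 2 + p * e_int[a + 2]
  }
  age <- pmin(pmax(age, 0), max_age)
  lo <- pmin(floor(age), max_age - 1)
  frac <- age - lo
  (1 - frac) * e_int[lo + 1] + frac * e_int[lo + 2]
}

#' Packaged synthetic life table
#'
#' The life table shipped with the package: a synthetic abridged (5-year
#' band) schedule with near-constant child/young-adult mortality and a
#' Gompertz adult tail, scaled so that remaining life expectancy at age 10
#' is 65 years, plus background disability weights that rise monotonically
#' with age. It is a documented stand-in for national all-cause mortality
#' and age-specific background morbidity data; replace it with a real table
#' via `bl_default_config(life_table = ...)` or the config file.
#'
#' @return data.frame with columns `age_start`, `q_annual`,
#'   `disability_weight`.
#' @seealso [make_life_table_fixture()] which generates (and calibrates)
#'   this fixture from code.
#' @export
bl_packaged_life_table <- function() {
  path <- system.file("extdata", "life_table_synthetic.csv", package = "blcea")
  if (nzchar(path) && file.exists(path)) {
    read_life_table(path)
  } else {
    make_life_table_fixture(target_e10 = 65, max_age = 100)
  }
}

#' Read / write a life table CSV
#'
#' Columns: `age_start`, `q_annual`, `disability_weight`.
#' @param path CSV file path.
#' @return `read_life_table`: the life table data.frame.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  need <- c("age_start", "q_annual", "disability_weight")
  if (!all(need %in% names(lt)))
    stop("life table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lt[need]
}

#' @rdname read_life_table
#' @param lt life table data.frame.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(lt, path, row.names = FALSE)
  invisible(path)
}
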