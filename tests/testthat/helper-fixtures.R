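# Small fabricated objects used across tests.

# A hand-built cohort trace (class bl_trace) from aligned vectors.
fake_trace <- function(t_start, t_end, state, alive_start, alive_end,
                       d_disease = NULL, d_background = NULL,
                       entry_age = 10) {
  deaths <- alive_start - alive_end
  if (is.null(d_disease)) d_disease <- ifelse(state != "post_disease", deaths, 0)
  if (is.null(d_background)) d_background <- ifelse(state == "post_disease", deaths, 0)
  structure(list(t_start = t_start, t_end = t_end, state = state,
                 alive_start = alive_start, alive_end = alive_end,
                 d_disease = d_disease, d_background = d_background,
                 age_mid = entry_age + (t_start + t_end) / 24),
            class = "bl_trace")
}

# life table with no mortality before the cap and no background morbidity:
# e(a) = cap - a exactly
flat_life_table <- function(dw = 0) {
  data.frame(age_start = c(0, 50), q_annual = c(0, 0),
             disability_weight = c(dw, dw))
}

# base config variant with an immortal cohort (no disease or background
# mortality) and optional zero discounting, for closed-form cost checks
immortal_config <- function(r = 0) {
  cfg <- bl_default_config(life_table = flat_life_table())
  cfg$survival$beta0$mean <- -60        # hazard ~ exp(-60): effectively zero
  cfg$survival$beta_advanced$mean <- 0
  cfg$econ$annual_discount_rate <- r
  cfg
}
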