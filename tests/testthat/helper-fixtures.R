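# Shared fixtures: built once per test run, small enough to stay fast.

tiny_model_config <- function(seed = 3) {
  model_config(max_tokens = 12, d_text = 8, n_text_layers = 2,
               n_text_heads = 2, ffn_mult = 2, mlp_widths = c(6, 5),
               dropout = 0, d_fusion = 8, n_fusion_layers = 2,
               n_fusion_heads = 2, seed = seed)
}

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_spec(n_patients = 250, seed = 42))
    }
    cache
  }
})

small_episodes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_episode_table(small_cohort())
    cache
  }
})

# minimal hand-built patient history for extraction tests
toy_history <- function(event_age = NA, registration_age = 30,
                        patient_id = "T1") {
  list(patient_id = patient_id, sex = "male",
       registration_age = registration_age, cvd_event_age = event_age,
       true_lp = 0)
}

example_episode <- function(...) {
  ep <- list(entry_age = 52, bmi = 31, ethnicity = "Indian",
             smoking = "ex-smoker", prestrat_risk = "moderate risk")
  for (flag in names(riskfusion:::COMORBIDITY_LABELS)) ep[[flag]] <- 0
  mods <- list(...)
  for (nm in names(mods)) ep[[nm]] <- mods[[nm]]
  ep
}
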