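# shared desk-scale synthetic dataset, built once per test run
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- confounded_scenario(strength = 1, seed = 42, n_patients = 800)
      sim <- generate_population(cfg)
      cohort <- classify_new_users(sim$patients, sim$prescriptions,
                                   c(cfg$window_start, cfg$window_end))
      cache <<- list(cfg = cfg, sim = sim, cohort = cohort,
                     window = c(cfg$window_start, cfg$window_end))
    }
    cache
  }
})

d0 <- as.Date("2000-01-01") # convenient date origin for hand fixtures

# minimal patient table for hand-built prescription fixtures
fix_patients <- function(ids, registration = d0 - 800) {
  data.frame(patient_id = ids, registration_date = registration,
             death_date = as.Date(NA), transfer_date = as.Date(NA))
}

fix_rx <- function(patient_id, drug_class, issue_date, supply_days = 28L) {
  data.frame(patient_id = patient_id, drug_class = drug_class,
             issue_date = issue_date, supply_days = supply_days)
}
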