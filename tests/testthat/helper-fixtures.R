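# Shared fixture builders: everything generated in code, nothing on disk.

tiny_table <- function() {
  abundance_table(matrix(c(60, 40, 0,
                           25, 50, 25),
                         nrow = 2, byrow = TRUE,
                         dimnames = list(c("s1", "s2"), c("fA", "fB", "fC"))))
}

tiny_metadata <- function(n = 2, cohort = "c1",
                          diet = c("omnivore", "vegan")) {
  sample_metadata(data.frame(
    sample_id = paste0("s", seq_len(n)), cohort = cohort,
    diet = rep_len(diet, n), sex = rep_len(c("female", "male"), n),
    age = seq(30, 60, length.out = n), bmi = seq(20, 30, length.out = n)))
}

tiny_ffq <- function() {
  intakes <- matrix(c(1.5, 2.0, 3.0,
                      0.5, 0.0, 1.0),
                    nrow = 2, byrow = TRUE,
                    dimnames = list(c("s1", "s2"),
                                    c("milk", "cheese", "apples")))
  gm <- data.frame(item = c("milk", "cheese", "apples"),
                   group = c("dairy", "dairy", "fruits"),
                   hpdi_direction = c("reverse", "reverse", "positive"))
  ffq_table(intakes, gm)
}

# small simulated dataset reused across tests (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_cohorts = 3, n_samples = c(260, 220, 180),
                        n_features = 80, n_signature_features = 5,
                        planted_smd = 1.0, n_food_features = 6, seed = 99)
      cache <<- c(simulate_cohorts(cfg), list(config = cfg))
    }
    cache
  }
})

# FFQ table with >= 18 hPDI groups built from the generator's design
sim_ffq_18 <- function() small_sim()$ffq
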