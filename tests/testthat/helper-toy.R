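# Hand-constructed toy cohorts with hand-scored aMed expectations.

# Eight participants, four per sex. Within males every favorable component
# takes values 10/20/30/40 (median 25) and red meat the reverse; within
# females 100/200/300/400 (median 250). Alcohol probes the 5-25 g/d window
# at both ends. Hand-scored totals: males 0, 1, 9, 8; females 0, 1, 9, 8.
toy_intakes <- function() {
  fav <- setdiff(amed_components(), c("red_meat", "alcohol"))
  male_vals <- c(10, 20, 30, 40)
  female_vals <- c(100, 200, 300, 400)
  df <- data.frame(sample_id = c(paste0("m", 1:4), paste0("f", 1:4)))
  for (cp in fav) df[[cp]] <- c(male_vals, female_vals)
  df$red_meat <- c(rev(male_vals), rev(female_vals))
  df$alcohol <- c(0, 5, 25, 40, 4, 15, 24, 26)
  df$energy <- rep(2000, 8)
  df$sex <- rep(c("male", "female"), each = 4)
  df
}

toy_expected_totals <- c(0, 1, 9, 8, 0, 1, 9, 8)

# A 10-per-sex cohort in which one participant per sex is constructed to
# satisfy every scoring criterion (total 9) and one to fail every one
# (total 0); the rest have intermediate continuous intakes.
toy_extreme_cohort <- function(seed = 42) {
  set.seed(seed)
  n <- 20
  fav <- setdiff(amed_components(), c("red_meat", "alcohol"))
  df <- data.frame(sample_id = sprintf("P%02d", 1:n),
                   sex = rep(c("male", "female"), each = 10))
  for (cp in fav) df[[cp]] <- runif(n, 10, 100)
  df$red_meat <- runif(n, 50, 150)
  df$alcohol <- runif(n, 0, 4)
  df$energy <- runif(n, 1500, 3000)
  # participant 1 (male) and 11 (female): best on everything
  for (cp in fav) df[[cp]][c(1, 11)] <- 1000
  df$red_meat[c(1, 11)] <- 1
  df$alcohol[c(1, 11)] <- 15
  # participant 2 (male) and 12 (female): worst on everything
  for (cp in fav) df[[cp]][c(2, 12)] <- 0
  df$red_meat[c(2, 12)] <- 1000
  df$alcohol[c(2, 12)] <- 0
  df
}

# Small complete cohort for model tests: generated quickly at modest n.
toy_synthetic <- function(seed = 1, n = 200, ...) {
  generate_cohort(generator_config(n_participants = n, seed = seed, ...))
}
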