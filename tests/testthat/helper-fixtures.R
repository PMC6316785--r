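# in-code fixture builders shared across test files

make_survey <- function(...) {
  survey_table(tibble::tibble(...))
}

# a small two-method, three-site community
toy_survey <- function() {
  make_survey(
    site_id = c("A", "A", "B", "B", "C", "A", "B"),
    method = c("pollard", "pollard", "pollard", "pollard", "pollard", "malaise", "malaise"),
    family = "Pieridae",
    species = c(
      "Pieris rapae", "Pontia protodice", "Pieris rapae", "Colias eurytheme",
      "Pieris rapae", "Pieris rapae", "Pontia protodice"
    ),
    count = c(2L, 1L, 4L, 3L, 1L, 5L, 2L)
  )
}

make_occurrences <- function(n = 5, raw_name = "Danaus plexippus",
                             family = "Nymphalidae",
                             latitude = 34.05, longitude = -118.25,
                             event_date = as.Date("2015-05-01"),
                             coordinate_uncertainty_m = 30,
                             quality_grade = "research") {
  occurrence_table(tibble::tibble(
    raw_name = rep_len(raw_name, n),
    family = rep_len(family, n),
    latitude = rep_len(latitude, n),
    longitude = rep_len(longitude, n),
    event_date = rep_len(event_date, n),
    coordinate_uncertainty_m = rep_len(coordinate_uncertainty_m, n),
    quality_grade = rep_len(quality_grade, n)
  ))
}

# independent direct-formula paired t, kept deliberately separate from the
# implementation under test
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(
    t = t_stat, df = n - 1,
    p = 2 * stats::pt(-abs(t_stat), df = n - 1),
    mean_difference = mean(d)
  )
}

# exhaustive enumeration of the k-draw-with-replacement mean pooled richness
# over a list of unit species sets (oracle for small bootstrap cases)
oracle_enumerated_mean_richness <- function(unit_sets) {
  n <- length(unit_sets)
  draws <- expand.grid(rep(list(seq_len(n)), n))
  richness <- apply(draws, 1, function(idx) {
    length(unique(unlist(unit_sets[idx], use.names = FALSE)))
  })
  mean(richness)
}

expect_validation_error <- function(expr) {
  testthat::expect_error(expr, class = "lepisurv_validation_error")
}

expect_config_error <- function(expr) {
  testthat::expect_error(expr, class = "lepisurv_config_error")
}
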