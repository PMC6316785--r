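test_that("duplicate (site, method, species) rows pool additively", {
  tab <- make_survey(
    site_id = c("siteA", "siteA", "siteB"),
    method = "pollard", family = "Pieridae",
    species = "Pieris rapae", count = c(2, 3, 1)
  )
  expect_equal(nrow(tab), 2)
  expect_equal(tab$count[tab$site_id == "siteA"], 5L)
})

test_that("pooling is order-independent", {
  rows <- tibble::tibble(
    site_id = c("A", "B", "A", "C", "B", "A"),
    method = c("pollard", "malaise", "pollard", "pollard", "malaise", "malaise"),
    family = "Nymphalidae",
    species = c("Vanessa cardui", "Vanessa cardui", "Vanessa atalanta",
                "Vanessa cardui", "Danaus plexippus", "Vanessa cardui"),
    count = c(1, 2, 3, 4, 5, 6)
  )
  set.seed(11)
  for (rep in 1:5) {
    perm <- rows[sample.int(nrow(rows)), ]
    expect_equal(survey_table(perm), survey_table(rows))
  }
})

test_that("malformed survey rows are rejected with row-numbered diagnostics", {
  bad_count <- tibble::tibble(
    site_id = c("A", "B"), method = "pollard", species = "Pieris rapae",
    count = c(3, -1)
  )
  expect_error(survey_table(bad_count), "row 2.*negative",
               class = "lepisurv_validation_error")
  expect_validation_error(survey_table(tibble::tibble(
    site_id = "A", method = "pollard", species = "Pieris rapae", count = 1.5
  )))
  expect_validation_error(survey_table(tibble::tibble(
    site_id = "A", method = "pollard", species = "", count = 1
  )))
  expect_config_error(survey_table(tibble::tibble(site_id = "A", count = 1)))
})

test_that("survey CSV round-trips losslessly, including via a dialect", {
  world <- simulate_world(community_model(n_species = 8, n_sites = 5), seed = 101)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(world$survey, path)
  expect_equal(read_survey_csv(path), world$survey)

  # same file under renamed columns resolves through a dialect
  renamed <- withr::local_tempfile(fileext = ".csv")
  raw <- readr::read_csv(path, show_col_types = FALSE)
  names(raw)[names(raw) == "count"] <- "n_individuals"
  readr::write_csv(raw, renamed, na = "")
  expect_equal(
    read_survey_csv(renamed, survey_dialect(count = "n_individuals")),
    world$survey
  )
})

test_that("occurrence records parse dates and preserve missing uncertainty", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scientificName,family,decimalLatitude,decimalLongitude,eventDate,coordinateUncertaintyInMeters,qualityGrade",
    "Danaus plexippus,Nymphalidae,34.05,-118.25,2015-04-01,250,research",
    "Vanessa cardui,Nymphalidae,34.10,-118.30,2015-05-02,,research"
  ), path)
  recs <- read_occurrence_csv(path)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$event_date[1], as.Date("2015-04-01"))
  expect_equal(recs$latitude[1], 34.05)
  expect_equal(recs$longitude[1], -118.25)
  expect_true(is.na(recs$coordinate_uncertainty_m[2]))
  expect_identical(recs$scientific_name, recs$raw_name)
})

test_that("unparseable occurrence fields raise row-named validation errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scientificName,decimalLatitude,decimalLongitude,eventDate",
    "Danaus plexippus,34.05,-118.25,not-a-date"
  ), path)
  expect_error(read_occurrence_csv(path), "row\\(s\\) 1",
               class = "lepisurv_validation_error")
  expect_validation_error(occurrence_table(tibble::tibble(
    raw_name = "x", latitude = 95, longitude = 0, event_date = as.Date("2015-04-01")
  )))
  expect_validation_error(occurrence_table(tibble::tibble(
    raw_name = "x", latitude = 0, longitude = 0,
    event_date = as.Date("2015-04-01"), coordinate_uncertainty_m = -5
  )))
})

test_that("a synthetic occurrence export round-trips record-for-record", {
  world <- simulate_benchmark_world(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrence_csv(world$incidental, path)
  back <- read_occurrence_csv(path)
  expect_equal(nrow(back), 105)
  expect_equal(back$raw_name, world$incidental$raw_name)
  expect_equal(back$coordinate_uncertainty_m, world$incidental$coordinate_uncertainty_m)
  expect_equal(back$event_date, world$incidental$event_date)
})

test_that("the packaged incidence table matches its published values", {
  inc <- load_incidence_summary()
  expect_s3_class(inc, "lepisurv_incidence")
  expect_equal(nrow(inc), 30)
  expect_equal(n_sites(inc), 16L)
  rapae <- inc[inc$species == "Pieris rapae", ]
  expect_equal(
    c(rapae$pollard_sites, rapae$malaise_sites, rapae$inat_observations),
    c(16L, 14L, 4L)
  )
  adelpha <- inc[inc$species == "Adelpha californica", ]
  expect_equal(
    c(adelpha$pollard_sites, adelpha$malaise_sites, adelpha$inat_observations),
    c(0L, 0L, 4L)
  )
})

test_that("incidence counts sites with presence, ignoring abundance", {
  tab <- make_survey(
    site_id = c("A", "B"), method = "pollard", family = "Pieridae",
    species = "Pieris rapae", count = c(1, 7)
  )
  inc <- summarize_incidence(tab)
  expect_equal(inc$pollard_sites, 2L)
  expect_equal(inc$malaise_sites, 0L)
})

test_that("summarize_incidence drops all-zero species and is deterministic", {
  tab <- make_survey(
    site_id = c("A", "B"), method = "pollard", family = "Pieridae",
    species = c("Pieris rapae", "Pontia protodice"), count = c(0, 2)
  )
  inc <- summarize_incidence(tab)
  expect_equal(inc$species, "Pontia protodice")

  world <- simulate_world(community_model(n_species = 6, n_sites = 4), seed = 5)
  expect_identical(
    summarize_incidence(world$survey, world$incidental),
    summarize_incidence(world$survey, world$incidental)
  )
})

test_that("empty inputs give an empty summary", {
  empty <- make_survey(
    site_id = character(0), method = character(0),
    species = character(0), count = integer(0)
  )
  inc <- summarize_incidence(empty)
  expect_equal(nrow(inc), 0)
})

test_that("incidence never exceeds the number of distinct sites", {
  for (seed in 1:10) {
    world <- simulate_world(
      community_model(n_species = 8, n_sites = 5, detect_pollard = 0.7),
      seed = seed
    )
    inc <- summarize_incidence(world$survey)
    n_distinct_sites <- length(unique(world$survey$site_id))
    expect_true(all(inc$pollard_sites <= n_distinct_sites))
    expect_true(all(inc$malaise_sites <= n_distinct_sites))
  }
})

test_that("incidence_summary enforces its invariants", {
  base <- tibble::tibble(
    family = "Pieridae", species = "Pieris rapae",
    pollard_sites = 5L, malaise_sites = 2L, inat_observations = 1L
  )
  expect_validation_error(incidence_summary(dplyr::mutate(base, pollard_sites = 20L), n_sites = 16))
  expect_validation_error(incidence_summary(dplyr::mutate(base, malaise_sites = -1L), n_sites = 16))
  expect_validation_error(incidence_summary(dplyr::bind_rows(base, base), n_sites = 16))
})
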