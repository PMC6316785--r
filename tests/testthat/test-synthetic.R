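test_that("perfect occupancy and detection yield full observed richness everywhere", {
  model <- community_model(
    n_species = 6, n_sites = 4, occupancy = 1, detect_pollard = 1,
    detect_malaise = 1, n_surveys_per_site = 2, n_incidental = 0
  )
  world <- simulate_world(model, seed = 17)
  for (m in c("pollard", "malaise")) {
    stats <- per_site_stats(world$survey, m)
    expect_equal(nrow(stats), 4)
    expect_true(all(stats$richness == 6))
  }
  expect_equal(nrow(world$incidental), 0)
})

test_that("method asymmetry: zero trap detection empties only the trap table", {
  model <- community_model(
    n_species = 8, n_sites = 5, occupancy = 0.9, detect_pollard = 0.8,
    detect_malaise = 0, n_incidental = 0
  )
  world <- simulate_world(model, seed = 23)
  expect_equal(nrow(world$malaise_table), 0)
  expect_gt(nrow(world$pollard_table), 0)
})

test_that("simulation is seed-deterministic, byte-identical when serialised", {
  model <- community_model(n_species = 7, n_sites = 4, n_incidental = 30,
                           synonym_noise_rate = 0.5, outlier_prob = 0.1)
  w1 <- simulate_world(model, seed = 77)
  w2 <- simulate_world(model, seed = 77)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))
  w3 <- simulate_world(model, seed = 78)
  expect_false(identical(w1$truth$occupancy, w3$truth$occupancy))
})

test_that("observed data never contradict the ground truth", {
  for (seed in 1:6) {
    world <- simulate_world(community_model(n_species = 9, n_sites = 5), seed = seed)
    truth_present <- world$truth$abundance > 0
    for (row in seq_len(nrow(world$survey))) {
      sp <- world$survey$species[row]
      site <- world$survey$site_id[row]
      if (world$survey$count[row] > 0) expect_true(truth_present[sp, site])
    }
    # observed per-site richness bounded by true per-site richness
    for (m in c("pollard", "malaise")) {
      stats <- per_site_stats(world$survey, m)
      for (i in seq_len(nrow(stats))) {
        expect_lte(stats$richness[i], sum(truth_present[, stats$site_id[i]]))
      }
    }
    # incidental records only of truly extant species
    extant <- rownames(world$truth$abundance)[rowSums(world$truth$abundance) > 0]
    expect_true(all(world$incidental$scientific_name %in%
                      union(extant, unname(world$model$synonym_map))))
  }
})

test_that("per-site detection frequency recovers psi * (1 - (1-p)^K)", {
  psi <- c(0.9, 0.6, 0.4, 0.2)
  p_pol <- 0.5
  p_mal <- 0.2
  K <- 4
  n_sites <- 6
  n_worlds <- 200
  model <- community_model(
    n_species = 4, n_sites = n_sites, occupancy = psi,
    site_abundance = 3, detect_pollard = p_pol, detect_malaise = p_mal,
    n_surveys_per_site = K, n_incidental = 0
  )
  hits <- list(pollard = matrix(0, 4, 1), malaise = matrix(0, 4, 1))
  detected_sites <- function(world, m, sp) {
    rows <- world$survey
    length(unique(rows$site_id[rows$method == m & rows$species == sp & rows$count > 0]))
  }
  species <- model$species
  hit_pol <- hit_mal <- numeric(4)
  for (seed in seq_len(n_worlds)) {
    world <- simulate_world(model, seed = seed)
    for (i in 1:4) {
      hit_pol[i] <- hit_pol[i] + detected_sites(world, "pollard", species[i])
      hit_mal[i] <- hit_mal[i] + detected_sites(world, "malaise", species[i])
    }
  }
  n_trials <- n_worlds * n_sites
  expect_freq <- function(hits, p_event) {
    for (i in 1:4) {
      expected <- psi[i] * (1 - (1 - p_event)^K)
      half_width <- 4 * sqrt(expected * (1 - expected) / n_trials)
      expect_lt(abs(hits[i] / n_trials - expected), half_width + 1e-9)
    }
  }
  expect_freq(hit_pol, p_pol)
  expect_freq(hit_mal, p_mal)
})

test_that("pooled richness is monotone on matched-seed parameter ladders", {
  pooled_richness <- function(world, m) {
    length(unique(world$survey$species[world$survey$method == m & world$survey$count > 0]))
  }
  for (seed in 1:10) {
    # detection ladder
    r_by_p <- vapply(c(0.05, 0.2, 0.5, 0.9), function(p) {
      w <- simulate_world(
        community_model(n_species = 10, n_sites = 5, detect_pollard = p,
                        n_incidental = 0),
        seed = seed
      )
      pooled_richness(w, "pollard")
    }, numeric(1))
    expect_true(all(diff(r_by_p) >= 0))

    # site-count ladder
    r_by_m <- vapply(c(2, 5, 10), function(m) {
      w <- simulate_world(
        community_model(n_species = 10, n_sites = m, n_incidental = 0),
        seed = seed
      )
      pooled_richness(w, "pollard")
    }, numeric(1))
    expect_true(all(diff(r_by_m) >= 0))

    # survey-effort ladder
    r_by_k <- vapply(c(1, 4, 16), function(k) {
      w <- simulate_world(
        community_model(n_species = 10, n_sites = 5, n_surveys_per_site = k,
                        n_incidental = 0),
        seed = seed
      )
      pooled_richness(w, "pollard")
    }, numeric(1))
    expect_true(all(diff(r_by_k) >= 0))
  }
})

test_that("incidental species frequencies match multinomial expectations", {
  # chi-square goodness of fit against weight x total-abundance intensities,
  # per world; rejections at alpha = 0.01 must stay rare
  n_worlds <- 200
  rejected <- 0L
  tested <- 0L
  model <- community_model(
    n_species = 5, n_sites = 8, occupancy = 1, site_abundance = 5,
    n_incidental = 250, incidental_weight = c(4, 3, 2, 1, 1)
  )
  for (seed in seq_len(n_worlds)) {
    world <- simulate_world(model, seed = seed)
    intensity <- world$model$incidental_weight * rowSums(world$truth$abundance)
    counts <- table(factor(world$incidental$scientific_name, levels = model$species))
    if (any(intensity == 0)) next
    p <- intensity / sum(intensity)
    tested <- tested + 1L
    fit <- suppressWarnings(chisq.test(as.integer(counts), p = p))
    if (fit$p.value < 0.01) rejected <- rejected + 1L
  }
  expect_gte(tested, 150)
  expect_gte((tested - rejected) / tested, 0.95)
})

test_that("synonym corruption only ever uses mapped platform names", {
  model <- community_model(
    n_species = 30, n_sites = 4, n_incidental = 150, synonym_noise_rate = 1
  )
  world <- simulate_world(model, seed = 55)
  corrupted <- world$incidental$raw_name[
    world$incidental$raw_name %in% unname(model$synonym_map)
  ]
  expect_gt(length(corrupted), 0)
  # reconciliation restores every corrupted record
  fixed <- reconcile_taxonomy(world$incidental)
  expect_true(all(fixed$scientific_name %in% model$species))
})

test_that("the calibrated benchmark world reproduces the packaged table end-to-end", {
  world <- simulate_benchmark_world(seed = 12)
  expect_equal(nrow(world$incidental), 105)
  cfg <- filter_config(bbox = world$model$bbox)
  kept <- suppressWarnings(
    filter_records(reconcile_taxonomy(world$incidental), cfg)
  )
  expect_equal(nrow(kept), 104)
  report <- filter_report(kept)
  expect_equal(report$n_out[report$stage == "uncertainty"], 104L)
  inc <- summarize_incidence(world$survey, kept, n_sites = 16)
  expect_equal(
    as.data.frame(inc), as.data.frame(load_incidence_summary())
  )
  expect_equal(source_richness(inc, "pollard"), 27L)

  # same seed, byte-identical world
  expect_identical(
    serialize(simulate_benchmark_world(seed = 12), NULL),
    serialize(world, NULL)
  )
})

test_that("model validation rejects infeasible parameters", {
  expect_validation_error(community_model(n_species = 0))
  expect_validation_error(community_model(occupancy = 1.2))
  expect_validation_error(community_model(site_abundance = 0))
  expect_validation_error(community_model(incidental_weight = 0))
  expect_validation_error(community_model(n_surveys_per_site = 0))
})

test_that("worlds round-trip through the plain-text writers", {
  world <- simulate_world(
    community_model(n_species = 6, n_sites = 3, n_incidental = 20), seed = 31
  )
  dir <- withr::local_tempdir()
  paths <- write_world(world, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(read_survey_csv(paths[["survey"]]), world$survey)
  back <- read_occurrence_csv(paths[["occurrences"]])
  expect_equal(back$raw_name, world$incidental$raw_name)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$seed, 31)
  expect_equal(length(truth$species), 6)
})
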