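#' Generative model for a synthetic butterfly community
#'
#' Specifies the ground-truth world the simulator draws from: per-species
#' site occupancy, abundance at occupied sites, per-method detection
#' probabilities for the structured surveys, and an intensity-weighted
#' process for incidental observations. Defaults describe a 16-site urban
#' survey of a 30-species butterfly fauna over a four-month spring-summer
#' window, with a common-to-rare occupancy/abundance gradient, walk surveys
#' detecting more reliably than passive traps, and 104 incidental records.
#'
#' @param n_species Number of species in the regional pool.
#' @param n_sites Number of survey sites (each surveyed by both methods).
#' @param occupancy Per-species probability a site is occupied; scalar or
#'   length-`n_species`. Default: a logistic gradient from ~0.92 to ~0.08.
#' @param site_abundance Per-species mean abundance at occupied sites
#'   (zero-truncated Poisson mean); occupied means present, so abundance at
#'   an occupied site is at least 1. Default: log-spaced 8 down to 0.5.
#' @param detect_pollard,detect_malaise Per-species, per-survey-event
#'   detection probability of a present species, for each method.
#' @param n_surveys_per_site Survey events per site per method (default 8:
#'   e.g. biweekly trap-bottle changes over four months; at most 64, the
#'   per-cell block of detection uniforms reserved so that matched-seed
#'   worlds stay comparable across parameter ladders).
#' @param incidental_weight Per-species relative reporting weight; the
#'   probability a given incidental record is species i is proportional to
#'   `incidental_weight[i]` times species i's total true abundance. A
#'   "photogenic-species" reporting bias is expressed by unequal weights.
#' @param n_incidental Total number of incidental records to draw.
#' @param bbox Study bounding box `c(lat_min, lat_max, lon_min, lon_max)`;
#'   incidental records get uniform points in it.
#' @param date_start,date_end Study window; incidental dates are uniform in
#'   it, survey rows are dated `date_start`.
#' @param uncertainty_meanlog,uncertainty_sdlog Log-normal parameters (log
#'   metres) of typical incidental coordinate uncertainty.
#' @param outlier_prob Probability an incidental record instead gets
#'   `outlier_magnitude_m` uncertainty (the "continental-scale blunder").
#' @param outlier_magnitude_m Uncertainty assigned to outlier records
#'   (default 2,600,000 m, above the conventional 2500 km exclusion bar).
#' @param synonym_noise_rate Probability an incidental record's reported name
#'   is replaced by a platform synonym of its species (when one exists in
#'   `synonym_map`).
#' @param synonym_map Accepted-name to raw-synonym corruption source; the
#'   reverse of the reconciliation map.
#' @param species,families Species binomials and their families; default the
#'   packaged 30-species urban butterfly pool.
#' @return A list of class `lepisurv_model`.
#' @export
community_model <- function(n_species = 30,
                            n_sites = 16,
                            occupancy = NULL,
                            site_abundance = NULL,
                            detect_pollard = 0.4,
                            detect_malaise = 0.15,
                            n_surveys_per_site = 8,
                            incidental_weight = 1,
                            n_incidental = 104,
                            bbox = c(33.95, 34.25, -118.55, -118.05),
                            date_start = as.Date("2015-03-15"),
                            date_end = as.Date("2015-07-15"),
                            uncertainty_meanlog = log(50),
                            uncertainty_sdlog = 1,
                            outlier_prob = 0,
                            outlier_magnitude_m = 2.6e6,
                            synonym_noise_rate = 0,
                            synonym_map = invert_synonym_map(default_synonym_map()),
                            species = NULL,
                            families = NULL) {
  n_species <- as.integer(n_species)
  n_sites <- as.integer(n_sites)
  if (is.na(n_species) || n_species < 1) stop_validation("n_species must be >= 1")
  if (is.na(n_sites) || n_sites < 1) stop_validation("n_sites must be >= 1")

  if (is.null(species)) {
    pool <- default_species_pool()
    if (n_species <= nrow(pool)) {
      species <- pool$species[seq_len(n_species)]
      families <- families %||% pool$family[seq_len(n_species)]
    } else {
      species <- sprintf("Genus species%03d", seq_len(n_species))
      families <- families %||% rep("Nymphalidae", n_species)
    }
  }
  families <- families %||% rep(NA_character_, n_species)
  if (length(species) != n_species || length(families) != n_species) {
    stop_validation("species and families must have length n_species")
  }

  occupancy <- occupancy %||% stats::plogis(seq(2.5, -2.5, length.out = n_species))
  site_abundance <- site_abundance %||% exp(seq(log(8), log(0.5), length.out = n_species))
  recycle <- function(x, what) {
    if (length(x) == 1) x <- rep(x, n_species)
    if (length(x) != n_species) stop_validation(paste0(what, " must be scalar or length n_species"))
    x
  }
  occupancy <- recycle(occupancy, "occupancy")
  site_abundance <- recycle(site_abundance, "site_abundance")
  detect_pollard <- recycle(detect_pollard, "detect_pollard")
  detect_malaise <- recycle(detect_malaise, "detect_malaise")
  incidental_weight <- recycle(incidental_weight, "incidental_weight")

  for (p in list(occupancy, detect_pollard, detect_malaise)) {
    if (any(p < 0 | p > 1)) stop_validation("probabilities must lie in [0, 1]")
  }
  if (any(site_abundance <= 0)) stop_validation("site_abundance must be positive")
  if (any(incidental_weight < 0) || sum(incidental_weight) <= 0) {
    stop_validation("incidental weights must be non-negative with positive sum")
  }
  if (n_surveys_per_site < 1 || n_surveys_per_site > DETECT_BLOCK) {
    stop_validation(sprintf("n_surveys_per_site must be in [1, %d]", DETECT_BLOCK))
  }
  if (n_incidental < 0) stop_validation("n_incidental must be >= 0")
  if (outlier_prob < 0 || outlier_prob > 1 || synonym_noise_rate < 0 || synonym_noise_rate > 1) {
    stop_validation("rates must lie in [0, 1]")
  }

  structure(
    list(
      n_species = n_species, n_sites = n_sites,
      species = as.character(species), families = as.character(families),
      occupancy = occupancy, site_abundance = site_abundance,
      detect_pollard = detect_pollard, detect_malaise = detect_malaise,
      n_surveys_per_site = as.integer(n_surveys_per_site),
      incidental_weight = incidental_weight,
      n_incidental = as.integer(n_incidental),
      bbox = validate_bbox(bbox),
      date_start = as.Date(date_start), date_end = as.Date(date_end),
      uncertainty_meanlog = uncertainty_meanlog,
      uncertainty_sdlog = uncertainty_sdlog,
      outlier_prob = outlier_prob,
      outlier_magnitude_m = outlier_magnitude_m,
      synonym_noise_rate = synonym_noise_rate,
      synonym_map = synonym_map
    ),
    class = "lepisurv_model"
  )
}

invert_synonym_map <- function(map) setNames(names(map), unname(map))

default_species_pool <- function() {
  path <- system.file("extdata", "la_butterfly_incidence.csv", package = "lepisurv")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)[, c("family", "species")]
}

# zero-truncated Poisson via inverse CDF: occupied sites hold >= 1 individual
rtpois <- function(n, lambda) {
  p0 <- stats::dpois(0, lambda)
  stats::qpois(stats::runif(n, min = p0, max = 1), lambda)
}

#' Simulate a synthetic survey world
#'
#' Draws one realisation of a [community_model()]: site occupancy Bernoulli
#' per species, zero-truncated Poisson abundance at occupied sites, and for
#' each method a series of per-site survey events in which each present
#' species is detected with its per-event detection probability (a detection
#' contributes at least one counted individual; detected counts are pooled
#' per site). Incidental records are multinomial draws with probability
#' proportional to reporting weight times total true abundance, each given a
#' uniform point in the study box, a uniform date in the window, a log-normal
#' coordinate uncertainty (with an optional outlier mass) and, at the synonym
#' noise rate, a platform-synonym corrupted name.
#'
#' All randomness flows from `seed` through five named substreams
#' (occupancy, abundance, detection, incidental, corruption) of the
#' Mersenne-Twister generator, so the same seed reproduces the world exactly
#' and the caller's RNG state is untouched.
#'
#' @param model A [community_model()].
#' @param seed Integer seed; if `NULL`, drawn from the current RNG stream.
#' @return A list of class `lepisurv_world` with elements `truth` (occupancy
#'   and abundance matrices), `pollard_table` and `malaise_table`
#'   (`lepisurv_survey`), `survey` (both pooled), `incidental`
#'   (`lepisurv_occurrence`), `model`, and `seed`.
#' @examples
#' w <- simulate_world(community_model(n_species = 5, n_sites = 4), seed = 42)
#' per_site_stats(w$survey, "pollard")
#' @export
simulate_world <- function(model, seed = NULL) {
  stopifnot(inherits(model, "lepisurv_model"))
  seed <- seed %||% draw_seed()
  streams <- with_local_seed(seed, sample.int(.Machine$integer.max, 8L))
  names(streams) <- c(
    "occupancy", "abundance", "detect_pollard", "detect_malaise",
    "count_pollard", "count_malaise", "incidental", "corruption"
  )

  S <- model$n_species
  M <- model$n_sites
  site_ids <- sprintf("site_%02d", seq_len(M))

  occ <- with_local_seed(streams[["occupancy"]], {
    matrix(rbinom(S * M, 1, rep(model$occupancy, times = M)), nrow = S, ncol = M)
  })
  abund <- with_local_seed(streams[["abundance"]], {
    a <- matrix(0L, nrow = S, ncol = M)
    idx <- which(occ == 1)
    if (length(idx) > 0) {
      lam <- model$site_abundance[(idx - 1) %% S + 1]
      a[idx] <- rtpois(length(idx), lam)
    }
    a
  })
  dimnames(occ) <- dimnames(abund) <- list(model$species, site_ids)

  # detection uniforms are consumed in fixed-size blocks per present
  # (site, species) cell, site-major, so matched-seed worlds stay coupled
  # across ladders of detect_p, n_surveys (<= DETECT_BLOCK) and n_sites
  # (common random numbers); extra-individual counts use their own substream
  # so they cannot desynchronise detection
  detect_counts <- function(p_vec, detect_seed, count_seed) {
    K <- model$n_surveys_per_site
    n_det <- matrix(0L, nrow = S, ncol = M)
    with_local_seed(detect_seed, {
      for (s in seq_len(M)) {
        for (i in which(abund[, s] > 0)) {
          u <- runif(DETECT_BLOCK)
          n_det[i, s] <- sum(u[seq_len(K)] < p_vec[i])
        }
      }
    })
    counts <- matrix(0L, nrow = S, ncol = M)
    with_local_seed(count_seed, {
      idx <- which(n_det > 0)
      for (cell in idx) {
        i <- (cell - 1L) %% S + 1L
        # each detection event counts >= 1 individual; further individuals
        # present at the site are seen with the same per-event probability
        extra <- rbinom(n_det[cell], abund[cell] - 1L, p_vec[i])
        counts[cell] <- n_det[cell] + sum(extra)
      }
    })
    counts
  }
  pollard_counts <- detect_counts(
    model$detect_pollard, streams[["detect_pollard"]], streams[["count_pollard"]]
  )
  malaise_counts <- detect_counts(
    model$detect_malaise, streams[["detect_malaise"]], streams[["count_malaise"]]
  )

  counts_to_table <- function(counts, method) {
    idx <- which(counts > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      return(survey_table(tibble(
        site_id = character(0), method = character(0), family = character(0),
        species = character(0), count = integer(0), date = as.Date(character(0))
      )))
    }
    survey_table(tibble(
      site_id = site_ids[idx[, 2]],
      method = method,
      family = model$families[idx[, 1]],
      species = model$species[idx[, 1]],
      count = counts[idx],
      date = model$date_start
    ))
  }
  pollard_table <- counts_to_table(pollard_counts, "pollard")
  malaise_table <- counts_to_table(malaise_counts, "malaise")
  survey <- survey_table(dplyr::bind_rows(pollard_table, malaise_table))

  incidental <- with_local_seed(streams[["incidental"]], {
    n_inc <- model$n_incidental
    total_abund <- rowSums(abund)
    intensity <- model$incidental_weight * total_abund
    if (n_inc == 0 || sum(intensity) == 0) {
      if (n_inc > 0) warn("no species has positive incidental intensity; no records drawn")
      empty_occurrences()
    } else {
      sp_idx <- sample.int(S, n_inc, replace = TRUE, prob = intensity)
      n_days <- as.integer(model$date_end - model$date_start)
      unc <- rlnorm(n_inc, model$uncertainty_meanlog, model$uncertainty_sdlog)
      is_outlier <- runif(n_inc) < model$outlier_prob
      unc[is_outlier] <- model$outlier_magnitude_m
      occurrence_table(tibble(
        raw_name = model$species[sp_idx],
        family = model$families[sp_idx],
        latitude = runif(n_inc, model$bbox[["lat_min"]], model$bbox[["lat_max"]]),
        longitude = runif(n_inc, model$bbox[["lon_min"]], model$bbox[["lon_max"]]),
        event_date = model$date_start + sample.int(n_days + 1L, n_inc, replace = TRUE) - 1L,
        coordinate_uncertainty_m = unc,
        quality_grade = "research"
      ))
    }
  })

  incidental <- with_local_seed(streams[["corruption"]], {
    if (nrow(incidental) > 0 && model$synonym_noise_rate > 0 && length(model$synonym_map) > 0) {
      has_syn <- incidental$raw_name %in% names(model$synonym_map)
      corrupt <- has_syn & runif(nrow(incidental)) < model$synonym_noise_rate
      incidental$raw_name[corrupt] <- unname(model$synonym_map[incidental$raw_name[corrupt]])
      incidental$scientific_name <- incidental$raw_name
    }
    incidental
  })

  structure(
    list(
      truth = list(occupancy = occ, abundance = abund, species = model$species),
      pollard_table = pollard_table, malaise_table = malaise_table,
      survey = survey, incidental = incidental, model = model, seed = seed
    ),
    class = "lepisurv_world"
  )
}

empty_occurrences <- function() {
  occurrence_table(tibble(
    raw_name = character(0), family = character(0), latitude = numeric(0),
    longitude = numeric(0), event_date = as.Date(character(0)),
    coordinate_uncertainty_m = numeric(0), quality_grade = character(0)
  ))
}

#' @export
print.lepisurv_world <- function(x, ...) {
  cat(sprintf(
    "Synthetic survey world (seed %d): %d species pool, %d sites\n",
    x$seed, x$model$n_species %||% nrow(x$truth$abundance), ncol(x$truth$abundance)
  ))
  cat(sprintf(
    "  walk rows %d, trap rows %d, incidental records %d\n",
    nrow(x$pollard_table), nrow(x$malaise_table), nrow(x$incidental)
  ))
  invisible(x)
}

#' Deterministic benchmark world matching the packaged incidence table
#'
#' Constructs a synthetic world calibrated so that running the full pipeline
#' (taxonomy reconciliation, occurrence filtering, incidence summarisation)
#' reproduces the packaged 30-species urban-butterfly incidence table
#' exactly: 16 sites, source richness 27 / 18 / 22, 104 retained incidental
#' records. Site identities and abundances are drawn from the seed; the
#' incidence structure is fixed by construction. Three realistic data defects
#' are built in: one extra in-window, in-box record of *Atlides halesus* with
#' a 2,600,000 m coordinate uncertainty (so the raw incidental set holds 105
#' records, and exactly one falls at the uncertainty stage), and
#' platform-synonym names for two species (*Poanes melane* reported as
#' *Paratrytone melane*; *Papilio rumiko* as *Zerynthia rumina*) which
#' [reconcile_taxonomy()] must repair.
#'
#' @param seed Integer seed for the arbitrary choices (which sites, what
#'   abundances, where the points fall). Same seed, byte-identical world.
#' @return A `lepisurv_world`; `truth` holds the target incidence table.
#' @examples
#' w <- simulate_benchmark_world(seed = 1)
#' nrow(w$incidental) # 105 before filtering
#' @export
simulate_benchmark_world <- function(seed = 1) {
  target <- load_incidence_summary()
  model <- community_model(n_species = nrow(target), n_sites = n_sites(target))
  site_ids <- sprintf("site_%02d", seq_len(model$n_sites))
  streams <- with_local_seed(seed, sample.int(.Machine$integer.max, 3L))

  survey_rows <- with_local_seed(streams[1], {
    rows <- purrr::pmap(
      list(target$family, target$species, target$pollard_sites, target$malaise_sites),
      function(fam, sp, n_pol, n_mal) {
        pick <- function(k, method) {
          if (k == 0) return(NULL)
          tibble(
            site_id = sort(sample(site_ids, k)), method = method, family = fam,
            species = sp, count = 1L + rpois(k, 2), date = model$date_start
          )
        }
        dplyr::bind_rows(pick(n_pol, "pollard"), pick(n_mal, "malaise"))
      }
    )
    dplyr::bind_rows(rows)
  })
  survey <- survey_table(survey_rows)

  reverse_map <- invert_synonym_map(default_synonym_map())
  incidental <- with_local_seed(streams[2], {
    sp_idx <- rep(seq_len(nrow(target)), times = target$inat_observations)
    n_inc <- length(sp_idx)
    n_days <- as.integer(model$date_end - model$date_start)
    raw <- target$species[sp_idx]
    corrupted <- !is.na(match(raw, names(reverse_map)))
    raw[corrupted] <- unname(reverse_map[raw[corrupted]])
    base <- tibble(
      raw_name = raw,
      family = target$family[sp_idx],
      latitude = runif(n_inc, model$bbox[["lat_min"]], model$bbox[["lat_max"]]),
      longitude = runif(n_inc, model$bbox[["lon_min"]], model$bbox[["lon_max"]]),
      event_date = model$date_start + sample.int(n_days + 1L, n_inc, replace = TRUE) - 1L,
      coordinate_uncertainty_m = round(rlnorm(n_inc, log(50), 1), 1),
      quality_grade = "research"
    )
    blunder <- tibble(
      raw_name = "Atlides halesus", family = "Lycaenidae",
      latitude = mean(model$bbox[c("lat_min", "lat_max")]),
      longitude = mean(model$bbox[c("lon_min", "lon_max")]),
      event_date = model$date_start + 30L,
      coordinate_uncertainty_m = 2.6e6, quality_grade = "research"
    )
    occurrence_table(dplyr::bind_rows(base, blunder))
  })

  structure(
    list(
      truth = list(incidence = target),
      pollard_table = survey_table(dplyr::filter(survey, .data$method == "pollard")),
      malaise_table = survey_table(dplyr::filter(survey, .data$method == "malaise")),
      survey = survey, incidental = incidental, model = model, seed = as.integer(seed)
    ),
    class = "lepisurv_world"
  )
}

#' Write a synthetic world to plain-text files
#'
#' Writes the pooled survey table, the incidental occurrence records (Darwin
#' Core field names) and a ground-truth JSON (model parameters and, for
#' simulated worlds, the occupancy/abundance matrices) into a directory.
#'
#' @param world A `lepisurv_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "lepisurv_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    survey = file.path(dir, "survey.csv"),
    occurrences = file.path(dir, "occurrences.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_survey_csv(world$survey, paths[["survey"]])
  write_occurrence_csv(world$incidental, paths[["occurrences"]])
  truth <- list(
    seed = world$seed,
    n_sites = world$model$n_sites,
    species = world$model$species,
    occupancy = if (!is.null(world$truth$occupancy)) unname(apply(world$truth$occupancy, 1, as.integer, simplify = FALSE)),
    abundance = if (!is.null(world$truth$abundance)) unname(apply(world$truth$abundance, 1, as.integer, simplify = FALSE))
  )
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
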