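#' Column-name dialects for survey and occurrence files
#'
#' A dialect maps the package's canonical column names to the column names
#' actually present in a file. Defaults cover the package's own export format
#' (`survey_dialect()`) and Darwin Core simple-CSV field names as produced by
#' GBIF occurrence downloads (`darwin_core_dialect()`). Override individual
#' entries for files with non-standard headers.
#'
#' @param ... Named overrides, e.g. `species = "Species_Name"`. Names must be
#'   canonical column names; values are the column names in the file.
#' @return A named character vector mapping canonical names to file columns.
#' @examples
#' survey_dialect(count = "n_individuals")
#' darwin_core_dialect()
#' @export
survey_dialect <- function(...) {
  base <- c(
    site_id = "site_id", method = "method", species = "species",
    family = "family", count = "count", date = "date"
  )
  apply_dialect_overrides(base, list(...))
}

#' @rdname survey_dialect
#' @export
darwin_core_dialect <- function(...) {
  base <- c(
    raw_name = "scientificName",
    family = "family",
    latitude = "decimalLatitude",
    longitude = "decimalLongitude",
    event_date = "eventDate",
    coordinate_uncertainty_m = "coordinateUncertaintyInMeters",
    quality_grade = "qualityGrade"
  )
  apply_dialect_overrides(base, list(...))
}

apply_dialect_overrides <- function(base, overrides) {
  if (length(overrides) == 0) return(base)
  bad <- setdiff(names(overrides), names(base))
  if (length(bad) > 0 || is.null(names(overrides)) || any(names(overrides) == "")) {
    stop_config(paste0(
      "Unknown dialect entries: ", paste(bad, collapse = ", "),
      ". Valid canonical names: ", paste(names(base), collapse = ", ")
    ))
  }
  base[names(overrides)] <- unlist(overrides, use.names = FALSE)
  base
}

new_survey_table <- function(x) {
  structure(as_tibble(x), class = c("lepisurv_survey", class(as_tibble(x))))
}

#' Build a validated per-site survey table
#'
#' Validates long-format survey rows of (site, method, species, count) and
#' pools counts additively over duplicate (site, method, species) keys, so the
#' result carries the pooled species abundance for each site. Pooling is
#' order-independent: permuting input rows yields an identical table.
#'
#' @param x A data frame with columns `site_id`, `method` (`"pollard"` or
#'   `"malaise"`), `family`, `species`, `count` (non-negative integer) and
#'   optionally `date`.
#' @return A tibble of class `lepisurv_survey`, one row per
#'   (site, method, species), sorted deterministically.
#' @examples
#' survey_table(data.frame(
#'   site_id = "A", method = "pollard", family = "Pieridae",
#'   species = "Pieris rapae", count = c(2, 3)
#' ))
#' @export
survey_table <- function(x) {
  x <- as_tibble(x)
  required <- c("site_id", "method", "species", "count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_config(paste0("Missing survey columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"family" %in% names(x)) x$family <- NA_character_
  if (!"date" %in% names(x)) x$date <- as.Date(NA)
  x$site_id <- as.character(x$site_id)
  x$method <- as.character(x$method)
  x$family <- as.character(x$family)
  x$species <- as.character(x$species)

  validate_survey_rows(x)
  x$count <- as.integer(round(suppressWarnings(as.numeric(x$count))))
  x$date <- as.Date(x$date)

  pooled <- x |>
    dplyr::group_by(.data$site_id, .data$method, .data$family, .data$species) |>
    dplyr::summarise(
      count = sum(.data$count),
      date = if (all(is.na(.data$date))) as.Date(NA) else min(.data$date, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$method, .data$site_id, .data$family, .data$species)
  new_survey_table(pooled[, c("site_id", "method", "family", "species", "count", "date")])
}

validate_survey_rows <- function(x) {
  problems <- character(0)
  bad_row <- function(i, why) sprintf("row %d: %s", i, why)
  count_num <- suppressWarnings(as.numeric(x$count))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$species[i]) || !nzchar(trimws(x$species[i]))) {
      problems <- c(problems, bad_row(i, "empty species name"))
    }
    if (!is.na(x$method[i]) && !x$method[i] %in% SURVEY_METHODS) {
      problems <- c(problems, bad_row(i, sprintf(
        "unknown method '%s' (expected %s)", x$method[i],
        paste(SURVEY_METHODS, collapse = " or ")
      )))
    }
    cn <- count_num[i]
    if (is.na(cn)) {
      problems <- c(problems, bad_row(i, sprintf("unparseable count '%s'", x$count[i])))
    } else if (cn < 0) {
      problems <- c(problems, bad_row(i, sprintf("negative count %s", format(cn))))
    } else if (abs(cn - round(cn)) > 1e-8) {
      problems <- c(problems, bad_row(i, sprintf("non-integer count %s", format(cn))))
    }
  }
  if (length(problems) > 0) {
    stop_validation(paste0(
      "Invalid survey rows:\n", paste(head(problems, 20), collapse = "\n")
    ))
  }
  invisible(x)
}

#' Read and write long-format survey tables
#'
#' `read_survey_csv()` reads a CSV of per-site abundance records, resolves
#' column names through a [survey_dialect()], validates every row (malformed
#' rows are reported with their row number) and pools duplicate
#' (site, method, species) rows additively. `write_survey_csv()` is its
#' lossless inverse.
#'
#' @param path File path.
#' @param dialect Column-name mapping from [survey_dialect()].
#' @return `read_survey_csv()` returns a `lepisurv_survey` tibble;
#'   `write_survey_csv()` returns `path` invisibly.
#' @export
read_survey_csv <- function(path, dialect = survey_dialect()) {
  raw <- read_delim_quiet(path)
  needed <- dialect[c("site_id", "method", "species", "count")]
  missing_cols <- setdiff(unname(needed), names(raw))
  if (length(missing_cols) > 0) {
    stop_config(paste0(
      "File ", path, " lacks required columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  out <- tibble(
    site_id = as.character(raw[[dialect[["site_id"]]]]),
    method = as.character(raw[[dialect[["method"]]]]),
    species = as.character(raw[[dialect[["species"]]]]),
    count = raw[[dialect[["count"]]]]
  )
  fam_col <- dialect[["family"]]
  out$family <- if (fam_col %in% names(raw)) as.character(raw[[fam_col]]) else NA_character_
  date_col <- dialect[["date"]]
  out$date <- if (date_col %in% names(raw)) parse_dates(raw[[date_col]], path) else as.Date(NA)
  survey_table(out)
}

#' @rdname read_survey_csv
#' @param x A `lepisurv_survey` table.
#' @export
write_survey_csv <- function(x, path) {
  stopifnot(inherits(x, "lepisurv_survey"))
  readr::write_csv(x, path, na = "")
  invisible(path)
}

read_delim_quiet <- function(path) {
  if (!file.exists(path)) stop_config(paste0("File not found: ", path))
  delim <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE, na = c("", "NA")
  )
}

parse_dates <- function(x, path) {
  parsed <- as.Date(rep(NA, length(x)))
  not_missing <- !is.na(x) & nzchar(x)
  # strict ISO 8601; non-matching strings become NA and are reported below
  parsed[not_missing] <- as.Date(x[not_missing], format = "%Y-%m-%d")
  bad <- which(not_missing & is.na(parsed))
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "Unparseable date(s) in %s at row(s) %s (expected ISO 8601)",
      path, paste(head(bad, 10), collapse = ", ")
    ))
  }
  parsed
}

new_occurrence_table <- function(x) {
  structure(as_tibble(x), class = c("lepisurv_occurrence", class(as_tibble(x))))
}

#' Build a validated occurrence-record table
#'
#' Occurrence records are incidental, presence-only observations in Darwin
#' Core style: a reported name, a point coordinate, an event date, an optional
#' coordinate uncertainty in metres and a quality flag. Missing uncertainty is
#' preserved as missing, never coerced to zero. `scientific_name` starts equal
#' to `raw_name` and is updated by [reconcile_taxonomy()].
#'
#' @param x A data frame with columns `raw_name`, `latitude`, `longitude`,
#'   `event_date`, and optionally `family`, `coordinate_uncertainty_m`,
#'   `quality_grade`, `scientific_name`.
#' @return A tibble of class `lepisurv_occurrence` with a stable `record_id`.
#' @export
occurrence_table <- function(x) {
  x <- as_tibble(x)
  required <- c("raw_name", "latitude", "longitude", "event_date")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_config(paste0("Missing occurrence columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"record_id" %in% names(x)) x$record_id <- seq_len(nrow(x))
  if (!"family" %in% names(x)) x$family <- NA_character_
  if (!"coordinate_uncertainty_m" %in% names(x)) x$coordinate_uncertainty_m <- NA_real_
  if (!"quality_grade" %in% names(x)) x$quality_grade <- NA_character_
  if (!"scientific_name" %in% names(x)) x$scientific_name <- x$raw_name

  x$raw_name <- as.character(x$raw_name)
  x$scientific_name <- as.character(x$scientific_name)
  x$family <- as.character(x$family)
  x$quality_grade <- as.character(x$quality_grade)
  x$latitude <- as.numeric(x$latitude)
  x$longitude <- as.numeric(x$longitude)
  x$coordinate_uncertainty_m <- as.numeric(x$coordinate_uncertainty_m)
  x$event_date <- as.Date(x$event_date)

  bad_lat <- which(!is.na(x$latitude) & abs(x$latitude) > 90)
  bad_lon <- which(!is.na(x$longitude) & abs(x$longitude) > 180)
  bad_unc <- which(!is.na(x$coordinate_uncertainty_m) & x$coordinate_uncertainty_m < 0)
  problems <- c(
    if (length(bad_lat) > 0) sprintf("row %d: latitude outside [-90, 90]", bad_lat),
    if (length(bad_lon) > 0) sprintf("row %d: longitude outside [-180, 180]", bad_lon),
    if (length(bad_unc) > 0) sprintf("row %d: negative coordinate uncertainty", bad_unc)
  )
  if (length(problems) > 0) {
    stop_validation(paste0("Invalid occurrence rows:\n", paste(head(problems, 20), collapse = "\n")))
  }
  cols <- c(
    "record_id", "raw_name", "scientific_name", "family", "latitude",
    "longitude", "event_date", "coordinate_uncertainty_m", "quality_grade"
  )
  new_occurrence_table(x[, cols])
}

#' Read and write occurrence-record files
#'
#' `read_occurrence_csv()` reads a Darwin Core style CSV or TSV export (as
#' produced by GBIF downloads), resolving field names through
#' [darwin_core_dialect()]. Dates are parsed to calendar dates; unparseable
#' dates or out-of-range coordinates raise a validation error naming the row;
#' missing coordinate uncertainty stays missing. `write_occurrence_csv()`
#' writes records back under the dialect's field names, losslessly.
#'
#' @param path File path (`.tsv`/`.tab` are read tab-separated).
#' @param dialect Column-name mapping from [darwin_core_dialect()].
#' @return `read_occurrence_csv()` returns a `lepisurv_occurrence` tibble.
#' @export
read_occurrence_csv <- function(path, dialect = darwin_core_dialect()) {
  raw <- read_delim_quiet(path)
  name_col <- dialect[["raw_name"]]
  if (!name_col %in% names(raw)) {
    stop_config(paste0("File ", path, " lacks required column: ", name_col))
  }
  grab <- function(canonical) {
    col <- dialect[[canonical]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  lat <- parse_coordinates(grab("latitude"), "latitude", path)
  lon <- parse_coordinates(grab("longitude"), "longitude", path)
  occurrence_table(tibble(
    raw_name = as.character(raw[[name_col]]),
    family = as.character(grab("family")),
    latitude = lat,
    longitude = lon,
    event_date = parse_dates(grab("event_date"), path),
    coordinate_uncertainty_m = suppressWarnings(as.numeric(grab("coordinate_uncertainty_m"))),
    quality_grade = as.character(grab("quality_grade"))
  ))
}

parse_coordinates <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "Unparseable %s in %s at row(s) %s", what, path,
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  out
}

#' @rdname read_occurrence_csv
#' @param x A `lepisurv_occurrence` table.
#' @export
write_occurrence_csv <- function(x, path, dialect = darwin_core_dialect()) {
  stopifnot(inherits(x, "lepisurv_occurrence"))
  out <- tibble(
    !!dialect[["raw_name"]] := x$raw_name,
    !!dialect[["family"]] := x$family,
    !!dialect[["latitude"]] := x$latitude,
    !!dialect[["longitude"]] := x$longitude,
    !!dialect[["event_date"]] := format(x$event_date, "%Y-%m-%d"),
    !!dialect[["coordinate_uncertainty_m"]] := x$coordinate_uncertainty_m,
    !!dialect[["quality_grade"]] := x$quality_grade
  )
  delim <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

new_incidence_summary <- function(x, n_sites) {
  x <- as_tibble(x)
  attr(x, "n_sites") <- as.integer(n_sites)
  structure(x, class = c("lepisurv_incidence", class(x)))
}

#' Build a species-by-source incidence summary
#'
#' An incidence summary holds, per species, the number of survey sites at
#' which it was recorded by each structured method (site incidence, not
#' abundance) and the number of incidental observations. Rows that are zero
#' everywhere are dropped.
#'
#' @param x A data frame with columns `family`, `species`, `pollard_sites`,
#'   `malaise_sites`, `inat_observations`.
#' @param n_sites Number of survey sites per structured method; site
#'   incidences may not exceed it.
#' @return A tibble of class `lepisurv_incidence` carrying `n_sites` as an
#'   attribute (see [n_sites()]).
#' @export
incidence_summary <- function(x, n_sites) {
  x <- as_tibble(x)
  required <- c("family", "species", "pollard_sites", "malaise_sites", "inat_observations")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_config(paste0("Missing incidence columns: ", paste(missing_cols, collapse = ", ")))
  }
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 1) stop_config("n_sites must be a positive integer")
  for (col in c("pollard_sites", "malaise_sites", "inat_observations")) {
    x[[col]] <- as.integer(x[[col]])
    if (any(is.na(x[[col]])) || any(x[[col]] < 0)) {
      stop_validation(paste0(col, " must be non-negative integers"))
    }
  }
  if (any(x$pollard_sites > n_sites) || any(x$malaise_sites > n_sites)) {
    stop_validation("site incidence exceeds n_sites")
  }
  if (anyDuplicated(paste(x$family, x$species))) {
    stop_validation("duplicate (family, species) rows in incidence summary")
  }
  x <- x[x$pollard_sites + x$malaise_sites + x$inat_observations > 0, required]
  x <- dplyr::arrange(x, .data$family, .data$species)
  new_incidence_summary(x, n_sites)
}

#' Number of survey sites behind an incidence summary
#'
#' @param x A `lepisurv_incidence` table.
#' @return An integer scalar.
#' @export
n_sites <- function(x) {
  n <- attr(x, "n_sites", exact = TRUE)
  if (is.null(n)) stop_config("object carries no n_sites attribute")
  n
}

#' Load the packaged urban-butterfly incidence table
#'
#' The package ships the published species-by-source summary of a 16-site
#' urban butterfly study in the Los Angeles Basin (spring-summer 2015): for
#' each of 30 species, the number of sites (out of 16) where it was recorded
#' on volunteer transect walks and in Malaise traps, and its number of
#' filtered incidental (iNaturalist) observations. This is the worked-example
#' dataset behind [source_richness()], [mean_richness_from_incidence()] and
#' friends.
#'
#' @return A `lepisurv_incidence` tibble of 30 species with `n_sites = 16`.
#' @examples
#' inc <- load_incidence_summary()
#' source_richness(inc, "pollard")
#' @export
load_incidence_summary <- function() {
  path <- system.file("extdata", "la_butterfly_incidence.csv", package = "lepisurv")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  incidence_summary(raw, n_sites = 16L)
}

#' Summarise surveys and incidental records into a species-by-source table
#'
#' For each species, counts the distinct sites with a positive count under
#' each structured method (abundance is ignored beyond presence) and the
#' number of incidental occurrence records. Species observed nowhere are
#' dropped. Deterministic: the same inputs always give the same table.
#'
#' @param survey A `lepisurv_survey` table (may mix both methods).
#' @param occurrences Optional `lepisurv_occurrence` table of already filtered
#'   and reconciled incidental records.
#' @param n_sites Number of sites per structured method; defaults to the
#'   number of distinct `site_id` values in `survey`.
#' @return A `lepisurv_incidence` tibble.
#' @export
summarize_incidence <- function(survey, occurrences = NULL, n_sites = NULL) {
  stopifnot(inherits(survey, "lepisurv_survey"))
  if (is.null(n_sites)) {
    n_sites <- max(1L, length(unique(survey$site_id)))
  }
  site_counts <- survey |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$family, .data$species, .data$method) |>
    dplyr::summarise(sites = dplyr::n_distinct(.data$site_id), .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "method", values_from = "sites", values_fill = 0L,
      names_expand = FALSE
    )
  for (m in SURVEY_METHODS) if (!m %in% names(site_counts)) site_counts[[m]] <- 0L

  if (!is.null(occurrences) && nrow(occurrences) > 0) {
    stopifnot(inherits(occurrences, "lepisurv_occurrence"))
    obs <- occurrences |>
      dplyr::group_by(family = .data$family, species = .data$scientific_name) |>
      dplyr::summarise(inat_observations = dplyr::n(), .groups = "drop")
  } else {
    obs <- tibble(family = character(0), species = character(0), inat_observations = integer(0))
  }

  merged <- dplyr::full_join(site_counts, obs, by = c("family", "species"))
  merged$pollard_sites <- as.integer(merged$pollard %||% 0L)
  merged$malaise_sites <- as.integer(merged$malaise %||% 0L)
  merged$pollard_sites[is.na(merged$pollard_sites)] <- 0L
  merged$malaise_sites[is.na(merged$malaise_sites)] <- 0L
  merged$inat_observations <- as.integer(merged$inat_observations)
  merged$inat_observations[is.na(merged$inat_observations)] <- 0L
  incidence_summary(merged, n_sites = n_sites)
}

#' @export
print.lepisurv_incidence <- function(x, ...) {
  cat(sprintf(
    "Species-by-source incidence summary: %d species, %d sites per method\n",
    nrow(x), n_sites(x)
  ))
  NextMethod()
}
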