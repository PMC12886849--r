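#' Column-name dialect for survey tables
#'
#' Maps the package's canonical record fields to the column names of an
#' input CSV. Defaults follow the BioTIME public export. Fields mapped to
#' `NA` are treated as absent: a missing `community_id` falls back to
#' `study_id`, a missing `taxon_group` to `"all"`, missing coordinates to
#' `NA`.
#'
#' @param study_id,community_id,year,sample_id,species_id,latitude,longitude,taxon_group
#'   Column names in the input file for each canonical field.
#' @return Named character vector (a dialect).
#' @export
biotime_dialect <- function(study_id = "STUDY_ID",
                            community_id = NA,
                            year = "YEAR",
                            sample_id = "SAMPLE_DESC",
                            species_id = "GENUS_SPECIES",
                            latitude = "LATITUDE",
                            longitude = "LONGITUDE",
                            taxon_group = "TAXA") {
  c(study_id = study_id, community_id = community_id, year = year,
    sample_id = sample_id, species_id = species_id, latitude = latitude,
    longitude = longitude, taxon_group = taxon_group)
}

#' Read a long-format survey table
#'
#' Reads one presence record per row — (study, community, year, sample,
#' species) — from a CSV, resolving column names through a dialect,
#' collapsing duplicate rows, and rejecting (with a warning) rows whose year
#' does not parse to a 4-digit integer. Abundance columns, if any, are
#' ignored: presence means at least one record of the species in that
#' (year, sample).
#'
#' @param path CSV file path.
#' @param dialect Named character vector from [biotime_dialect()].
#' @return Tibble of presence records with canonical columns `study_id`,
#'   `community_id`, `year` (integer), `sample_id`, `species_id`,
#'   `latitude`, `longitude`, `taxon_group`. Attributes `n_malformed` and
#'   `n_duplicates` count rejected and collapsed rows.
#' @export
read_survey_table <- function(path, dialect = biotime_dialect()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("study_id", "year", "sample_id", "species_id")
  for (field in required) {
    col <- dialect[[field]]
    if (is.na(col) || !col %in% names(raw)) {
      stop("required column for '", field, "' (mapped to '", col,
           "') not found in ", path, call. = FALSE)
    }
  }
  pick <- function(field, default) {
    col <- dialect[[field]]
    if (!is.na(col) && col %in% names(raw)) raw[[col]] else default
  }
  n <- nrow(raw)
  rec <- tibble::tibble(
    study_id = as.character(raw[[dialect[["study_id"]]]]),
    community_id = as.character(pick("community_id",
                                     raw[[dialect[["study_id"]]]])),
    year = suppressWarnings(as.integer(raw[[dialect[["year"]]]])),
    sample_id = as.character(raw[[dialect[["sample_id"]]]]),
    species_id = as.character(raw[[dialect[["species_id"]]]]),
    latitude = as.numeric(pick("latitude", NA_real_)),
    longitude = as.numeric(pick("longitude", NA_real_)),
    taxon_group = as.character(pick("taxon_group", "all"))
  )
  bad <- is.na(rec$year) | rec$year < 1000 | rec$year > 9999
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable year rejected",
            call. = FALSE)
    rec <- rec[!bad, ]
  }
  dedup <- dplyr::distinct(
    rec, .data$study_id, .data$community_id, .data$year, .data$sample_id,
    .data$species_id, .keep_all = TRUE
  )
  attr(dedup, "n_malformed") <- sum(bad)
  attr(dedup, "n_duplicates") <- nrow(rec) - nrow(dedup)
  dedup
}

#' Drop records earlier than a cutoff year
#'
#' Early survey years (before 1927 by default) are filtered out because very
#' early surveys show artefacts of evolving survey techniques. Records from
#' the cutoff year itself are retained (the rule is "earlier than").
#'
#' @param records Presence-record tibble.
#' @param cutoff_year First retained year (default 1927).
#' @return Filtered tibble; attribute `n_removed` counts dropped records.
#' @export
filter_min_year <- function(records, cutoff_year = 1927) {
  keep <- records$year >= cutoff_year
  out <- records[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

km_per_deg_lat <- 111.32

# spherical-Earth bounding-box area in km^2 (simple local approximation)
bbox_area_km2 <- function(lat, lon) {
  dy <- diff(range(lat)) * km_per_deg_lat
  dx <- diff(range(lon)) * km_per_deg_lat * cos(mean(range(lat)) * pi / 180)
  dx * dy
}

#' Partition spatially extended studies into local communities
#'
#' Studies whose coordinate bounding box exceeds `area_threshold_km2` are
#' split into grid cells of roughly `cell_km` km on a side (fixed-size in km
#' under a local equal-area approximation of latitude/longitude), and each
#' cell becomes its own community; records of a study keep a single
#' community otherwise. This is a simplified stand-in for published spatial
#' partitioning protocols; grid origin is the study's bounding-box corner.
#'
#' @param records Presence-record tibble with `latitude`/`longitude` for any
#'   study exceeding the threshold (such a study with no usable coordinates
#'   is skipped with a warning).
#' @param area_threshold_km2 Bounding-box area above which a study is split
#'   (default 96).
#' @param cell_km Grid cell edge length in km (default 10).
#' @return Records re-labelled with partitioned `community_id`s.
#' @export
partition_grid <- function(records, area_threshold_km2 = 96, cell_km = 10) {
  split_one <- function(df) {
    has_xy <- !is.na(df$latitude) & !is.na(df$longitude)
    if (!any(has_xy)) return(df) # no extent information: keep as one
    lat <- df$latitude[has_xy]
    lon <- df$longitude[has_xy]
    if (bbox_area_km2(lat, lon) <= area_threshold_km2) return(df)
    if (!all(has_xy)) {
      warning("study '", df$study_id[1], "': ", sum(!has_xy),
              " record(s) without coordinates dropped during partitioning",
              call. = FALSE)
      df <- df[has_xy, ]
    }
    lat0 <- min(df$latitude)
    lon0 <- min(df$longitude)
    kx <- km_per_deg_lat * cos(mean(range(df$latitude)) * pi / 180)
    ix <- floor((df$longitude - lon0) * kx / cell_km)
    iy <- floor((df$latitude - lat0) * km_per_deg_lat / cell_km)
    df$community_id <- paste0(df$community_id, "_g", ix, "_", iy)
    df
  }
  grps <- split(records, records$study_id)
  dplyr::bind_rows(lapply(grps, split_one))
}

#' Assemble per-community time series
#'
#' Nests filtered (and, if applicable, partitioned) presence records into
#' one row per community, carrying the observation table and the span of
#' surveyed years. Gap years are preserved as gaps — nothing is imputed;
#' missing years are handled downstream by averaging similarity only over
#' available year pairs.
#'
#' @param records Presence-record tibble.
#' @return Tibble of class `community_series` with columns `community_id`,
#'   `taxon_group`, `first_year`, `last_year`, `n_years`, and the
#'   list-column `obs` (tibbles of `year`, `sample_id`, `species_id`).
#' @export
build_series <- function(records) {
  grp <- split(tibble::as_tibble(records), records$community_id)
  out <- purrr::map2(names(grp), grp, function(cid, g) {
    tibble::tibble(
      community_id = cid,
      taxon_group = g$taxon_group[1],
      first_year = min(g$year),
      last_year = max(g$year),
      n_years = length(unique(g$year)),
      obs = list(tibble::tibble(year = g$year, sample_id = g$sample_id,
                                species_id = g$species_id))
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("community_series", class(out))
  out
}

#' Read an annual climate anomaly series
#'
#' Two-column CSV of (year, value). Years must be strictly consecutive;
#' gaps are an error because the delayed-response filter is a year-by-year
#' recursion.
#'
#' @param path CSV file path; first column year, second the anomaly.
#' @return Tibble with columns `year` (integer) and `value`.
#' @examples
#' # a synthetic global-temperature-anomaly stand-in ships with the package
#' gsat <- read_climate(system.file("extdata", "gsat_synthetic.csv",
#'                                  package = "lagturn"))
#' delayed_series(gsat, delay_years = 10)
#' @export
read_climate <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) stop("climate file needs (year, value) columns",
                          call. = FALSE)
  out <- tibble::tibble(year = as.integer(raw[[1]]),
                        value = as.numeric(raw[[2]]))
  if (any(diff(out$year) != 1)) {
    stop("climate series years must be consecutive (gap after ",
         out$year[which(diff(out$year) != 1)[1]], ")", call. = FALSE)
  }
  out
}
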