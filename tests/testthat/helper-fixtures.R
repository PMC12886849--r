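# Small in-code fixtures shared across test files.

# one community's observations: fully surveyed years, one sample per year,
# composition replacing `shift` species per year from a richness-10 set
rolling_obs <- function(years, richness = 10, shift = 1) {
  dplyr::bind_rows(lapply(seq_along(years), function(i) {
    sp <- seq((i - 1) * shift + 1, length.out = richness)
    tibble::tibble(year = years[i], sample_id = "s1",
                   species_id = sprintf("sp%03d", sp))
  }))
}

# presence records for a point-located study
point_records <- function(study, n = 5, lat = 50, lon = 0, year = 2000) {
  tibble::tibble(
    study_id = study, community_id = study, year = year,
    sample_id = "s1", species_id = sprintf("sp%02d", seq_len(n)),
    latitude = lat + runif(n, 0, 0.001), longitude = lon + runif(n, 0, 0.001),
    taxon_group = "all"
  )
}

# flatten a community_series tibble back into long presence records
ser_to_records <- function(ser) {
  dplyr::bind_rows(purrr::pmap(
    list(ser$community_id, ser$taxon_group, ser$obs),
    function(cid, taxon, obs) {
      dplyr::mutate(obs, study_id = "flat", community_id = cid,
                    latitude = NA_real_, longitude = NA_real_,
                    taxon_group = taxon)
    }
  ))
}

# write a survey CSV in BioTIME-style column names
write_biotime_csv <- function(records, path) {
  out <- data.frame(
    STUDY_ID = records$study_id, YEAR = records$year,
    SAMPLE_DESC = records$sample_id, GENUS_SPECIES = records$species_id,
    LATITUDE = records$latitude, LONGITUDE = records$longitude,
    TAXA = records$taxon_group
  )
  write.csv(out, path, row.names = FALSE)
  path
}
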