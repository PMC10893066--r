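# Small in-code fixtures shared across test files.

make_obs <- function(animal_id, time, value, blq = FALSE,
                     group = "bolus_low", analyte = "plasma_parent",
                     time_unit = "hours", lloq = 0.1) {
  tibble::tibble(animal_id = animal_id, group = group, analyte = analyte,
                 time = time, time_unit = time_unit, value = value,
                 blq = blq, lloq = lloq)
}

make_doses <- function(animal_id, dose_level = 0.3, weight = 0.3,
                       loaded = NA_real_) {
  tibble::tibble(animal_id = animal_id, dose_level_mg_per_kg = dose_level,
                 weight_kg = weight, loaded_dose_mg = loaded)
}

# A tiny valid bolus study: 2 animals x 3 timepoints.
tiny_bolus_study <- function() {
  ids <- paste0("r", 1:6)
  obs <- make_obs(ids, time = rep(c(0.5, 2, 24), each = 2),
                  value = c(10, 12, 6, 7, 0.5, 0.6))
  pk_study(obs, make_doses(ids), design = "sparse_bolus")
}

ref_path <- function(file) {
  system.file("extdata", file, package = "implantpk", mustWork = TRUE)
}
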