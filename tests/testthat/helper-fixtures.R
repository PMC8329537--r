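# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small clean (error-free) bundle shared across caller/pipeline tests.
small_clean_bundle <- function() {
  cached("small_clean_bundle", function() {
    generate_dataset(sim_config(
      n_founders = 40, n_generations = 3, markers_per_chrom = 300,
      genotyping_error_rate = 0, missing_rate = 0, seed = 5
    ))
  })
}

# Seven-animal toy pedigree: two founder grandparents, a founder sire,
# one dam with known parents, two of her calves, and one calf of a
# founder dam (no genotyped grandparent -> never a family).
toy_pedigree <- function() {
  tibble::tibble(
    animal_id = c("GS", "GD", "SIRE", "DAM", "C1", "C2", "C3"),
    sire_id   = c(NA, NA, NA, "GS", "SIRE", "SIRE", "SIRE"),
    dam_id    = c(NA, NA, NA, "GD", "DAM", "DAM", "GD"),
    sex       = c("M", "F", "M", "F", "F", "M", "F"),
    birth_date = as.Date("2000-01-01") + c(0, 0, 0, 400, 1200, 1600, 900),
    farm_id = "FARM01",
    chip_class = "GGP-50K"
  )
}

# Independent brute-force family enumeration: loop over every
# (dam, offspring) pair and check the genotyping pattern directly.
brute_force_families <- function(pedigree, genotyped) {
  out <- list()
  for (i in seq_len(nrow(pedigree))) {
    off <- pedigree$animal_id[i]
    dam <- pedigree$dam_id[i]
    if (is.na(dam) || !(off %in% genotyped) || !(dam %in% genotyped)) next
    j <- which(pedigree$animal_id == dam)
    if (length(j) != 1) next
    gs <- pedigree$sire_id[j]
    gd <- pedigree$dam_id[j]
    gs_ok <- !is.na(gs) && gs %in% genotyped
    gd_ok <- !is.na(gd) && gd %in% genotyped
    if (!gs_ok && !gd_ok) next
    out[[length(out) + 1]] <- data.frame(dam_id = dam, offspring_id = off)
  }
  do.call(rbind, out)
}

# Alleles a grandparent with dosage g (NA = missing) can have transmitted.
transmissible <- function(g) {
  if (is.na(g)) c(0L, 1L) else unique(c(if (g <= 1) 0L, if (g >= 1) 1L))
}
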