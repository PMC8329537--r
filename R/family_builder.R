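#' Extract three-generation families from a genotyped pedigree
#'
#' A three-generation family is the unit in which one maternal meiosis is
#' observable: a genotyped offspring (generation 1), its genotyped dam
#' (generation 2, the focal parent whose meiosis is phenotyped), and at
#' least one genotyped grandparent of the dam (generation 3). The
#' offspring's sire is kept when present (and used only to resolve
#' transmitted alleles); families sharing a dam are separate meioses.
#'
#' @param pedigree Tibble with `animal_id`, `sire_id`, `dam_id` (and any
#'   further columns); must be acyclic.
#' @param genotyped_ids Character vector of genotyped animal ids.
#' @return A tibble, one row per (dam, offspring) meiosis: `family_id`,
#'   `offspring_id`, `dam_id`, `sire_id`, `grandsire_id`, `granddam_id`,
#'   with the grandparent ids set to `NA` when ungenotyped (they are then
#'   not used for phasing).
#' @export
extract_three_gen_families <- function(pedigree, genotyped_ids) {
  if (nrow(pedigree) == 0) {
    return(tibble::tibble(family_id = character(), offspring_id = character(),
                          dam_id = character(), sire_id = character(),
                          grandsire_id = character(),
                          granddam_id = character()))
  }
  assert_pedigree_acyclic(pedigree)
  g <- function(id) !is.na(id) & id %in% genotyped_ids
  dams <- dplyr::select(pedigree, dam_of = "animal_id",
                        grandsire_id = "sire_id", granddam_id = "dam_id")
  fam <- pedigree |>
    dplyr::select(offspring_id = "animal_id", dam_id = "dam_id",
                  sire_id = "sire_id") |>
    dplyr::inner_join(dams, by = c("dam_id" = "dam_of")) |>
    dplyr::mutate(
      grandsire_id = ifelse(g(.data$grandsire_id), .data$grandsire_id,
                            NA_character_),
      granddam_id = ifelse(g(.data$granddam_id), .data$granddam_id,
                           NA_character_)
    ) |>
    dplyr::filter(
      g(.data$offspring_id), g(.data$dam_id),
      !is.na(.data$grandsire_id) | !is.na(.data$granddam_id)
    )
  fam$sire_id <- ifelse(g(fam$sire_id), fam$sire_id, NA_character_)
  fam$family_id <- sprintf("%s|%s", fam$dam_id, fam$offspring_id)
  dplyr::select(fam, "family_id", "offspring_id", "dam_id", "sire_id",
                "grandsire_id", "granddam_id")
}

#' Filter families by SNP panel density
#'
#' Retains families whose genotyped members (offspring, dam, genotyped
#' grandparents, and the sire when genotyped) were all typed on chips with
#' at least `min_marker_count` markers. Default threshold 50,000 (the
#' "at least 50K chip" rule).
#'
#' @param families Tibble from [extract_three_gen_families()].
#' @param pedigree Pedigree tibble carrying `animal_id` and `chip_class`.
#' @param chip_sizes Named integer vector mapping chip-class labels to
#'   marker counts; an unknown label in the pedigree is an error.
#' @param min_marker_count Minimum marker count (default 50000).
#' @return The filtered family tibble.
#' @export
filter_by_panel <- function(families, pedigree, chip_sizes,
                            min_marker_count = 50000) {
  lab <- stats::setNames(pedigree$chip_class, pedigree$animal_id)
  used <- unique(stats::na.omit(lab[unlist(families[, c(
    "offspring_id", "dam_id", "sire_id", "grandsire_id", "granddam_id")],
    use.names = FALSE)]))
  unknown <- setdiff(used, names(chip_sizes))
  if (length(unknown)) {
    stop("unknown chip_class label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  size_of <- function(id) {
    out <- rep(NA_real_, length(id))
    ok <- !is.na(id)
    out[ok] <- chip_sizes[lab[id[ok]]]
    out
  }
  dense <- function(id) is.na(id) | size_of(id) >= min_marker_count
  keep <- dense(families$offspring_id) & dense(families$dam_id) &
    dense(families$sire_id) & dense(families$grandsire_id) &
    dense(families$granddam_id)
  families[keep, , drop = FALSE]
}
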