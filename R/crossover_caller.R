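#' Phase a focal parent's haplotypes by grandparental origin
#'
#' Single-pass Mendelian deduction. At each marker the dam's two alleles
#' must partition into one transmitted by her sire (grandpaternal) and one
#' by her dam (grandmaternal). A genotype `g` restricts the alleles a
#' grandparent can have transmitted (hom -> that allele; het or missing ->
#' either), and at heterozygous sites the assignment `(gp, gm)` is phased
#' when exactly one of the two orderings is compatible. Sites where no
#' ordering is compatible are Mendelian inconsistencies: they are set
#' phase-unknown and counted, never fatal.
#'
#' @param dam_geno Integer dosage vector (0/1/2, `NA` missing) of the dam.
#' @param grandsire_geno,granddam_geno Dosage vectors of the dam's parents,
#'   or `NULL` when ungenotyped.
#' @return A tibble, one row per marker: `gp_allele`, `gm_allele` (0/1 or
#'   `NA`), `het` (dam heterozygous), `phase_known` (origin resolved at a
#'   het site), `inconsistent` (Mendelian conflict).
#' @export
#' @examples
#' # dam het, grandsire hom alt -> grandpaternal allele is the alt allele
#' phase_parent(1L, 2L, NULL)
phase_parent <- function(dam_geno, grandsire_geno = NULL,
                         granddam_geno = NULL) {
  m <- length(dam_geno)
  if (is.null(grandsire_geno)) grandsire_geno <- rep(NA_integer_, m)
  if (is.null(granddam_geno)) granddam_geno <- rep(NA_integer_, m)
  stopifnot(length(grandsire_geno) == m, length(granddam_geno) == m)

  # can grandparent with genotype g have transmitted allele a?
  can0 <- function(g) is.na(g) | g <= 1L
  can1 <- function(g) is.na(g) | g >= 1L

  het <- !is.na(dam_geno) & dam_geno == 1L
  gp <- gm <- rep(NA_integer_, m)
  phase_known <- rep(FALSE, m)
  inconsistent <- rep(FALSE, m)

  # heterozygous: orderings (gp,gm) = (0,1) or (1,0)
  ok01 <- can0(grandsire_geno) & can1(granddam_geno)
  ok10 <- can1(grandsire_geno) & can0(granddam_geno)
  set01 <- het & ok01 & !ok10
  set10 <- het & ok10 & !ok01
  gp[set01] <- 0L; gm[set01] <- 1L
  gp[set10] <- 1L; gm[set10] <- 0L
  phase_known[set01 | set10] <- TRUE
  inconsistent[het & !ok01 & !ok10] <- TRUE

  # homozygous: both alleles equal; check transmissibility from each side
  hom0 <- !is.na(dam_geno) & dam_geno == 0L
  hom2 <- !is.na(dam_geno) & dam_geno == 2L
  gp[hom0] <- gm[hom0] <- 0L
  gp[hom2] <- gm[hom2] <- 1L
  bad_hom <- (hom0 & !(can0(grandsire_geno) & can0(granddam_geno))) |
    (hom2 & !(can1(grandsire_geno) & can1(granddam_geno)))
  gp[bad_hom] <- gm[bad_hom] <- NA_integer_
  inconsistent[bad_hom] <- TRUE

  tibble::tibble(gp_allele = gp, gm_allele = gm, het = het,
                 phase_known = phase_known, inconsistent = inconsistent)
}

#' Identify informative sites and the transmitted maternal allele
#'
#' A site is informative when the dam is heterozygous with known phase and
#' the allele she transmitted to the offspring is determinable: the
#' offspring is homozygous, or heterozygous with the other parent
#' homozygous (resolving each parent's contribution). Offspring genotypes
#' that are Mendelian-impossible given the sire are flagged and excluded.
#'
#' @param phased Tibble from [phase_parent()].
#' @param offspring_geno Offspring dosage vector.
#' @param sire_geno Dosage vector of the offspring's other parent, or
#'   `NULL` when ungenotyped.
#' @return A tibble per marker: `informative`, `transmitted` (0/1 allele
#'   the dam passed, `NA` when ambiguous), `inconsistent`.
#' @export
informative_sites <- function(phased, offspring_geno, sire_geno = NULL) {
  m <- nrow(phased)
  if (is.null(sire_geno)) sire_geno <- rep(NA_integer_, m)
  stopifnot(length(offspring_geno) == m, length(sire_geno) == m)

  transmitted <- rep(NA_integer_, m)
  inconsistent <- rep(FALSE, m)
  o0 <- !is.na(offspring_geno) & offspring_geno == 0L
  o1 <- !is.na(offspring_geno) & offspring_geno == 1L
  o2 <- !is.na(offspring_geno) & offspring_geno == 2L
  s_hom0 <- !is.na(sire_geno) & sire_geno == 0L
  s_hom2 <- !is.na(sire_geno) & sire_geno == 2L

  transmitted[o0] <- 0L
  transmitted[o2] <- 1L
  transmitted[o1 & s_hom0] <- 1L
  transmitted[o1 & s_hom2] <- 0L
  # sire cannot have contributed the required allele
  bad <- (o0 & s_hom2) | (o2 & s_hom0)
  transmitted[bad] <- NA_integer_
  inconsistent[bad] <- TRUE

  informative <- phased$het & phased$phase_known & !is.na(transmitted) &
    !inconsistent & !phased$inconsistent
  tibble::tibble(informative = informative, transmitted = transmitted,
                 inconsistent = inconsistent)
}

#' Trace the grandparental origin of the transmitted haplotype
#'
#' At every informative site the transmitted allele matches exactly one of
#' the dam's phased alleles; the site is labelled with the grandparental
#' haplotype carrying it. Sites whose transmitted allele matches neither
#' phased allele (possible only through genotyping error) are dropped and
#' counted.
#'
#' @param phased Tibble from [phase_parent()].
#' @param info Tibble from [informative_sites()].
#' @param map Marker map aligned with `phased` (columns `chrom`, `pos`).
#' @return A tibble of informative sites: `marker`, `chrom`, `pos`,
#'   `origin` (`"GP"` grandpaternal / `"GM"` grandmaternal), with a
#'   `dropped` attribute counting mismatching sites.
#' @export
trace_origin <- function(phased, info, map) {
  sel <- which(info$informative)
  tr <- info$transmitted[sel]
  gp <- phased$gp_allele[sel]
  gm <- phased$gm_allele[sel]
  origin <- ifelse(tr == gp, "GP", ifelse(tr == gm, "GM", NA_character_))
  keep <- !is.na(origin)
  out <- tibble::tibble(marker = sel[keep], chrom = map$chrom[sel][keep],
                        pos = map$pos[sel][keep], origin = origin[keep])
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Call crossovers from an origin vector
#'
#' One crossover event per adjacent pair of informative markers with
#' different grandparental origins, localized to the 0-based half-open
#' interval `[left_bp, right_bp)` between the two flanking informative
#' SNPs; the per-chromosome count is the number of origin switches.
#'
#' @param origin Tibble from [trace_origin()] (sorted by chromosome and
#'   position).
#' @return A tibble of events: `chrom`, `left_bp`, `right_bp`.
#' @export
#' @examples
#' ov <- tibble::tibble(marker = 1:5, chrom = "chr1",
#'                      pos = c(10, 20, 30, 40, 50) * 1L,
#'                      origin = c("GP", "GP", "GM", "GM", "GM"))
#' call_crossovers(ov) # one event in [20, 30)
call_crossovers <- function(origin) {
  if (nrow(origin) == 0) {
    return(tibble::tibble(chrom = character(), left_bp = numeric(),
                          right_bp = numeric()))
  }
  origin |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe({
      o <- .data$origin
      p <- .data$pos
      sw <- which(o[-1] != o[-length(o)])
      tibble::tibble(left_bp = p[sw], right_bp = p[sw + 1])
    }) |>
    dplyr::ungroup()
}

#' Remove markers inside masked regions
#'
#' Drops markers falling in any of a set of excluded (problematic)
#' regions, given as 0-based half-open intervals per chromosome, before
#' phasing and calling.
#'
#' @param map Marker map tibble (`chrom`, `pos`, ...).
#' @param mask Tibble `chrom`, `start`, `end` (0-based half-open), or
#'   `NULL`/empty for no masking.
#' @return The filtered map.
#' @export
apply_region_mask <- function(map, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(map)
  if (any(mask$start >= mask$end)) {
    stop("malformed mask interval: start must be < end", call. = FALSE)
  }
  hit <- rep(FALSE, nrow(map))
  for (i in seq_len(nrow(mask))) {
    hit <- hit | (map$chrom == mask$chrom[i] & map$pos >= mask$start[i] &
                    map$pos < mask$end[i])
  }
  map[!hit, , drop = FALSE]
}

#' Drop meioses exceeding the genome-wide crossover cap
#'
#' Removes records with more than `max_count` genome-wide crossovers
#' (default 45), the standard guard against residual genotyping or
#' pedigree errors inflating counts.
#'
#' @param records Tibble with a crossover-count column `R`.
#' @param max_count Cap; records with `R > max_count` are removed.
#' @return The filtered records.
#' @export
#' @examples
#' qc_filter_meioses(tibble::tibble(R = c(46, 45, 23)))$R # 45 23
qc_filter_meioses <- function(records, max_count = 45) {
  records[records$R <= max_count, , drop = FALSE]
}

#' Call maternal crossovers for one three-generation family
#'
#' Runs the full per-family chain: phase the dam against her genotyped
#' parents, determine informative sites and transmitted alleles from the
#' offspring (and its sire when genotyped), trace grandparental origin,
#' and call crossovers per chromosome.
#'
#' @param family One row of the family tibble from
#'   [extract_three_gen_families()].
#' @param genotypes Integer dosage matrix (markers x animals) with column
#'   names equal to animal ids, aligned with `map` rows.
#' @param map Marker map tibble.
#' @return List: `events` (tibble `chrom`, `left_bp`, `right_bp`),
#'   `record` (one-row tibble with `dam_id`, `offspring_id`, `R`,
#'   `informative_n`, `n_inconsistent`, `n_dropped`).
#' @export
call_family_crossovers <- function(family, genotypes, map) {
  geno_of <- function(id) {
    if (is.na(id) || !id %in% colnames(genotypes)) NULL
    else genotypes[, id]
  }
  phased <- phase_parent(genotypes[, family$dam_id],
                         geno_of(family$grandsire_id),
                         geno_of(family$granddam_id))
  info <- informative_sites(phased, genotypes[, family$offspring_id],
                            geno_of(family$sire_id))
  ov <- trace_origin(phased, info, map)
  events <- call_crossovers(ov)
  record <- tibble::tibble(
    dam_id = family$dam_id,
    offspring_id = family$offspring_id,
    R = nrow(events),
    informative_n = nrow(ov),
    n_inconsistent = sum(phased$inconsistent) + sum(info$inconsistent),
    n_dropped = attr(ov, "dropped")
  )
  list(events = events, record = record)
}

#' Call maternal crossovers for a set of families
#'
#' Applies the region mask, calls every family, and drops families whose
#' per-site Mendelian-inconsistency rate exceeds `max_inconsistency`
#' (symptomatic of pedigree or genotyping error).
#'
#' @param families Family tibble from [extract_three_gen_families()].
#' @param genotypes Dosage matrix (markers x animals).
#' @param map Marker map aligned with the genotype rows.
#' @param mask Optional excluded-region tibble for [apply_region_mask()].
#' @param max_inconsistency Maximum tolerated fraction of inconsistent
#'   sites per family (default 0.02).
#' @param chip_classes Optional named vector `animal_id -> chip_class` to
#'   carry the dam's chip class onto the records.
#' @return List: `records` (one row per retained meiosis), `events`
#'   (all events with `family_id`), `n_dropped_families`.
#' @export
call_pedigree_crossovers <- function(families, genotypes, map, mask = NULL,
                                     max_inconsistency = 0.02,
                                     chip_classes = NULL) {
  if (!is.null(mask)) {
    map_keep <- apply_region_mask(map, mask)
    genotypes <- genotypes[match(map_keep$marker_id, map$marker_id), ,
                           drop = FALSE]
    map <- map_keep
  }
  calls <- purrr::map(seq_len(nrow(families)), function(i) {
    call_family_crossovers(families[i, ], genotypes, map)
  })
  records <- dplyr::bind_rows(purrr::map(calls, "record"))
  records$family_id <- families$family_id
  rate <- records$n_inconsistent / nrow(map)
  keep <- rate <= max_inconsistency
  events <- dplyr::bind_rows(
    purrr::map(which(keep), function(i) {
      ev <- calls[[i]]$events
      if (nrow(ev)) ev$family_id <- families$family_id[i]
      ev
    })
  )
  records <- records[keep, , drop = FALSE]
  if (!is.null(chip_classes)) {
    records$chip_class <- unname(chip_classes[records$dam_id])
  }
  list(records = records, events = events,
       n_dropped_families = sum(!keep))
}
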