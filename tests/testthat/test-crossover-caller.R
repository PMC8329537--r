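# Independent Mendelian deduction oracle over all trio genotype
# combinations: enumerate the ordered assignments (grandpaternal,
# grandmaternal) compatible with what each grandparent can transmit.
phase_oracle <- function(dam, gs, gd) {
  if (is.na(dam)) return(list(known = FALSE, inconsistent = FALSE))
  cand <- list()
  for (gp in transmissible(gs)) {
    for (gm in transmissible(gd)) {
      if (gp + gm == dam) cand[[length(cand) + 1]] <- c(gp, gm)
    }
  }
  cand <- unique(cand)
  if (length(cand) == 0) return(list(known = FALSE, inconsistent = TRUE))
  if (dam == 1 && length(cand) == 1) {
    return(list(known = TRUE, gp = cand[[1]][1], gm = cand[[1]][2],
                inconsistent = FALSE))
  }
  list(known = dam != 1, inconsistent = FALSE)
}

test_that("phasing matches the Mendelian deduction oracle on every trio combination", {
  states <- c(0L, 1L, 2L, NA_integer_)
  combos <- expand.grid(dam = states, gs = states, gd = states)
  ph <- phase_parent(combos$dam, combos$gs, combos$gd)
  for (i in seq_len(nrow(combos))) {
    oracle <- phase_oracle(combos$dam[i], combos$gs[i], combos$gd[i])
    lab <- paste(combos[i, ], collapse = "/")
    expect_equal(ph$inconsistent[i], oracle$inconsistent, label = lab)
    if (!is.na(combos$dam[i]) && combos$dam[i] == 1L) {
      expect_equal(ph$phase_known[i],
                   isTRUE(oracle$known) && !oracle$inconsistent, label = lab)
      if (isTRUE(oracle$known) && !oracle$inconsistent) {
        expect_equal(ph$gp_allele[i], oracle$gp, label = lab)
        expect_equal(ph$gm_allele[i], oracle$gm, label = lab)
      }
    }
  }
})

test_that("phasing examples: hom-alt grandsire resolves phase; triple hets do not", {
  # dam het, grandsire hom alt -> grandpaternal allele is alt
  ph <- phase_parent(1L, 2L, NULL)
  expect_true(ph$phase_known)
  expect_equal(ph$gp_allele, 1L)
  expect_equal(ph$gm_allele, 0L)
  # dam homozygous: alleles equal, never an informative site
  ph <- phase_parent(2L, 1L, 1L)
  expect_false(ph$het)
  expect_equal(ph$gp_allele, ph$gm_allele)
  # everyone heterozygous: deduction impossible
  ph <- phase_parent(1L, 1L, 1L)
  expect_false(ph$phase_known)
})

# Transmission oracle: which dam allele(s) are consistent with the
# offspring genotype given what the sire can transmit?
transmitted_oracle <- function(off, sire) {
  if (is.na(off)) return(NA_integer_)
  ok <- unique(unlist(lapply(c(0L, 1L), function(dt) {
    for (st in transmissible(sire)) if (dt + st == off) return(dt)
    NULL
  })))
  if (length(ok) == 1) ok else NA_integer_
}

test_that("informative sites match the transmission deduction oracle", {
  states <- c(0L, 1L, 2L, NA_integer_)
  combos <- expand.grid(off = states, sire = states)
  phased_het <- phase_parent(rep(1L, nrow(combos)),
                             rep(0L, nrow(combos)), NULL) # phased het dam
  info <- informative_sites(phased_het, combos$off, combos$sire)
  for (i in seq_len(nrow(combos))) {
    lab <- paste(combos[i, ], collapse = "/")
    oracle <- transmitted_oracle(combos$off[i], combos$sire[i])
    if (info$inconsistent[i]) {
      # sire cannot have contributed its required allele
      expect_true(combos$off[i] %in% c(0L, 2L), label = lab)
      expect_false(info$informative[i], label = lab)
    } else {
      expect_equal(info$transmitted[i], oracle, label = lab)
      expect_equal(info$informative[i], !is.na(oracle), label = lab)
    }
  }
})

test_that("unphased or homozygous dam sites are never informative", {
  ph_unphased <- phase_parent(1L, 1L, 1L)
  expect_false(informative_sites(ph_unphased, 0L, NULL)$informative)
  ph_hom <- phase_parent(0L, 0L, 0L)
  expect_false(informative_sites(ph_hom, 0L, NULL)$informative)
})

test_that("origin tracing and switch counting follow the site-wise oracle", {
  map <- tibble::tibble(marker_id = sprintf("m%d", 1:5), chrom = "chr1",
                        pos = c(100L, 200L, 300L, 400L, 500L))
  ph <- phase_parent(rep(1L, 5), rep(0L, 5), NULL) # gp = 0, gm = 1
  # transmitted alleles 0,0,1,1,1 -> origins GP,GP,GM,GM,GM -> 1 switch
  info <- informative_sites(ph, c(0L, 0L, 2L, 2L, 2L), NULL)
  ov <- trace_origin(ph, info, map)
  expect_equal(ov$origin, c("GP", "GP", "GM", "GM", "GM"))
  ev <- call_crossovers(ov)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$left_bp, 200)
  expect_equal(ev$right_bp, 300)
  # constant origins -> no events; alternating -> 2 events
  info2 <- informative_sites(ph, rep(0L, 5), NULL)
  expect_equal(nrow(call_crossovers(trace_origin(ph, info2, map))), 0)
  info3 <- informative_sites(ph, c(0L, 2L, 0L, 0L, 0L), NULL)
  expect_equal(nrow(call_crossovers(trace_origin(ph, info3, map))), 2)
  # zero informative sites -> empty vector, zero events
  ov0 <- trace_origin(ph, informative_sites(ph, rep(NA_integer_, 5), NULL), map)
  expect_equal(nrow(ov0), 0)
  expect_equal(nrow(call_crossovers(ov0)), 0)
})

test_that("region mask removes exactly the markers inside intervals", {
  map <- tibble::tibble(marker_id = sprintf("m%d", 1:10), chrom = "chr1",
                        pos = seq(0L, 90L, by = 10L))
  expect_identical(apply_region_mask(map, NULL), map)
  expect_identical(apply_region_mask(map, tibble::tibble(chrom = character(),
                                                         start = integer(),
                                                         end = integer())),
                   map)
  # half-open [20, 50) covers markers at 20, 30, 40
  masked <- apply_region_mask(map, tibble::tibble(chrom = "chr1",
                                                  start = 20L, end = 50L))
  expect_equal(masked$pos, c(0L, 10L, seq(50L, 90L, 10L)))
  # whole-chromosome mask empties it
  expect_equal(nrow(apply_region_mask(map, tibble::tibble(chrom = "chr1",
                                                          start = 0L,
                                                          end = 100L))), 0)
  expect_error(apply_region_mask(map, tibble::tibble(chrom = "chr1",
                                                     start = 5L, end = 5L)),
               "malformed")
})

test_that("the 45-crossover cap keeps counts at or below the cap", {
  rec <- tibble::tibble(R = c(46, 45, 23))
  expect_equal(qc_filter_meioses(rec)$R, c(45, 23))
  expect_equal(qc_filter_meioses(rec, max_count = Inf)$R, rec$R)
  expect_equal(qc_filter_meioses(tibble::tibble(R = c(10, 45)))$R, c(10, 45))
})

test_that("called counts equal the truth-parity oracle on clean data", {
  b <- small_clean_bundle()
  fam <- extract_three_gen_families(b$pedigree, colnames(b$genotypes))
  fam <- fam[1:40, ]
  for (i in seq_len(nrow(fam))) {
    f <- fam[i, ]
    ph <- phase_parent(b$genotypes[, f$dam_id],
                       if (!is.na(f$grandsire_id)) b$genotypes[, f$grandsire_id],
                       if (!is.na(f$granddam_id)) b$genotypes[, f$granddam_id])
    info <- informative_sites(ph, b$genotypes[, f$offspring_id],
                              if (!is.na(f$sire_id)) b$genotypes[, f$sire_id])
    ov <- trace_origin(ph, info, b$map)
    ev <- call_crossovers(ov)
    tp <- b$positions[b$positions$meiosis_id == f$family_id, ]
    for (ch in unique(b$map$chrom)) {
      p <- ov$pos[ov$chrom == ch]
      xo <- tp$pos_bp[tp$chrom == ch]
      oracle <- if (length(p) < 2) 0 else {
        cnt <- vapply(seq_len(length(p) - 1), function(k)
          sum(xo > p[k] & xo <= p[k + 1]), numeric(1))
        sum(cnt %% 2 == 1)
      }
      expect_equal(sum(ev$chrom == ch), oracle)
    }
  }
})

test_that("calling is invariant to marker shuffling after canonical sorting", {
  b <- small_clean_bundle()
  fam <- extract_three_gen_families(b$pedigree, colnames(b$genotypes))[1, ]
  perm <- sample(nrow(b$map))
  map_shuf <- b$map[perm, ]
  geno_shuf <- b$genotypes[perm, ]
  ord <- order(map_shuf$chrom, map_shuf$pos)
  r1 <- call_family_crossovers(fam, b$genotypes, b$map)
  r2 <- call_family_crossovers(fam, geno_shuf[ord, ], map_shuf[ord, ])
  expect_equal(r1$record$R, r2$record$R)
  expect_equal(r1$events$left_bp, r2$events$left_bp)
})

test_that("zero simulated crossovers imply zero called events", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chrom = 100, seed = 19)
  map <- make_marker_map(cfg)
  set.seed(20)
  m <- nrow(map)
  gs_h <- rbinom(m, 1, 0.5); gd_h <- rbinom(m, 1, 0.5)
  dam_gp <- gs_h                      # dam's grandpaternal haplotype
  dam_gm <- gd_h
  off_mat <- simulate_meiosis(dam_gp, dam_gm, 0L, map)$gamete
  geno <- cbind(GS = 2L * gs_h, GD = 2L * gd_h, DAM = dam_gp + dam_gm,
                SIRE = rep(0L, m), OFF = off_mat + 0L)
  rownames(geno) <- map$marker_id
  fam <- tibble::tibble(family_id = "DAM|OFF", offspring_id = "OFF",
                        dam_id = "DAM", sire_id = "SIRE",
                        grandsire_id = "GS", granddam_id = "GD")
  res <- call_family_crossovers(fam, geno, map)
  expect_equal(res$record$R, 0)
  expect_gt(res$record$informative_n, 0)
})
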