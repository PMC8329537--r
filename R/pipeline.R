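#' Default pipeline configuration
#'
#' Returns the declarative run configuration with every analysis constant
#' surfaced as a key: panel-density threshold (50,000 markers), genome-wide
#' crossover cap (45), temperature cutoffs (26.67 / 4.44 degrees C), age
#' bins (20 months + 10-month increments), and the per-family Mendelian
#' inconsistency tolerance. Values can be overridden by a YAML file or an
#' override list.
#'
#' @param overrides Named list merged over the defaults (one level deep).
#' @return A named list.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    seed = 2026L,
    out_dir = NULL,
    simulate = TRUE,
    sim = list(),                 # overrides for sim_config()
    pedigree_csv = NULL,
    genotypes_vcf = NULL,
    temperature_csv = NULL,
    mask_bed = NULL,
    min_marker_count = 50000,
    max_crossovers = 45,
    hot_c = 26.67,
    cold_c = 4.44,
    max_inconsistency = 0.02,
    use_temperature = TRUE,
    fit_model = TRUE,
    chip_sizes = NULL             # defaults to the sim config's classes
  )
  utils::modifyList(cfg, overrides)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> family extraction -> crossover calling
#' -> covariates -> mixed model -> summaries, collecting per-stage record
#' counts in a manifest. With an `out_dir` every stage artifact is written
#' (CSV/JSON); partial outputs written before a failing stage are
#' preserved.
#'
#' @param config A list from [pipeline_config()], or a path to a YAML file
#'   with the same keys.
#' @return A list of class `recomb_run`: `families`, `records` (QC-passed
#'   meioses with covariates and residual `Y`), `events`, `fit`
#'   (`recomb_fit` or `NULL`), `spline`, `age_groups`, `temp_groups`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config(yaml::read_yaml(config))
  out_dir <- config$out_dir
  emit <- function(x, file) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      readr::write_csv(x, file.path(out_dir, file))
    }
  }
  digests <- character(0)

  if (isTRUE(config$simulate)) {
    bundle <- stage("simulate", {
      sim <- do.call(sim_config, utils::modifyList(
        list(seed = config$seed), config$sim))
      generate_dataset(sim)
    })
    ped <- bundle$pedigree
    geno <- bundle$genotypes
    map <- bundle$map
    temps <- if (isTRUE(config$use_temperature)) bundle$temperature else NULL
    chip_sizes <- bundle$config$chip_classes
  } else {
    loaded <- stage("load-inputs", {
      for (f in c("pedigree_csv", "genotypes_vcf")) {
        if (is.null(config[[f]])) stop("missing required input path: ", f)
      }
      if (isTRUE(config$use_temperature) && is.null(config$temperature_csv)) {
        stop("temperature stage enabled but temperature_csv not given")
      }
      vcf <- read_genotypes_vcf(config$genotypes_vcf)
      files <- unlist(config[c("pedigree_csv", "genotypes_vcf",
                               "temperature_csv", "mask_bed")])
      list(ped = read_pedigree_csv(config$pedigree_csv),
           geno = vcf$genotypes, map = vcf$map,
           temps = if (isTRUE(config$use_temperature))
             read_temperature_csv(config$temperature_csv),
           digests = tools::md5sum(files))
    })
    ped <- loaded$ped
    geno <- loaded$geno
    map <- loaded$map
    temps <- loaded$temps
    digests <- loaded$digests
    chip_sizes <- config$chip_sizes %||% sim_config()$chip_classes
  }
  mask <- if (!is.null(config$mask_bed)) read_region_mask(config$mask_bed)

  fam_all <- stage("families", extract_three_gen_families(ped, colnames(geno)))
  families <- stage("families",
                    filter_by_panel(fam_all, ped, chip_sizes,
                                    config$min_marker_count))
  emit(families, "families.csv")

  called <- stage("call", {
    call_pedigree_crossovers(
      families, geno, map, mask = mask,
      max_inconsistency = config$max_inconsistency,
      chip_classes = stats::setNames(ped$chip_class, ped$animal_id))
  })
  n_called <- nrow(called$records)
  records <- qc_filter_meioses(called$records, config$max_crossovers)
  emit(called$events, "events.csv")
  emit(records, "meioses.csv")

  records <- stage("covariates", {
    out <- build_covariates(records, ped, temps,
                            hot = config$hot_c, cold = config$cold_c)
    adjust_rate(out)
  })
  emit(records, "analysis_table.csv")

  fit <- NULL
  spline <- NULL
  age_groups <- NULL
  temp_groups <- NULL
  if (isTRUE(config$fit_model)) {
    fit <- stage("model", {
      dams <- unique(records$dam_id)
      grm <- compute_grm(t(geno[, dams, drop = FALSE]))
      d <- dplyr::rename(records, parent_id = "dam_id")
      fit_mixed_model(d, grm,
                      use_temperature = isTRUE(config$use_temperature))
    })
    spline <- stage("summaries", {
      if (length(unique(records$A)) >= 10) fit_age_spline(records$Y,
                                                          records$A)
    })
    age_groups <- group_summary(records$Y, age_group(records$A))
    if (isTRUE(config$use_temperature)) {
      temp_groups <- temp_group_summary(records$Y, records$T1)
      emit(temp_groups, "temp_groups.csv")
    }
    emit(age_groups, "age_groups.csv")
    if (!is.null(spline)) emit(spline$grid, "spline_grid.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("recombinr")),
    seed = config$seed,
    simulate = isTRUE(config$simulate),
    input_digests = as.list(digests),
    counts = list(
      animals = nrow(ped),
      genotyped = ncol(geno),
      families_extracted = nrow(fam_all),
      families_after_panel = nrow(families),
      families_dropped_inconsistency = called$n_dropped_families,
      meioses_called = n_called,
      meioses_after_qc = nrow(records),
      records_with_temperature = if ("temp_complete" %in% names(records))
        sum(records$temp_complete) else 0L
    )
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(fit)) {
      jsonlite::write_json(
        list(coefficients = tidy(fit), variance = as.list(glance(fit))),
        file.path(out_dir, "model_report.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }

  structure(list(
    families = families, records = records, events = called$events,
    fit = fit, spline = spline, age_groups = age_groups,
    temp_groups = temp_groups, manifest = manifest, config = config
  ), class = "recomb_run")
}

#' Assemble the run report
#'
#' Collects the display artifacts of a completed run: the coefficient
#' table (the eight fixed-effect factors when temperature terms were
#' fitted), variance components and heritability, the age spline grid,
#' the age-group summary, and the temperature boxplot statistics. Runs
#' without the temperature stage omit the temperature rows with a note.
#'
#' @param run A `recomb_run` from [run_pipeline()].
#' @return A list of class `recomb_report`.
#' @export
make_report <- function(run) {
  stopifnot(inherits(run, "recomb_run"))
  if (is.null(run$fit)) {
    stop("model stage did not run; no report can be assembled",
         call. = FALSE)
  }
  coefs <- dplyr::filter(tidy(run$fit), .data$term != "(Intercept)")
  notes <- character(0)
  if (!run$fit$use_temperature) {
    notes <- "temperature stage disabled: T1/T2 rows omitted"
  }
  structure(list(
    factors = coefs,
    variance = glance(run$fit),
    spline_grid = if (!is.null(run$spline)) run$spline$grid,
    argmin_age = if (!is.null(run$spline)) run$spline$argmin_age,
    age_groups = run$age_groups,
    temp_groups = run$temp_groups,
    counts = run$manifest$counts,
    notes = notes
  ), class = "recomb_report")
}

#' @export
print.recomb_report <- function(x, ...) {
  cat("<recomb_report>\n")
  print(x$factors)
  cat(sprintf("  h2 = %.3f (SE %.3f)\n", x$variance$h2, x$variance$h2_se))
  if (!is.null(x$argmin_age)) {
    cat(sprintf("  age spline minimum: %.0f months\n", x$argmin_age))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
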