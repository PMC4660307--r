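#' Configuration for the full social-structure analysis pipeline
#'
#' Bundles everything [run_pipeline()] needs: the data source (a synthetic
#' scenario or CSV paths), the inclusion filter, permutation settings, and
#' output location. Comparison definitions mirror the study design: within-
#' vs between-class tests per sex, male-male class comparisons, male-female
#' blocks, male clustering, and SLAR model fitting per male class.
#'
#' @param scenario synthetic scenario name (see [scenario_config()]), or
#'   NULL when reading files.
#' @param sightings_path,attributes_path,calf_path input CSVs (ignored when
#'   `scenario` is given).
#' @param min_days,min_years inclusion filter thresholds.
#' @param indices association indices to analyse.
#' @param n_permutations permutations for the CV test and the class tests.
#' @param flips flips per permutation in the CV test.
#' @param n_randomizations randomizations for the mean-difference tests.
#' @param slar_bins,slar_blocks SLAR binning and jackknife blocks.
#' @param out_dir output directory for artifacts.
#' @param seed master seed; each stochastic stage derives its own seed from
#'   it and records it in the stage artifact.
#' @param fast logical; use 1,000 permutations/randomizations instead of
#'   the field-standard 10,000.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(scenario = "paper_like", sightings_path = NULL,
                            attributes_path = NULL, calf_path = NULL,
                            min_days = 6, min_years = 4,
                            indices = c("HWI", "HWIG"),
                            n_permutations = 10000, flips = 100,
                            n_randomizations = 10000,
                            slar_bins = 8, slar_blocks = 15,
                            out_dir = "ffsoc-results", seed = 1,
                            fast = FALSE) {
  if (fast) {
    n_permutations <- min(n_permutations, 1000)
    n_randomizations <- min(n_randomizations, 1000)
  }
  structure(list(scenario = scenario, sightings_path = sightings_path,
                 attributes_path = attributes_path, calf_path = calf_path,
                 min_days = min_days, min_years = min_years,
                 indices = match.arg(indices, c("HWI", "HWIG"),
                                     several.ok = TRUE),
                 n_permutations = n_permutations, flips = flips,
                 n_randomizations = n_randomizations,
                 slar_bins = slar_bins, slar_blocks = slar_blocks,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#' @param path YAML file whose keys match the [analysis_config()] arguments.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(analysis_config, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full paper-shaped social-structure analysis
#'
#' Executes, in order: inclusion filter; HWI and HWIG matrices; CV
#' permutation tests for nonrandom association (both indices);
#' sex-stratified within- vs between-class tests; male-male and male-female
#' randomization comparisons; male average-linkage clustering with
#' cophenetic validation and Newick export (the female clustering is
#' computed but flagged when its cophenetic correlation is inadequate);
#' SLAR estimation and temporal-model fitting per male community class; and
#' a reproductive-condition table for SC females at the end of the study
#' span. Artifacts (CSV/JSON, Newick, a markdown summary) are written under
#' `config$out_dir`; every stochastic stage records its seed.
#'
#' @param config an [analysis_config].
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  res <- list(config = config)

  calf_records <- NULL
  res$data <- .stage("load", {
    if (!is.null(config$scenario)) {
      gen <- generate_scenario(config$scenario, seed = config$seed)
      write_sightings(gen$dataset, out("sightings.csv"),
                      out("attributes.csv"))
      write_ground_truth(gen$truth, out("ground_truth.json"))
      calf_records <- gen$calf_records
      if (nrow(gen$calf_records))
        utils::write.csv(transform(gen$calf_records,
                                   date = format(date, "%Y-%m-%d")),
                         out("calf_records.csv"), row.names = FALSE)
      gen$dataset
    } else {
      if (is.null(config$sightings_path)) stop("no scenario and no input path")
      if (!is.null(config$calf_path))
        calf_records <- read_calf_records(config$calf_path)
      read_sightings(config$sightings_path, config$attributes_path)
    }
  })

  res$filtered <- .stage("filter",
    filter_individuals(res$data, config$min_days, config$min_years))
  d <- res$filtered
  ind <- d$individuals
  if (all(ind$community_class == "unknown"))
    stop("pipeline stage 'filter' failed: class comparisons requested but ",
         "no individual has a known community class (labels NC/SC missing)",
         call. = FALSE)

  res$hwi <- .stage("associations", half_weight_matrix(d))
  res$hwig <- .stage("associations", hwig_matrix(res$hwi))
  write_assoc_matrix(res$hwi, out("hwi.csv"))
  write_assoc_matrix(res$hwig, out("hwig.csv"))
  mats <- list(HWI = res$hwi, HWIG = res$hwig)

  res$cv_tests <- .stage("permtest", lapply(config$indices, function(k) {
    t <- cv_test(d, k, n_permutations = config$n_permutations,
                 flips = config$flips, seed = config$seed + 11L)
    write_permtest(t, out(paste0("cv_test_", tolower(k), ".json")))
    t
  }))
  names(res$cv_tests) <- config$indices

  cls <- stats::setNames(ind$community_class, ind$id)
  sexes <- stats::setNames(ind$sex, ind$id)
  males <- ind$id[ind$sex == "male"]
  females <- ind$id[ind$sex == "female"]

  res$class_tests <- .stage("compare", {
    tests <- list()
    for (k in config$indices) {
      for (sx in c("male", "female")) {
        idset <- ind$id[ind$sex == sx]
        idset <- idset[cls[idset] %in% c("NC", "SC")]
        if (length(idset) < 4L || length(unique(cls[idset])) < 2L) next
        nm <- paste0(sx, "_within_vs_between_", tolower(k))
        tests[[nm]] <- mantel_class_test(
          mats[[k]], cls[idset], n_permutations = config$n_permutations,
          seed = config$seed + 23L)
      }
    }
    tests
  })

  res$male_comparisons <- .stage("compare", {
    cmp <- list()
    nc_m <- males[cls[males] == "NC"]; sc_m <- males[cls[males] == "SC"]
    for (k in config$indices) {
      if (length(nc_m) >= 2L && length(sc_m) >= 2L)
        cmp[[paste0("ncmale_vs_scmale_within_", tolower(k))]] <-
          randomization_mean_difference(
            mats[[k]], dyad_set(within = nc_m), dyad_set(within = sc_m),
            n = config$n_randomizations, seed = config$seed + 31L)
      if (length(nc_m) && length(sc_m) && length(females))
        cmp[[paste0("ncmale_vs_scmale_to_females_", tolower(k))]] <-
          randomization_mean_difference(
            mats[[k]],
            dyad_set(between = nc_m, and = females),
            dyad_set(between = sc_m, and = females),
            n = config$n_randomizations, seed = config$seed + 37L)
    }
    cmp
  })
  .stage("compare", {
    all_tests <- c(res$class_tests, res$male_comparisons)
    jsonlite::write_json(lapply(all_tests, function(t) {
      if (inherits(t, "mantel_class_test"))
        list(statistic = t$statistic, p_value = t$p_value,
             n = t$n_permutations, seed = t$seed, unit = "individual")
      else
        list(statistic = t$observed_difference, p_value = t$p_value,
             n = t$n_randomizations, seed = t$seed, unit = t$unit)
    }), out("comparisons.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  })

  res$clustering <- .stage("cluster", {
    cl_res <- list()
    for (sx in c("male", "female")) {
      idset <- ind$id[ind$sex == sx]
      if (length(idset) < 3L) next
      for (k in config$indices) {
        sub <- .subset_assoc(mats[[k]], idset)
        dend <- average_linkage(sub)
        fit <- cophenetic_correlation(dend, sub)
        nm <- paste0(sx, "_", tolower(k))
        if (sx == "male") {
          write_newick(dend, out(paste0("dendrogram_", nm, ".nwk")))
          write_merge_table(dend, out(paste0("merges_", nm, ".csv")))
        }
        cl_res[[nm]] <- list(dendrogram = dend, fit = fit,
                             inadequate = !isTRUE(fit$quality_flag))
      }
    }
    cl_res
  })

  res$slar <- .stage("slar", {
    sl <- list()
    for (cl_name in c("NC", "SC")) {
      idset <- males[cls[males] == cl_name]
      if (length(idset) < 3L) next
      est <- estimate_slar(d, idset, n_bins = config$slar_bins,
                           n_blocks = config$slar_blocks)
      fits <- fit_slar_models(estimate = est)
      write_slar_curve(est, out(paste0("slar_", tolower(cl_name),
                                       "_males.csv")))
      write_slar_model_table(fits, out(paste0("slar_models_",
                                              tolower(cl_name),
                                              "_males.csv")))
      sl[[cl_name]] <- list(estimate = est, fits = fits)
    }
    sl
  })

  res$reproductive <- .stage("reproductive", {
    if (is.null(calf_records) || !nrow(calf_records)) NULL else {
      sc_f <- females[cls[females] == "SC"]
      if (!length(sc_f)) NULL else {
        at <- max(d$samples)
        tab <- data.frame(
          id = sc_f,
          condition = vapply(sc_f, function(f)
            reproductive_condition(d, f, at, calf_records), character(1)),
          row.names = NULL)
        utils::write.csv(tab, out("sc_female_reproductive_conditions.csv"),
                         row.names = FALSE)
        tab
      }
    }
  })

  .write_summary(res, out("summary.md"))
  invisible(res)
}

# restrict an assoc_matrix to a subset of ids
.subset_assoc <- function(matrix, ids) {
  pos <- match(ids, matrix$ids)
  out <- matrix
  out$ids <- ids
  out$values <- matrix$values[pos, pos, drop = FALSE]
  out$counts <- NULL
  out
}

.write_summary <- function(res, path) {
  ln <- c("# Social-structure analysis summary", "",
          sprintf("Individuals after filter: %d (of %d); %d sampling periods.",
                  nrow(res$filtered$individuals), nrow(res$data$individuals),
                  length(res$filtered$samples)),
          sprintf("Master seed: %d", res$config$seed), "",
          "## Nonrandom association (CV permutation test)")
  for (k in names(res$cv_tests)) {
    t <- res$cv_tests[[k]]
    ln <- c(ln, sprintf("- %s: observed CV %.4f, P = %.4g (%d perms x %d flips, seed %d)",
                        k, t$observed_cv, t$p_value, t$n_permutations,
                        t$flips_per_permutation, t$seed))
  }
  ln <- c(ln, "", "## Within- vs between-class comparisons")
  for (nm in names(res$class_tests)) {
    t <- res$class_tests[[nm]]
    ln <- c(ln, sprintf("- %s: within %.4f between %.4f, P = %.4g",
                        nm, t$within_mean, t$between_mean, t$p_value))
  }
  ln <- c(ln, "", "## Male-male and male-female comparisons")
  for (nm in names(res$male_comparisons)) {
    t <- res$male_comparisons[[nm]]
    ln <- c(ln, sprintf("- %s: diff %.4f (A %.4f vs B %.4f), P = %.4g",
                        nm, t$observed_difference, t$mean_a, t$mean_b,
                        t$p_value))
  }
  ln <- c(ln, "", "## Clustering (cophenetic correlation)")
  for (nm in names(res$clustering)) {
    f <- res$clustering[[nm]]$fit
    ln <- c(ln, sprintf("- %s: CCC %s%s", nm,
                        if (f$defined) sprintf("%.3f", f$cophenetic_correlation)
                        else "undefined",
                        if (res$clustering[[nm]]$inadequate)
                          " (inadequate, < 0.8)" else ""))
  }
  ln <- c(ln, "", "## SLAR temporal models")
  for (cl_name in names(res$slar)) {
    f <- res$slar[[cl_name]]$fits
    ln <- c(ln, sprintf("- %s males: best model %s (c_hat %.3g); null rate %.4f",
                        cl_name, f$best_model, f$c_hat,
                        res$slar[[cl_name]]$estimate$null_rate))
  }
  if (!is.null(res$reproductive)) {
    ln <- c(ln, "", "## SC female reproductive conditions at end of span")
    ln <- c(ln, sprintf("- %s: %s", res$reproductive$id,
                        res$reproductive$condition))
  }
  writeLines(ln, path)
  invisible(path)
}
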