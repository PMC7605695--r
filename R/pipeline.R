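#' Pipeline configuration
#'
#' Bundles every analysis choice: the data source (a generator preset, an
#' explicit [generator_config()], or file paths), dichotomization thresholds,
#' the gender-composition mode, the consumption-layer flags, the AUDIT risk
#' threshold, the transitivity scheme, the correlation mode and alpha.
#'
#' @param preset name of a [generator_preset()] to simulate from.
#' @param generator an explicit [generator_config()] (overrides `preset`).
#' @param seed seed used when simulating (overrides the preset's).
#' @param roster_path,matrix_paths,nomination_paths alternatively, paths to a
#'   roster CSV, a named list (classroom -> path) of contact matrices and an
#'   optional named list of nomination networks.
#' @param matrix_dialect,nomination_dialect dialects for the file readers.
#' @param thresholds an [intensity_thresholds()].
#' @param composition_attribute attribute for the composition layer.
#' @param composition_mode `"homophilous_subnetwork"` (same-gender subnetwork
#'   of the minimum-intensity layer; feeds the gender-composition correlation)
#'   or `"stratified_census"`; the stratified censuses are reported in either
#'   mode.
#' @param consumption_restrict_to_contact,consumption_symmetrize flags passed
#'   to [consumption_layer()].
#' @param audit_threshold AUDIT risk cut-off (default 8).
#' @param alpha significance level (default 0.05).
#' @param correlation_mode passed to [transitive_profile_correlation()].
#' @param scheme a [transitivity_scheme()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = NULL, generator = NULL, seed = NULL,
                            roster_path = NULL, matrix_paths = NULL,
                            nomination_paths = NULL,
                            matrix_dialect = "csv",
                            nomination_dialect = "edge_list",
                            thresholds = intensity_thresholds(),
                            composition_attribute = "gender",
                            composition_mode = c("homophilous_subnetwork",
                                                 "stratified_census"),
                            consumption_restrict_to_contact = FALSE,
                            consumption_symmetrize = FALSE,
                            audit_threshold = 8,
                            alpha = 0.05,
                            correlation_mode = "node_profile",
                            scheme = transitivity_scheme()) {
  composition_mode <- match.arg(composition_mode)
  simulated <- !is.null(preset) || !is.null(generator)
  if (!simulated && (is.null(roster_path) || is.null(matrix_paths))) {
    ts_stop("either a generator preset/config or roster_path + matrix_paths is required",
            "usage_error")
  }
  if (!simulated) {
    paths <- c(roster_path, unlist(matrix_paths), unlist(nomination_paths))
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files) > 0) {
      ts_stop(sprintf("input file(s) not found: %s",
                      paste(missing_files, collapse = ", ")), "io_error")
    }
  }
  structure(list(preset = preset, generator = generator, seed = seed,
                 roster_path = roster_path, matrix_paths = matrix_paths,
                 nomination_paths = nomination_paths,
                 matrix_dialect = matrix_dialect,
                 nomination_dialect = nomination_dialect,
                 thresholds = thresholds,
                 composition_attribute = composition_attribute,
                 composition_mode = composition_mode,
                 consumption_restrict_to_contact = consumption_restrict_to_contact,
                 consumption_symmetrize = consumption_symmetrize,
                 audit_threshold = as.integer(audit_threshold),
                 alpha = alpha,
                 correlation_mode = correlation_mode,
                 scheme = scheme),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

load_study <- function(cfg) {
  if (!is.null(cfg$generator) || !is.null(cfg$preset)) {
    gcfg <- cfg$generator %||% generator_preset(cfg$preset, seed = cfg$seed)
    if (!is.null(cfg$seed)) {
      gcfg$seed <- as.integer(cfg$seed)
    }
    return(generate_study(gcfg))
  }
  ros <- read_roster(cfg$roster_path)
  mats <- lapply(names(cfg$matrix_paths), function(cl) {
    read_contact_matrix(cfg$matrix_paths[[cl]], cfg$matrix_dialect,
                        classroom = cl)
  })
  names(mats) <- names(cfg$matrix_paths)
  noms <- NULL
  if (!is.null(cfg$nomination_paths)) {
    noms <- lapply(names(cfg$nomination_paths), function(cl) {
      read_network(cfg$nomination_paths[[cl]], cfg$nomination_dialect,
                   classroom = cl, layer = "consumption")
    })
    names(noms) <- names(cfg$nomination_paths)
  }
  list(roster = ros, contact_matrices = mats, nomination_networks = noms)
}

#' Run the full triadic analysis pipeline
#'
#' For each classroom: dichotomize the ordinal contact matrix into the three
#' intensity layers, build the gender-composition and consumption layers,
#' compute triad censuses for every layer, then aggregate censuses per
#' rural/urban setting, classify AUDIT risk, test risk against gender and
#' setting by chi-square, and correlate the transitive-triad profiles of the
#' consumption layer with the minimum-intensity and gender-composition layers
#' (with exact power). Degenerate stages (zero-variance correlation vectors,
#' chi-square tables with an empty margin) are recorded as warnings in the
#' report, not errors. Output is deterministic for fixed inputs and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return object of class `analysis_report`; see the elements `censuses`,
#'   `setting_censuses`, `risk`, `correlations`, `warnings`, `provenance`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  study <- load_study(cfg)
  ros <- study$roster
  warnings <- character(0)
  scheme <- cfg$scheme
  classrooms <- names(study$contact_matrices)

  nets <- list()
  census_objects <- list()
  stratified <- list()
  cor_rows <- list()
  for (cl in classrooms) {
    layers <- tryCatch(
      build_layers(cl, study, ros, cfg),
      triadscope_error = function(e) {
        ts_stop(sprintf("classroom '%s', layer construction: %s",
                        cl, conditionMessage(e)), "pipeline_stage_error")
      })
    nets[[cl]] <- layers
    census_objects[[cl]] <- lapply(layers, triad_census, scheme = scheme)
    stratified[[cl]] <- stratified_census(layers$minimum, ros,
                                          cfg$composition_attribute, scheme)
    if (!is.null(layers$consumption)) {
      for (target in c("minimum",
                       paste0(cfg$composition_attribute, "_homophilous"))) {
        res <- tryCatch(
          transitive_profile_correlation(layers$consumption, layers[[target]],
                                         scheme, cfg$correlation_mode,
                                         cfg$alpha),
          triadscope_error = function(e) {
            conditionMessage(e)
          })
        if (is.character(res)) {
          warnings <- c(warnings,
                        sprintf("classroom '%s', correlation vs %s: %s",
                                cl, target, res))
          res <- list(r = NA_real_, n = NA_integer_, p_value = NA_real_,
                      power = NA_real_)
        }
        cor_rows[[length(cor_rows) + 1]] <- data.frame(
          classroom = cl,
          setting = classroom_setting(ros, cl),
          target_layer = target,
          n = res$n, r = res$r, p_value = res$p_value, power = res$power,
          stringsAsFactors = FALSE)
      }
    }
  }

  census_long <- censuses_to_long(census_objects, ros)
  settings <- unique(census_long$setting)
  layer_names <- unique(census_long$layer)
  setting_census_objects <- list()
  for (s in settings) {
    cls <- classrooms[vapply(classrooms, classroom_setting, "", ros = ros) == s]
    setting_census_objects[[s]] <- lapply(setNames(layer_names, layer_names),
      function(ly) {
        aggregate_censuses(lapply(cls, function(cl) census_objects[[cl]][[ly]]))
      })
  }
  setting_long <- setting_censuses_to_long(setting_census_objects)

  scored <- score_audit_all(ros, threshold = cfg$audit_threshold)
  chi_gender <- risk_chi_square(scored, "gender", cfg, warnings)
  warnings <- chi_gender$warnings
  chi_setting <- risk_chi_square(scored, "setting", cfg, warnings)
  warnings <- chi_setting$warnings

  correlations <- if (length(cor_rows) > 0) do.call(rbind, cor_rows) else NULL
  structure(list(
    classrooms = classrooms,
    roster = ros,
    config = cfg,
    networks = nets,
    census_objects = census_objects,
    setting_census_objects = setting_census_objects,
    censuses = census_long,
    setting_censuses = setting_long,
    stratified = stratified,
    risk = list(overall = risk_proportions(scored),
                by_gender = risk_proportions(scored, "gender"),
                by_setting = risk_proportions(scored, "setting"),
                chi_square_gender = chi_gender$result,
                chi_square_setting = chi_setting$result,
                threshold = cfg$audit_threshold,
                classifications = scored),
    correlations = correlations,
    warnings = warnings,
    provenance = list(config_hash = config_hash(cfg),
                      seed = cfg$seed %||% cfg$generator$seed %||% NA_integer_,
                      package_version = as.character(utils::packageVersion("triadscope")))),
    class = "analysis_report")
}

build_layers <- function(cl, study, ros, cfg) {
  three <- dichotomize_all(study$contact_matrices[[cl]], cfg$thresholds)
  comp <- homophilous_subnetwork(three$minimum, ros, cfg$composition_attribute)
  layers <- list(minimum = three$minimum, intermediate = three$intermediate,
                 maximum = three$maximum)
  layers[[comp$layer]] <- comp
  if (!is.null(study$nomination_networks) &&
      !is.null(study$nomination_networks[[cl]])) {
    layers$consumption <- consumption_layer(
      study$nomination_networks[[cl]], three$minimum,
      restrict_to_contact = cfg$consumption_restrict_to_contact,
      symmetrize = cfg$consumption_symmetrize)
  }
  layers
}

classroom_setting <- function(ros, cl) {
  ros$setting[match(cl, ros$classroom)]
}

censuses_to_long <- function(census_objects, ros) {
  rows <- list()
  for (cl in names(census_objects)) {
    for (ly in names(census_objects[[cl]])) {
      cen <- census_objects[[cl]][[ly]]
      pct <- if (cen$n_triads > 0) 100 * cen$counts / cen$n_triads
             else rep(NA_real_, 16)
      rows[[length(rows) + 1]] <- data.frame(
        classroom = cl, setting = classroom_setting(ros, cl),
        layer = ly,
        code = names(cen$counts), count = as.integer(cen$counts),
        pct = pct,
        partition = ifelse(names(cen$counts) %in% cen$scheme$transitive,
                           "transitive", "intransitive"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

setting_censuses_to_long <- function(setting_census_objects) {
  rows <- list()
  for (s in names(setting_census_objects)) {
    for (ly in names(setting_census_objects[[s]])) {
      cen <- setting_census_objects[[s]][[ly]]
      pct <- if (cen$n_triads > 0) 100 * cen$counts / cen$n_triads
             else rep(NA_real_, 16)
      rows[[length(rows) + 1]] <- data.frame(
        setting = s, layer = ly,
        code = names(cen$counts), count = as.integer(cen$counts), pct = pct,
        partition = ifelse(names(cen$counts) %in% cen$scheme$transitive,
                           "transitive", "intransitive"),
        transitive_total = cen$transitive_total,
        n_triads = cen$n_triads,
        transitive_share = cen$transitive_share,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

risk_chi_square <- function(scored, by, cfg, warnings) {
  tab <- table(scored[[by]], factor(scored$at_risk, c(FALSE, TRUE),
                                    c("no_risk", "at_risk")))
  res <- tryCatch(chi_square(unclass(tab)),
                  triadscope_error = function(e) conditionMessage(e))
  if (is.character(res)) {
    warnings <- c(warnings, sprintf("chi-square risk x %s: %s", by, res))
    res <- NULL
  }
  list(result = res, warnings = warnings)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d classrooms (%s), %d actors\n",
              length(x$classrooms),
              paste(sort(unique(x$censuses$setting)), collapse = "/"),
              nrow(x$roster)))
  agg <- unique(x$setting_censuses[, c("setting", "layer", "transitive_total",
                                       "n_triads")])
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %s / %s: %d/%d transitive triads\n", agg$setting[i],
                agg$layer[i], agg$transitive_total[i], agg$n_triads[i]))
  }
  if (length(x$warnings) > 0) {
    cat(sprintf("  (%d warnings collected)\n", length(x$warnings)))
  }
  invisible(x)
}

#' Rural vs urban contrast table
#'
#' Contrasts the two settings: per layer, the transitive-triad counts, triad
#' totals and transitive shares side by side, plus the risk proportions with
#' the setting-by-risk chi-square.
#'
#' @param report an [run_pipeline()] report.
#' @return list with `triads` (data frame, one row per layer) and `risk`
#'   (risk proportions by setting plus the chi-square result), or `NULL` with
#'   a warning when the report covers a single setting.
#' @export
compare_settings <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  settings <- names(report$setting_census_objects)
  if (length(settings) < 2) {
    warning("report covers a single setting; contrast skipped")
    return(NULL)
  }
  layers <- names(report$setting_census_objects[[1]])
  triads <- do.call(rbind, lapply(layers, function(ly) {
    row <- data.frame(layer = ly, stringsAsFactors = FALSE)
    for (s in settings) {
      cen <- report$setting_census_objects[[s]][[ly]]
      row[[paste0(s, "_transitive")]] <- cen$transitive_total
      row[[paste0(s, "_triads")]] <- cen$n_triads
      row[[paste0(s, "_share")]] <- cen$transitive_share
    }
    row
  }))
  list(triads = triads,
       risk = list(proportions = report$risk$by_setting,
                   chi_square = report$risk$chi_square_setting))
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (the full machine-readable report), `censuses.csv`,
#' `correlations.csv`, `risk_table.csv` and, for audit, every derived binary
#' network under `networks/` in both DL and edge-list dialects.
#'
#' @param report an [run_pipeline()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(file.path(dir, "networks"), recursive = TRUE, showWarnings = FALSE)
  body <- list(
    classrooms = report$classrooms,
    censuses = report$censuses,
    setting_censuses = report$setting_censuses,
    risk = list(overall = report$risk$overall,
                by_gender = report$risk$by_gender,
                by_setting = report$risk$by_setting,
                threshold = report$risk$threshold,
                chi_square_gender = chi_to_list(report$risk$chi_square_gender),
                chi_square_setting = chi_to_list(report$risk$chi_square_setting)),
    correlations = report$correlations,
    warnings = report$warnings,
    provenance = report$provenance)
  jsonlite::write_json(body, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  write.csv(report$censuses, file.path(dir, "censuses.csv"), row.names = FALSE)
  if (!is.null(report$correlations)) {
    write.csv(report$correlations, file.path(dir, "correlations.csv"),
              row.names = FALSE)
  }
  risk_tab <- rbind(cbind(by = "all", report$risk$overall),
                    cbind(by = "gender", report$risk$by_gender),
                    cbind(by = "setting", report$risk$by_setting))
  write.csv(risk_tab, file.path(dir, "risk_table.csv"), row.names = FALSE)
  for (cl in names(report$networks)) {
    for (ly in names(report$networks[[cl]])) {
      net <- report$networks[[cl]][[ly]]
      base <- file.path(dir, "networks", paste0(cl, "_", net$layer))
      write_network(net, paste0(base, ".dl"), "ucinet_dl")
      write_network(net, paste0(base, "_edges.csv"), "edge_list")
    }
  }
  invisible(dir)
}

chi_to_list <- function(x) {
  if (is.null(x)) return(NULL)
  list(statistic = x$statistic, df = x$df, p_value = x$p_value,
       continuity_corrected = x$continuity_corrected)
}
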