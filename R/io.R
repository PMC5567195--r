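RECORD_COLUMNS <- c("plot_id", "observer_id", "observer_status",
                    "habitat_code", "x", "y", "area_m2", "visit_date",
                    "item_kind", "item_id", "abundance", "vitality",
                    "intensity", "role")

#' Write plot records to a long-format CSV
#'
#' One row per recorded item (structure/function, typical species or
#' pressure), with `abundance`/`vitality` filled only for species and
#' `intensity`/`role` only for pressures. A plot with no records at all is
#' kept as a single row with `item_kind = "none"`, so empty plots survive a
#' round trip.
#'
#' @param dataset a [survey_dataset()] (or a list of [plot_record()]s).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plot_records <- function(dataset, path) {
  plots <- if (inherits(dataset, "survey_dataset")) dataset$plots
           else dataset
  rows <- lapply(plots, function(p) {
    base <- data.frame(plot_id = p$plot_id, observer_id = p$observer_id,
                       observer_status = p$observer_status,
                       habitat_code = p$habitat_code,
                       x = p$x, y = p$y, area_m2 = p$area_m2,
                       visit_date = as.character(p$visit_date))
    item_rows <- list()
    if (length(p$structures_present) > 0) {
      item_rows$sf <- data.frame(
        base, item_kind = "structure_function",
        item_id = p$structures_present,
        abundance = "", vitality = "", intensity = "", role = "",
        row.names = NULL)
    }
    if (nrow(p$species_obs) > 0) {
      item_rows$ts <- data.frame(
        base, item_kind = "typical_species",
        item_id = p$species_obs$species_id,
        abundance = p$species_obs$abundance,
        vitality = p$species_obs$vitality,
        intensity = "", role = "", row.names = NULL)
    }
    if (nrow(p$pressures) > 0) {
      item_rows$pt <- data.frame(
        base, item_kind = "pressure",
        item_id = p$pressures$activity_code,
        abundance = "", vitality = "",
        intensity = p$pressures$intensity,
        role = p$pressures$role, row.names = NULL)
    }
    if (length(item_rows) == 0) {
      item_rows$none <- data.frame(
        base, item_kind = "none", item_id = "",
        abundance = "", vitality = "", intensity = "", role = "",
        row.names = NULL)
    }
    do.call(rbind, item_rows)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out[, RECORD_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read plot records from a long-format CSV
#'
#' Inverse of [write_plot_records()]. Rows are validated one by one;
#' malformed rows are rejected with messages naming the offending row and
#' field. An empty file with a valid header yields an empty list with a
#' warning.
#'
#' @param path input CSV path.
#' @return a list of [plot_record()] objects.
#' @export
read_plot_records <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  miss <- setdiff(RECORD_COLUMNS, names(df))
  if (length(miss) > 0) {
    stop("plot-records CSV missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("plot-records CSV has a header but no rows", call. = FALSE)
    return(list())
  }
  check_row_level <- function(values, levels, field, rows) {
    ok <- tolower(trimws(values)) %in% levels
    if (!all(ok)) {
      stop("row ", paste(rows[!ok] + 1, collapse = ", "),
           ": invalid ", field, " value ",
           paste(unique(values[!ok]), collapse = ", "), call. = FALSE)
    }
  }
  rows <- seq_len(nrow(df))
  check_row_level(df$observer_status, OBSERVER_LEVELS, "observer_status",
                  rows)
  check_row_level(df$item_kind, c(ITEM_KINDS, "none"), "item_kind", rows)
  is_ts <- tolower(df$item_kind) == "typical_species"
  check_row_level(df$abundance[is_ts], ABUNDANCE_LEVELS, "abundance",
                  rows[is_ts])
  check_row_level(df$vitality[is_ts], VITALITY_LEVELS, "vitality",
                  rows[is_ts])
  is_pt <- tolower(df$item_kind) == "pressure"
  check_row_level(df$intensity[is_pt], INTENSITY_LEVELS, "intensity",
                  rows[is_pt])
  check_row_level(df$role[is_pt], ROLE_LEVELS, "role", rows[is_pt])

  lapply(split(df, factor(df$plot_id, levels = unique(df$plot_id))),
         function(sub) {
    sf <- sub[tolower(sub$item_kind) == "structure_function", ]
    ts <- sub[tolower(sub$item_kind) == "typical_species", ]
    pt <- sub[tolower(sub$item_kind) == "pressure", ]
    plot_record(
      sub$plot_id[1], sub$habitat_code[1], sub$observer_id[1],
      sub$observer_status[1],
      as.numeric(sub$x[1]), as.numeric(sub$y[1]),
      structures_present = sf$item_id,
      species_obs = species_observations(ts$item_id, ts$abundance,
                                         ts$vitality),
      pressures = pressure_records(pt$item_id, pt$intensity, pt$role),
      area_m2 = as.numeric(sub$area_m2[1]),
      visit_date = sub$visit_date[1])
  }) |> unname()
}

#' Pipeline run configuration
#'
#' File paths and analysis switches for [run_pipeline()].
#'
#' @param protocol_path habitat protocol YAML.
#' @param records_path plot-records CSV (long format).
#' @param polygon_path habitat patch GeoJSON.
#' @param out_dir output directory (created if needed).
#' @param site_code site identifier for the assembled survey.
#' @param item_kinds item kinds to analyse (default all three).
#' @param n_permutations permutations for every permutation test.
#' @param seed integer RNG seed (mandatory; recorded in every output).
#' @param min_observers flagging threshold, see [flag_low_support()].
#' @param alternative sidedness of the edge-distance test.
#' @return an object of class `run_config`.
#' @export
run_config <- function(protocol_path, records_path, polygon_path, out_dir,
                       site_code = "site", item_kinds = ITEM_KINDS,
                       n_permutations = 5000, seed, min_observers = 2,
                       alternative = "two.sided") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  for (p in c(protocol_path, records_path, polygon_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  item_kinds <- match.arg(item_kinds, ITEM_KINDS, several.ok = TRUE)
  structure(
    list(protocol_path = protocol_path, records_path = records_path,
         polygon_path = polygon_path, out_dir = out_dir,
         site_code = site_code, item_kinds = item_kinds,
         n_permutations = n_permutations, seed = as.integer(seed),
         min_observers = min_observers, alternative = alternative),
    class = "run_config"
  )
}

quality_report_to_list <- function(q) {
  list(item_kind = q$item_kind,
       n_plots = as.list(q$n_plots),
       mean_richness = as.list(q$mean_richness),
       completeness_per_plot = q$completeness_per_plot,
       completeness_pooled = q$completeness_pooled,
       accuracy = q$accuracy,
       items_shared = q$items_shared,
       items_only_experts = q$items_only_experts,
       items_only_nonexperts = q$items_only_nonexperts,
       support_counts = as.list(q$support_counts),
       min_observers = q$min_observers,
       flagged_items = q$flagged_items)
}

#' Run the full assessment + quality pipeline
#'
#' Reads the protocol, plot records and patch polygon, assembles the
#' survey, and writes five outputs to `out_dir`: `assessment.csv`
#' (per-plot criterion scores and statuses), `quality.json` (per item
#' kind quality report), `anova.json` (permutational ANOVA of per-plot
#' richness on observer status, per item kind), `edge.json` (edge-distance
#' comparison) and `summary.txt` (status tallies by observer group). Every
#' output embeds the seed and a hash of the run configuration; a failure
#' at any stage removes partial outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the output `paths` and the computed
#'   objects (`assessment`, `quality`, `anova`, `edge`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  paths <- file.path(config$out_dir,
                     c(assessment = "assessment.csv",
                       quality = "quality.json",
                       anova = "anova.json",
                       edge = "edge.json",
                       summary = "summary.txt"))
  names(paths) <- c("assessment", "quality", "anova", "edge", "summary")
  cfg_hash <- rlang::hash(unclass(config))
  written <- character()
  stage <- "setup"
  result <- tryCatch({
    stage <- "read inputs"
    protocol <- read_protocol_yaml(config$protocol_path)
    plots <- read_plot_records(config$records_path)
    polygon <- read_polygon_geojson(config$polygon_path)
    dataset <- survey_dataset(config$site_code, protocol$habitat_code,
                              plots, protocol)
    message("read ", length(plots), " plots for habitat ",
            protocol$habitat_code)

    stage <- "assessment"
    assessment <- assess_survey(dataset)
    header <- sprintf("# seed=%d config_hash=%s", config$seed, cfg_hash)
    writeLines(header, paths["assessment"])
    suppressWarnings(
      utils::write.table(assessment, paths["assessment"], sep = ",",
                         row.names = FALSE, append = TRUE, quote = FALSE))
    written <- c(written, paths["assessment"])
    message("assessed ", nrow(assessment), " plots")

    stage <- "quality"
    quality <- lapply(config$item_kinds, function(kind) {
      compare_groups(dataset, kind, min_observers = config$min_observers)
    })
    names(quality) <- config$item_kinds
    jsonlite::write_json(
      list(seed = config$seed, config_hash = cfg_hash,
           reports = lapply(quality, quality_report_to_list)),
      paths["quality"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, paths["quality"])
    message("flagged ",
            sum(vapply(quality, function(q) length(q$flagged_items),
                       integer(1))), " low-support items")

    stage <- "permutational ANOVA"
    anova <- lapply(config$item_kinds, function(kind) {
      tab <- build_incidence(dataset, kind)
      perm_anova(per_plot_richness(tab), tab$observer_status,
                 n_permutations = config$n_permutations,
                 seed = config$seed)
    })
    names(anova) <- config$item_kinds
    jsonlite::write_json(
      list(seed = config$seed, config_hash = cfg_hash,
           n_permutations = config$n_permutations,
           tests = lapply(anova, function(a) {
             list(table = a$table, df_residual = a$df_residual,
                  group_means = as.list(a$group_means))
           })),
      paths["anova"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, paths["anova"])

    stage <- "edge-distance comparison"
    edge <- compare_edge_distance(dataset, polygon,
                                  n_permutations = config$n_permutations,
                                  seed = config$seed,
                                  alternative = config$alternative)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = cfg_hash,
           mean_dist_expert = edge$mean_dist_expert,
           mean_dist_nonexpert = edge$mean_dist_nonexpert,
           observed_diff = edge$observed_diff,
           p_value = edge$p_value,
           n_permutations = edge$n_permutations,
           alternative = edge$alternative),
      paths["edge"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, paths["edge"])

    stage <- "summary"
    lines <- c(
      sprintf("Survey %s, habitat %s", config$site_code,
              protocol$habitat_code),
      sprintf("seed=%d config_hash=%s", config$seed, cfg_hash), "")
    for (crit in c(sf = "sf_status", ts = "ts_status", pt = "pt_status",
                   overall = "overall_status")) {
      tally <- table(assessment$observer_status,
                     factor(assessment[[crit]], levels = STATUS_LEVELS))
      lines <- c(lines, paste0(crit, " classification by observer group:"))
      for (grp in rownames(tally)) {
        lines <- c(lines, sprintf("  %-10s %s", grp,
                                  paste(sprintf("%s=%d", colnames(tally),
                                                tally[grp, ]),
                                        collapse = " ")))
      }
      lines <- c(lines, "")
    }
    writeLines(lines, paths["summary"])
    written <- c(written, paths["summary"])

    list(paths = paths, assessment = assessment, quality = quality,
         anova = anova, edge = edge)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
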