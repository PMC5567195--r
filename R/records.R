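#' Typical-species observation table
#'
#' Builds/validates the species-observation table of a plot record: one row
#' per typical species seen in the plot, with its abundance class
#' (`rare < occasional < frequent < abundant`) and vitality class
#' (`poor < moderate < good`). Categorical values are case-insensitive on
#' input and stored canonical lower-case.
#'
#' @param species_id character vector of species ids.
#' @param abundance abundance class per species.
#' @param vitality vitality class per species.
#' @return a data frame with columns `species_id`, `abundance`, `vitality`.
#' @export
species_observations <- function(species_id = character(),
                                 abundance = character(),
                                 vitality = character()) {
  df <- data.frame(species_id = as.character(species_id),
                   abundance = match_level(abundance, ABUNDANCE_LEVELS,
                                           "abundance"),
                   vitality = match_level(vitality, VITALITY_LEVELS,
                                          "vitality"))
  if (anyDuplicated(df$species_id)) {
    stop("duplicate species_id within one plot", call. = FALSE)
  }
  df
}

#' Pressure/threat record table
#'
#' One row per activity recorded in a plot, with its intensity
#' (`low`/`medium`/`high`) and role. An activity already taking place and
#' expected to continue is both a pressure and a threat (`role = "both"`);
#' the classification rule counts each activity once regardless of role.
#'
#' @param activity_code character vector of activity codes.
#' @param intensity intensity class per activity.
#' @param role `"pressure"`, `"threat"` or `"both"` (default `"both"`).
#' @return a data frame with columns `activity_code`, `intensity`, `role`.
#' @export
pressure_records <- function(activity_code = character(),
                             intensity = character(),
                             role = rep("both", length(activity_code))) {
  data.frame(activity_code = as.character(activity_code),
             intensity = match_level(intensity, INTENSITY_LEVELS, "intensity"),
             role = match_level(role, ROLE_LEVELS, "role"))
}

#' One completed field protocol (a sample plot)
#'
#' A `plot_record` holds everything one observer (or observer team) recorded
#' on one 100 m2 sample plot: which checklist structures and functions were
#' present, which typical species were seen (with abundance and vitality),
#' and which pressures/threats were observed (with intensity).
#'
#' @param plot_id unique plot identifier.
#' @param habitat_code habitat-type code of the plot.
#' @param observer_id identifier of the observer (a team counts as one id).
#' @param observer_status `"expert"` or `"non_expert"`.
#' @param x,y planar coordinates of the plot centre, in meters.
#' @param structures_present character vector of checked checklist item ids.
#' @param species_obs a [species_observations()] data frame.
#' @param pressures a [pressure_records()] data frame.
#' @param area_m2 plot area in square meters (default 100).
#' @param visit_date calendar date of the visit (`Date` or `"YYYY-MM-DD"`).
#' @return an object of class `plot_record`.
#' @export
plot_record <- function(plot_id, habitat_code, observer_id, observer_status,
                        x, y,
                        structures_present = character(),
                        species_obs = species_observations(),
                        pressures = pressure_records(),
                        area_m2 = 100, visit_date = as.Date("2015-10-01")) {
  observer_status <- match_level(observer_status, OBSERVER_LEVELS,
                                 "observer_status")
  area_m2 <- as.numeric(area_m2)
  if (is.na(area_m2) || area_m2 <= 0) {
    stop("area_m2 must be > 0", call. = FALSE)
  }
  structures_present <- unique(as.character(structures_present))
  if (anyDuplicated(species_obs$species_id)) {
    stop("species_obs species_id values must be unique within a plot",
         call. = FALSE)
  }
  structure(
    list(plot_id = as.character(plot_id),
         habitat_code = as.character(habitat_code),
         observer_id = as.character(observer_id),
         observer_status = observer_status,
         x = as.numeric(x), y = as.numeric(y),
         area_m2 = area_m2,
         visit_date = as.Date(visit_date),
         structures_present = structures_present,
         species_obs = species_obs,
         pressures = pressures),
    class = "plot_record"
  )
}

#' @export
print.plot_record <- function(x, ...) {
  cat(sprintf("Plot %s (habitat %s, %s %s): %d structures, %d species, %d pressures\n",
              x$plot_id, x$habitat_code, x$observer_status, x$observer_id,
              length(x$structures_present), nrow(x$species_obs),
              nrow(x$pressures)))
  invisible(x)
}

#' A survey: all plots for one site and habitat type
#'
#' The unit of the expert-vs-non-expert quality comparison: every plot
#' recorded for one habitat type at one site, by both observer groups,
#' together with the habitat's assessment protocol.
#'
#' @param site_code site identifier (e.g. a Natura 2000 code).
#' @param habitat_code habitat-type code shared by all plots.
#' @param plots list of [plot_record()] objects.
#' @param protocol the [habitat_protocol()] for this habitat type.
#' @return an object of class `survey_dataset`.
#' @export
survey_dataset <- function(site_code, habitat_code, plots, protocol) {
  stopifnot(inherits(protocol, "habitat_protocol"))
  if (length(plots) == 0) stop("survey needs at least one plot", call. = FALSE)
  if (!all(vapply(plots, inherits, logical(1), "plot_record"))) {
    stop("plots must all be plot_record objects", call. = FALSE)
  }
  codes <- vapply(plots, function(p) p$habitat_code, character(1))
  if (!all(codes == habitat_code)) {
    stop("all plots must share habitat_code ", habitat_code, call. = FALSE)
  }
  ids <- vapply(plots, function(p) p$plot_id, character(1))
  if (anyDuplicated(ids)) {
    stop("plot_id values must be unique within a survey", call. = FALSE)
  }
  structure(
    list(site_code = as.character(site_code),
         habitat_code = as.character(habitat_code),
         plots = plots, protocol = protocol),
    class = "survey_dataset"
  )
}

#' @export
print.survey_dataset <- function(x, ...) {
  st <- observer_statuses(x)
  cat(sprintf("Survey %s / habitat %s: %d plots (%d expert, %d non-expert)\n",
              x$site_code, x$habitat_code, length(x$plots),
              sum(st == "expert"), sum(st == "non_expert")))
  invisible(x)
}

plot_ids <- function(dataset) {
  vapply(dataset$plots, function(p) p$plot_id, character(1))
}

observer_statuses <- function(dataset) {
  vapply(dataset$plots, function(p) p$observer_status, character(1))
}

observer_ids <- function(dataset) {
  vapply(dataset$plots, function(p) p$observer_id, character(1))
}

# item ids of one kind recorded on one plot
plot_items <- function(plot, item_kind) {
  switch(item_kind,
         structure_function = plot$structures_present,
         typical_species = plot$species_obs$species_id,
         pressure = unique(plot$pressures$activity_code),
         stop("unknown item_kind: ", item_kind, call. = FALSE))
}
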