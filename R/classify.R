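#' Classify the structures-and-functions criterion of a plot
#'
#' Applies the national threshold rule to the fraction of checklist items
#' recorded as present: more than 50% present is Favourable (FV), between
#' 25% and 50% (both ends included) is Unfavourable-Inadequate (U1), and
#' less than 25% is Unfavourable-Bad (U2). "More than" and "less than" are
#' strict, so the middle band is the closed interval [0.25, 0.5].
#'
#' @param n_present number of checklist items recorded present (>= 0).
#' @param checklist_size total number of items on the habitat's checklist
#'   (>= 1).
#' @return a single status code, `"FV"`, `"U1"` or `"U2"`.
#' @examples
#' classify_structures_functions(6, 10)  # "FV"
#' classify_structures_functions(5, 10)  # "U1" (50% is not more than 50%)
#' classify_structures_functions(2, 10)  # "U2"
#' @export
classify_structures_functions <- function(n_present, checklist_size) {
  if (length(n_present) != 1 || is.na(n_present) ||
      n_present < 0 || n_present != round(n_present)) {
    stop("n_present must be a single non-negative integer", call. = FALSE)
  }
  if (length(checklist_size) != 1 || is.na(checklist_size) ||
      checklist_size < 1 || checklist_size != round(checklist_size)) {
    stop("checklist_size must be a single positive integer", call. = FALSE)
  }
  if (n_present > checklist_size) {
    stop("n_present (", n_present, ") exceeds checklist_size (",
         checklist_size, ")", call. = FALSE)
  }
  fraction <- n_present / checklist_size
  if (fraction > 0.5) "FV" else if (fraction < 0.25) "U2" else "U1"
}

#' Classify the future-prospects criterion from pressures and threats
#'
#' The more numerous and the more intense the recorded pressures and
#' threats, the worse the future prospects of the habitat in the plot:
#' no records, or a single record of low or medium intensity, is
#' Favourable (FV); up to three records of low or medium intensity is
#' Unfavourable-Inadequate (U1); at least one high-intensity activity, or
#' more than three activities, is Unfavourable-Bad (U2). Each recorded
#' activity counts once, whether it acts as a pressure, a threat, or both.
#'
#' @param pressures a [pressure_records()] data frame (possibly empty).
#' @return a single status code, `"FV"`, `"U1"` or `"U2"`.
#' @examples
#' classify_future_prospects(pressure_records())                    # "FV"
#' classify_future_prospects(pressure_records("A04", "medium"))     # "FV"
#' classify_future_prospects(pressure_records("G01", "high"))       # "U2"
#' @export
classify_future_prospects <- function(pressures) {
  if (is.null(pressures) || nrow(as.data.frame(pressures)) == 0) return("FV")
  pressures <- as.data.frame(pressures)
  intensity <- match_level(pressures$intensity, INTENSITY_LEVELS, "intensity")
  n <- length(intensity)
  if (any(intensity == "high") || n > 3) return("U2")
  if (n <= 1) "FV" else "U1"
}

# ordinal multipliers of the typical-species score
ABUNDANCE_MULT <- c(rare = 0.25, occasional = 0.5, frequent = 0.75,
                    abundant = 1.0)
VITALITY_MULT  <- c(poor = 0.5, moderate = 0.75, good = 1.0)

#' Score the typical-species criterion of a plot
#'
#' Weighted, normalized typical-species score in \[0, 1\]: each observed
#' typical species contributes its protocol weight multiplied by ordinal
#' factors for its abundance class (rare 0.25, occasional 0.5,
#' frequent 0.75, abundant 1.0) and vitality class (poor 0.5,
#' moderate 0.75, good 1.0); the sum is divided by the total weight of the
#' habitat's full typical-species list. The score is 1 only when every
#' typical species is abundant and in good vitality, and 0 when none was
#' seen. Observed species absent from the protocol list (e.g. off-list
#' records by non-experts) are ignored with a warning.
#'
#' @param species_obs a [species_observations()] data frame.
#' @param protocol the plot's [habitat_protocol()].
#' @return a single numeric score in \[0, 1\].
#' @examples
#' prot <- habitat_protocol("h",
#'   data.frame(item_id = "sf1", label = "x", item_class = "natural_feature"),
#'   data.frame(species_id = c("A", "B", "C"), weight = c(2, 1, 1)),
#'   data.frame(activity_code = character(), label = character()))
#' obs <- species_observations(c("A", "C"),
#'                             c("frequent", "rare"), c("good", "moderate"))
#' score_typical_species(obs, prot)  # 0.421875
#' @export
score_typical_species <- function(species_obs, protocol) {
  stopifnot(inherits(protocol, "habitat_protocol"))
  ts <- protocol$typical_species
  if (nrow(ts) == 0) {
    stop("protocol has an empty typical_species list", call. = FALSE)
  }
  species_obs <- as.data.frame(species_obs)
  if (nrow(species_obs) == 0) return(0)
  unknown <- setdiff(species_obs$species_id, ts$species_id)
  if (length(unknown) > 0) {
    warning("ignoring species not on the typical-species list: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    species_obs <- species_obs[!species_obs$species_id %in% unknown, ,
                               drop = FALSE]
  }
  if (nrow(species_obs) == 0) return(0)
  ab <- match_level(species_obs$abundance, ABUNDANCE_LEVELS, "abundance")
  vi <- match_level(species_obs$vitality, VITALITY_LEVELS, "vitality")
  w <- ts$weight[match(species_obs$species_id, ts$species_id)]
  sum(w * ABUNDANCE_MULT[ab] * VITALITY_MULT[vi]) / sum(ts$weight)
}

#' Classify the typical-species criterion from its score
#'
#' Applies the same 0.5 / 0.25 threshold rule as
#' [classify_structures_functions()] to the typical-species score, keeping
#' the two plot-level condition criteria on a common scale: FV above 0.5,
#' U1 on \[0.25, 0.5\], U2 below 0.25.
#'
#' @param ts_score a score in \[0, 1\], from [score_typical_species()].
#' @return a single status code, `"FV"`, `"U1"` or `"U2"`.
#' @export
classify_typical_species <- function(ts_score) {
  if (length(ts_score) != 1 || is.na(ts_score) ||
      ts_score < 0 || ts_score > 1) {
    stop("ts_score must be a single value in [0, 1]", call. = FALSE)
  }
  if (ts_score > 0.5) "FV" else if (ts_score < 0.25) "U2" else "U1"
}

#' Assess the conservation status of one plot
#'
#' Runs the three plot-level criteria — specific structures and functions,
#' typical species, and pressures and threats (future prospects) — and
#' combines them one-out-all-out: the overall plot status is the worst of
#' the three criterion statuses. The worst-case combiner is the standard
#' Article 17 convention; the source protocols leave the combination to
#' expert judgment.
#'
#' @param plot a [plot_record()].
#' @param protocol the matching [habitat_protocol()].
#' @return an object of class `assessment_result`: a list with fields
#'   `plot_id`, `observer_status`, `sf_fraction`, `sf_status`, `ts_score`,
#'   `ts_status`, `pt_status`, `overall_status`.
#' @export
assess_plot <- function(plot, protocol) {
  stopifnot(inherits(plot, "plot_record"),
            inherits(protocol, "habitat_protocol"))
  if (plot$habitat_code != protocol$habitat_code) {
    stop("plot habitat_code (", plot$habitat_code,
         ") does not match protocol habitat_code (",
         protocol$habitat_code, ")", call. = FALSE)
  }
  checklist <- protocol$sf_checklist$item_id
  off_list <- setdiff(plot$structures_present, checklist)
  if (length(off_list) > 0) {
    warning("plot ", plot$plot_id, ": ignoring structure items not on the ",
            "checklist: ", paste(off_list, collapse = ", "), call. = FALSE)
  }
  n_present <- length(intersect(plot$structures_present, checklist))
  sf_fraction <- n_present / length(checklist)
  sf_status <- classify_structures_functions(n_present, length(checklist))
  ts_score <- score_typical_species(plot$species_obs, protocol)
  ts_status <- classify_typical_species(ts_score)
  pt_status <- classify_future_prospects(plot$pressures)
  structure(
    list(plot_id = plot$plot_id,
         observer_status = plot$observer_status,
         sf_fraction = sf_fraction, sf_status = sf_status,
         ts_score = ts_score, ts_status = ts_status,
         pt_status = pt_status,
         overall_status = worst_status(sf_status, ts_status, pt_status)),
    class = "assessment_result"
  )
}

#' @export
print.assessment_result <- function(x, ...) {
  cat(sprintf("Plot %s: S&F %s (%.2f), typical species %s (%.3f), future prospects %s -> overall %s\n",
              x$plot_id, x$sf_status, x$sf_fraction, x$ts_status, x$ts_score,
              x$pt_status, x$overall_status))
  invisible(x)
}

#' Assess every plot of a survey
#'
#' @param dataset a [survey_dataset()].
#' @return a data frame with one row per plot: `plot_id`, `observer_status`,
#'   `sf_fraction`, `sf_status`, `ts_score`, `ts_status`, `pt_status`,
#'   `overall_status`.
#' @export
assess_survey <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  rows <- lapply(dataset$plots, function(p) {
    a <- assess_plot(p, dataset$protocol)
    data.frame(plot_id = a$plot_id, observer_status = a$observer_status,
               sf_fraction = a$sf_fraction, sf_status = a$sf_status,
               ts_score = a$ts_score, ts_status = a$ts_status,
               pt_status = a$pt_status, overall_status = a$overall_status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
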