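#' Habitat assessment protocol
#'
#' A `habitat_protocol` is the per-habitat-type assessment template: the
#' checklist of specific structures and functions, the weighted list of
#' typical species, and the catalogue of pressure/threat activity codes.
#' Checklists, typical-species lists and their weights are habitat-specific
#' and are defined nationally by experts; this object carries one such
#' template.
#'
#' @param habitat_code habitat-type code, e.g. `"2120"` or `"9560"`.
#' @param sf_checklist data frame with columns `item_id`, `label`,
#'   `item_class` (one of `"natural_feature"`, `"degradation_absence"`).
#' @param typical_species data frame with columns `species_id`, `weight`
#'   (positive), and optionally `growth_form` (`"woody"`/`"herbaceous"`,
#'   used by the observer-detection simulator; defaults to `"woody"`).
#' @param pressure_catalogue data frame with columns `activity_code`, `label`.
#' @return an object of class `habitat_protocol`.
#' @examples
#' p <- habitat_protocol(
#'   "9560",
#'   sf_checklist = data.frame(item_id = c("sf1", "sf2"),
#'                             label = c("regeneration", "no logging"),
#'                             item_class = c("natural_feature",
#'                                            "degradation_absence")),
#'   typical_species = data.frame(species_id = c("juniperus_excelsa"),
#'                                weight = 3, growth_form = "woody"),
#'   pressure_catalogue = data.frame(activity_code = "A04",
#'                                   label = "grazing")
#' )
#' @export
habitat_protocol <- function(habitat_code, sf_checklist, typical_species,
                             pressure_catalogue) {
  habitat_code <- as.character(habitat_code)
  stopifnot(length(habitat_code) == 1L, nzchar(habitat_code))

  sf_checklist <- as.data.frame(sf_checklist)
  if (nrow(sf_checklist) == 0) {
    stop("sf_checklist must be non-empty", call. = FALSE)
  }
  need <- c("item_id", "label", "item_class")
  miss <- setdiff(need, names(sf_checklist))
  if (length(miss) > 0) {
    stop("sf_checklist missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sf_checklist$item_id <- as.character(sf_checklist$item_id)
  sf_checklist$item_class <- match_level(
    sf_checklist$item_class, c("natural_feature", "degradation_absence"),
    "item_class")
  if (anyDuplicated(sf_checklist$item_id)) {
    stop("sf_checklist item_id values must be unique", call. = FALSE)
  }

  typical_species <- as.data.frame(typical_species)
  miss <- setdiff(c("species_id", "weight"), names(typical_species))
  if (length(miss) > 0) {
    stop("typical_species missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  typical_species$species_id <- as.character(typical_species$species_id)
  typical_species$weight <- as.numeric(typical_species$weight)
  if (anyDuplicated(typical_species$species_id)) {
    stop("typical_species species_id values must be unique", call. = FALSE)
  }
  if (nrow(typical_species) > 0 &&
      (anyNA(typical_species$weight) || any(typical_species$weight <= 0))) {
    stop("typical_species weight values must all be > 0", call. = FALSE)
  }
  if (is.null(typical_species$growth_form)) {
    typical_species$growth_form <- rep("woody", nrow(typical_species))
  }
  typical_species$growth_form <- match_level(
    typical_species$growth_form, c("woody", "herbaceous"), "growth_form")

  pressure_catalogue <- as.data.frame(pressure_catalogue)
  miss <- setdiff(c("activity_code", "label"), names(pressure_catalogue))
  if (length(miss) > 0) {
    stop("pressure_catalogue missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pressure_catalogue$activity_code <-
    as.character(pressure_catalogue$activity_code)
  if (anyDuplicated(pressure_catalogue$activity_code)) {
    stop("pressure_catalogue activity_code values must be unique",
         call. = FALSE)
  }

  structure(
    list(habitat_code = habitat_code,
         sf_checklist = sf_checklist,
         typical_species = typical_species,
         pressure_catalogue = pressure_catalogue),
    class = "habitat_protocol"
  )
}

#' @export
print.habitat_protocol <- function(x, ...) {
  cat("Habitat assessment protocol for habitat type", x$habitat_code, "\n")
  cat("  structures & functions checklist:", nrow(x$sf_checklist), "items\n")
  cat("  typical species:", nrow(x$typical_species),
      sprintf("(weights %s)",
              paste(range(x$typical_species$weight), collapse = "-")), "\n")
  cat("  pressure catalogue:", nrow(x$pressure_catalogue), "activities\n")
  invisible(x)
}

#' Read a habitat protocol from YAML
#'
#' Expected layout: `habitat_code`; `sf_checklist` as a list of
#' `{id, label, class}`; `typical_species` as a list of
#' `{id, weight[, growth_form]}`; `pressure_catalogue` as a list of
#' `{code, label}`.
#'
#' @param path path to a YAML protocol definition.
#' @return a [habitat_protocol()].
#' @export
read_protocol_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("habitat_code", "sf_checklist", "typical_species",
            "pressure_catalogue")
  miss <- setdiff(need, names(y))
  if (length(miss) > 0) {
    stop("protocol YAML missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sf <- do.call(rbind, lapply(y$sf_checklist, function(it) {
    data.frame(item_id = it$id, label = it$label, item_class = it$class)
  }))
  ts <- do.call(rbind, lapply(y$typical_species, function(sp) {
    data.frame(species_id = sp$id, weight = sp$weight,
               growth_form = if (is.null(sp$growth_form)) "woody"
                             else sp$growth_form)
  }))
  pc <- do.call(rbind, lapply(y$pressure_catalogue, function(pr) {
    data.frame(activity_code = pr$code, label = pr$label)
  }))
  habitat_protocol(y$habitat_code, sf, ts, pc)
}

#' Write a habitat protocol to YAML
#'
#' Inverse of [read_protocol_yaml()]; a write/read round trip reproduces the
#' protocol exactly.
#'
#' @param protocol a [habitat_protocol()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protocol_yaml <- function(protocol, path) {
  stopifnot(inherits(protocol, "habitat_protocol"))
  y <- list(
    habitat_code = protocol$habitat_code,
    sf_checklist = lapply(seq_len(nrow(protocol$sf_checklist)), function(i) {
      r <- protocol$sf_checklist[i, ]
      list(id = r$item_id, label = r$label, class = r$item_class)
    }),
    typical_species = lapply(seq_len(nrow(protocol$typical_species)),
                             function(i) {
      r <- protocol$typical_species[i, ]
      list(id = r$species_id, weight = r$weight, growth_form = r$growth_form)
    }),
    pressure_catalogue = lapply(seq_len(nrow(protocol$pressure_catalogue)),
                                function(i) {
      r <- protocol$pressure_catalogue[i, ]
      list(code = r$activity_code, label = r$label)
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
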