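#' Build a plot-by-item incidence table
#'
#' Canonical 0/1 form of a survey for one item kind: rows are plots, columns
#' are item ids, cells indicate whether the plot records the item. For
#' `"structure_function"` the column set is the full protocol checklist plus
#' any off-list records; for species and pressures it is the union of
#' recorded ids (the protocol lists are open-ended in the field).
#'
#' @param dataset a [survey_dataset()].
#' @param item_kind one of `"structure_function"`, `"typical_species"`,
#'   `"pressure"`.
#' @return an object of class `incidence_table`: a list with the 0/1
#'   `matrix` (rownames plot ids, colnames item ids), `item_kind`, and
#'   per-plot `observer_status` and `observer_id` vectors aligned to rows.
#' @export
build_incidence <- function(dataset, item_kind) {
  stopifnot(inherits(dataset, "survey_dataset"))
  item_kind <- match.arg(item_kind, ITEM_KINDS)
  per_plot <- lapply(dataset$plots, plot_items, item_kind = item_kind)
  items <- sort(unique(unlist(per_plot)))
  if (item_kind == "structure_function") {
    items <- sort(unique(c(dataset$protocol$sf_checklist$item_id, items)))
  }
  mat <- matrix(0L, nrow = length(dataset$plots), ncol = length(items),
                dimnames = list(plot_ids(dataset), items))
  for (i in seq_along(per_plot)) {
    mat[i, per_plot[[i]]] <- 1L
  }
  structure(
    list(item_kind = item_kind, matrix = mat,
         observer_status = observer_statuses(dataset),
         observer_id = observer_ids(dataset)),
    class = "incidence_table"
  )
}

#' Per-plot richness (row sums of an incidence table)
#'
#' The number of distinct items of one kind recorded on each plot — the
#' response analysed per sampling area in the expert-vs-non-expert
#' comparison.
#'
#' @param table an [build_incidence()] table.
#' @return a named integer vector, one value per plot.
#' @export
per_plot_richness <- function(table) {
  stopifnot(inherits(table, "incidence_table"))
  rs <- rowSums(table$matrix)
  storage.mode(rs) <- "integer"
  rs
}

#' Cumulative pooled item set of one observer group
#'
#' Accumulates the records of all plots of one observer group into a single
#' set — the "wisdom of the crowds" view, in which many incomplete
#' non-expert plots may jointly cover as much as a few expert plots.
#'
#' @param table an [build_incidence()] table.
#' @param observer_status `"expert"` or `"non_expert"`.
#' @return a character vector of item ids (possibly empty).
#' @export
pooled_items <- function(table, observer_status) {
  stopifnot(inherits(table, "incidence_table"))
  observer_status <- match_level(observer_status, OBSERVER_LEVELS,
                                 "observer_status")
  keep <- table$observer_status == observer_status
  if (!any(keep)) {
    stop("no plots with observer_status ", observer_status, call. = FALSE)
  }
  sub <- table$matrix[keep, , drop = FALSE]
  colnames(sub)[colSums(sub) > 0]
}

#' Completeness of non-expert records relative to experts
#'
#' Two ratios contrasting the individual and the pooled view of the
#' non-expert data: `per_plot` is the mean non-expert per-plot richness
#' divided by the mean expert per-plot richness; `pooled` is the size of
#' the cumulative non-expert item set divided by the size of the cumulative
#' expert item set.
#'
#' @param dataset a [survey_dataset()] containing both observer groups.
#' @param item_kind item kind, as in [build_incidence()].
#' @return a list with numeric elements `per_plot` and `pooled`.
#' @export
completeness <- function(dataset, item_kind) {
  tab <- build_incidence(dataset, item_kind)
  rich <- per_plot_richness(tab)
  st <- tab$observer_status
  if (!all(OBSERVER_LEVELS %in% st)) {
    stop("completeness() needs plots from both observer groups",
         call. = FALSE)
  }
  mean_exp <- mean(rich[st == "expert"])
  mean_non <- mean(rich[st == "non_expert"])
  pooled_exp <- pooled_items(tab, "expert")
  pooled_non <- pooled_items(tab, "non_expert")
  if (mean_exp == 0 || length(pooled_exp) == 0) {
    stop("expert records are empty; completeness ratio undefined",
         call. = FALSE)
  }
  list(per_plot = mean_non / mean_exp,
       pooled = length(pooled_non) / length(pooled_exp))
}

#' Accuracy of non-expert records
#'
#' The fraction of distinct items reported by non-experts that are
#' corroborated, i.e. that appear in the pooled expert records or in an
#' optional reference set of items the experts know to occur in the region.
#'
#' @param dataset a [survey_dataset()] containing both observer groups.
#' @param item_kind item kind, as in [build_incidence()].
#' @param reference_set optional character vector of additionally accepted
#'   item ids (regional expert knowledge).
#' @return a single numeric value in \[0, 1\].
#' @export
accuracy <- function(dataset, item_kind, reference_set = character()) {
  tab <- build_incidence(dataset, item_kind)
  non <- pooled_items(tab, "non_expert")
  if (length(non) == 0) {
    stop("non-experts reported no items; accuracy undefined", call. = FALSE)
  }
  accepted <- union(pooled_items(tab, "expert"), as.character(reference_set))
  mean(non %in% accepted)
}

#' Distinct-observer support per non-expert item
#'
#' For every item reported by at least one non-expert, the number of
#' distinct non-expert observers that reported it (a team sharing one
#' observer id counts once, as do repeat reports by the same observer).
#'
#' @param dataset a [survey_dataset()].
#' @param item_kind item kind, as in [build_incidence()].
#' @return a named integer vector: item id -> distinct-observer count.
#' @export
support_counts <- function(dataset, item_kind) {
  tab <- build_incidence(dataset, item_kind)
  keep <- tab$observer_status == "non_expert"
  mat <- tab$matrix[keep, , drop = FALSE]
  obs <- tab$observer_id[keep]
  counts <- vapply(seq_len(ncol(mat)), function(j) {
    length(unique(obs[mat[, j] > 0]))
  }, integer(1))
  names(counts) <- colnames(mat)
  counts[counts > 0]
}

#' Flag items with low observer support
#'
#' Marks items whose distinct-observer support falls below a threshold —
#' records that are unique and not repeated by other observers are
#' candidates for downweighting or omission when analysing pooled citizen
#' science data. Flagging only marks; it never removes records.
#'
#' @param support a named count vector from [support_counts()].
#' @param min_observers minimum number of distinct observers for an item to
#'   be considered corroborated (default 2: singletons are flagged).
#' @return a character vector of flagged item ids.
#' @export
flag_low_support <- function(support, min_observers = 2) {
  if (length(min_observers) != 1 || is.na(min_observers) ||
      min_observers < 1 || min_observers != round(min_observers)) {
    stop("min_observers must be a single positive integer", call. = FALSE)
  }
  if (length(support) == 0) return(character())
  if (any(support < 1)) {
    stop("support counts must be >= 1 for reported items", call. = FALSE)
  }
  sort(names(support)[support < min_observers])
}

#' Full expert-vs-non-expert quality comparison
#'
#' Assembles, for one item kind, the per-group mean per-plot richness, the
#' two completeness ratios, the accuracy of non-expert records, the
#' partition of pooled items into shared / expert-only / non-expert-only
#' sets, and the distinct-observer support counts with low-support flags.
#'
#' @param dataset a [survey_dataset()] containing both observer groups.
#' @param item_kind item kind, as in [build_incidence()].
#' @param reference_set optional reference item set for [accuracy()].
#' @param min_observers flagging threshold for [flag_low_support()].
#' @return an object of class `quality_report` (a list of the metrics
#'   above).
#' @export
compare_groups <- function(dataset, item_kind,
                           reference_set = character(), min_observers = 2) {
  tab <- build_incidence(dataset, item_kind)
  rich <- per_plot_richness(tab)
  st <- tab$observer_status
  if (!all(OBSERVER_LEVELS %in% st)) {
    stop("compare_groups() needs plots from both observer groups",
         call. = FALSE)
  }
  pooled_exp <- pooled_items(tab, "expert")
  pooled_non <- pooled_items(tab, "non_expert")
  comp <- completeness(dataset, item_kind)
  acc <- if (length(pooled_non) > 0) {
    accuracy(dataset, item_kind, reference_set)
  } else {
    NA_real_
  }
  support <- support_counts(dataset, item_kind)
  structure(
    list(item_kind = tab$item_kind,
         n_plots = c(expert = sum(st == "expert"),
                     non_expert = sum(st == "non_expert")),
         mean_richness = c(expert = mean(rich[st == "expert"]),
                           non_expert = mean(rich[st == "non_expert"])),
         completeness_per_plot = comp$per_plot,
         completeness_pooled = comp$pooled,
         accuracy = acc,
         items_shared = sort(intersect(pooled_exp, pooled_non)),
         items_only_experts = sort(setdiff(pooled_exp, pooled_non)),
         items_only_nonexperts = sort(setdiff(pooled_non, pooled_exp)),
         support_counts = support,
         min_observers = min_observers,
         flagged_items = flag_low_support(support, min_observers)),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Expert vs non-expert quality report (", x$item_kind, ")\n", sep = "")
  cat(sprintf("  plots: %d expert, %d non-expert\n",
              x$n_plots["expert"], x$n_plots["non_expert"]))
  cat(sprintf("  mean per-plot richness: expert %.2f, non-expert %.2f\n",
              x$mean_richness["expert"], x$mean_richness["non_expert"]))
  cat(sprintf("  completeness: per-plot %.3f, pooled %.3f\n",
              x$completeness_per_plot, x$completeness_pooled))
  cat(sprintf("  accuracy of non-expert records: %.3f\n", x$accuracy))
  cat(sprintf("  pooled items: %d shared, %d expert-only, %d non-expert-only\n",
              length(x$items_shared), length(x$items_only_experts),
              length(x$items_only_nonexperts)))
  cat(sprintf("  flagged (support < %d observers): %s\n", x$min_observers,
              if (length(x$flagged_items) == 0) "none"
              else paste(x$flagged_items, collapse = ", ")))
  invisible(x)
}
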