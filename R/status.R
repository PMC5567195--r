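#' Conservation status classes
#'
#' The Habitats Directive Article 17 conservation-status classes, ordered
#' from best to worst: `FV` (Favourable), `U1` (Unfavourable-Inadequate),
#' `U2` (Unfavourable-Bad).
#'
#' @format A character vector of length 3.
#' @export
STATUS_LEVELS <- c("FV", "U1", "U2")

#' Coerce to an ordered conservation-status factor
#'
#' @param x character vector of status codes (`"FV"`, `"U1"`, `"U2"`,
#'   case-insensitive).
#' @return an ordered factor with levels `FV < U1 < U2` (increasing badness).
#' @examples
#' status_factor(c("FV", "u2", "U1"))
#' @export
status_factor <- function(x) {
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), c(STATUS_LEVELS, NA))
  if (length(bad) > 0) {
    stop("invalid status value(s): ", paste(bad, collapse = ", "),
         " (expected FV, U1 or U2)", call. = FALSE)
  }
  factor(x, levels = STATUS_LEVELS, ordered = TRUE)
}

#' Worst (most unfavourable) of several status classes
#'
#' One-out-all-out combiner: the overall class is the worst of its inputs
#' on the badness order `FV < U1 < U2`.
#'
#' @param ... status codes (character) or ordered status factors.
#' @return a single character status code.
#' @examples
#' worst_status("FV", "U1", "FV")  # "U1"
#' @export
worst_status <- function(...) {
  x <- status_factor(unlist(lapply(list(...), as.character)))
  if (length(x) == 0 || anyNA(x)) {
    stop("worst_status() needs at least one non-missing status", call. = FALSE)
  }
  as.character(max(x))
}

# canonical lower-case categorical levels used across the package
ABUNDANCE_LEVELS <- c("rare", "occasional", "frequent", "abundant")
VITALITY_LEVELS  <- c("poor", "moderate", "good")
INTENSITY_LEVELS <- c("low", "medium", "high")
ROLE_LEVELS      <- c("pressure", "threat", "both")
OBSERVER_LEVELS  <- c("expert", "non_expert")
ITEM_KINDS       <- c("structure_function", "typical_species", "pressure")

# case-insensitive match of x against a set of canonical lower-case levels;
# returns canonical values or errors naming the field
match_level <- function(x, levels, field) {
  x <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad) > 0) {
    stop("invalid ", field, " value(s): ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(levels, collapse = ", "), ")",
         call. = FALSE)
  }
  x
}
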