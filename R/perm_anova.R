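#' One-way ANOVA F statistic
#'
#' Classical one-way F from between- and within-group sums of squares:
#' `F = (SSB / (k - 1)) / (SSW / (n - k))`. Computed directly (not via a
#' model fit) because it is the core statistic whose null distribution the
#' permutation tests rebuild.
#'
#' @param response numeric response vector (per-plot counts).
#' @param factor grouping vector with at least 2 levels present.
#' @return the F statistic (>= 0). If all group means are distinct but the
#'   within-group variance is zero, `Inf` is returned with a warning; if
#'   all observations are equal, 0.
#' @examples
#' f_statistic(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
f_statistic <- function(response, factor) {
  response <- as.numeric(response)
  factor <- as.factor(as.character(factor))
  if (length(response) != length(factor)) {
    stop("response and factor must have the same length", call. = FALSE)
  }
  if (anyNA(response) || anyNA(factor)) {
    stop("response and factor must not contain NA", call. = FALSE)
  }
  k <- nlevels(droplevels(factor))
  n <- length(response)
  if (k < 2) stop("factor needs at least 2 levels", call. = FALSE)
  if (n - k < 1) stop("no residual degrees of freedom", call. = FALSE)
  gm <- tapply(response, factor, mean)
  gn <- tapply(response, factor, length)
  grand <- mean(response)
  ssb <- sum(gn * (gm[names(gn)] - grand)^2)
  ssw <- sum((response - gm[as.character(factor)])^2)
  if (ssw == 0) {
    if (ssb == 0) return(0)
    warning("zero within-group variance; F is infinite", call. = FALSE)
    return(Inf)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# thin orthonormal basis of the column space of X
qr_basis <- function(X) {
  qrx <- qr(X)
  list(Q = qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE], rank = qrx$rank)
}

# residual sums of squares of each column of Y after projection on Q
rss_cols <- function(Q, Y) {
  colSums(Y^2) - colSums(crossprod(Q, Y)^2)
}

#' Permutational ANOVA on per-plot counts
#'
#' One-way (observer status only) or two-way main-effects (status +
#' habitat type) ANOVA whose null distribution is built by permuting the
#' response vector — the individual plot counts — rather than assuming
#' normality. Suited to the small, unbalanced designs of field surveys
#' (a handful of expert plots against tens of non-expert plots).
#'
#' For the two-way design each factor is tested from the sequential
#' decomposition with the tested factor entered last (equivalent to Type-II
#' sums of squares for this no-interaction model): its F compares the
#' residual sum of squares of the model without it against the full
#' main-effects model. P-values use the add-one estimator
#' `(#\{F_perm >= F_obs\} + 1) / (n_permutations + 1)`, so the smallest
#' attainable p is `1 / (n_permutations + 1)`.
#'
#' @param response numeric vector of per-plot counts.
#' @param status observer-status factor (`expert` / `non_expert`).
#' @param habitat optional habitat-type factor; when supplied, the two-way
#'   main-effects model is fitted and both factors are tested.
#' @param n_permutations number of permutations (default 5000).
#' @param seed integer RNG seed (mandatory).
#' @param strata optional factor; when supplied, permutations shuffle the
#'   response only within strata levels (restricted permutation).
#' @return an object of class `perm_anova`: list with `table` (data frame:
#'   factor, df, F, p_value), `df_residual`, `group_means` (per status
#'   level), `n_permutations`, `seed`.
#' @examples
#' set.seed(1)
#' y <- c(rpois(6, 8), rpois(30, 3))
#' st <- rep(c("expert", "non_expert"), c(6, 30))
#' perm_anova(y, st, n_permutations = 199, seed = 42)
#' @export
perm_anova <- function(response, status, habitat = NULL,
                       n_permutations = 5000, seed, strata = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  response <- as.numeric(response)
  status <- droplevels(as.factor(as.character(status)))
  n <- length(response)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(status) != n) {
    stop("status must match the length of response", call. = FALSE)
  }
  factors <- list(status = status)
  if (!is.null(habitat)) {
    habitat <- droplevels(as.factor(as.character(habitat)))
    if (length(habitat) != n) {
      stop("habitat must match the length of response", call. = FALSE)
    }
    factors$habitat <- habitat
  }
  testable <- vapply(factors, nlevels, integer(1)) >= 2
  for (nm in names(factors)[!testable]) {
    warning("factor '", nm, "' has a single level; its test is skipped",
            call. = FALSE)
  }
  if (!any(testable)) stop("no testable factor", call. = FALSE)
  factors <- factors[testable]  # constant factors add nothing to the model

  X_full <- stats::model.matrix(
    stats::reformulate(names(factors)), data = as.data.frame(factors))
  full <- qr_basis(X_full)
  df_res <- n - full$rank
  if (df_res < 1) stop("no residual degrees of freedom", call. = FALSE)

  # permutation matrix of responses (shared across factors for a seed)
  set.seed(as.integer(seed))
  perm_idx <- if (is.null(strata)) {
    replicate(n_permutations, sample.int(n))
  } else {
    strata <- as.factor(as.character(strata))
    replicate(n_permutations, {
      idx <- seq_len(n)
      for (lev in levels(strata)) {
        w <- which(strata == lev)
        idx[w] <- w[sample.int(length(w))]
      }
      idx
    })
  }
  # center the response before the RSS computations: both models contain the
  # intercept, so F is unchanged, and centering avoids cancellation noise
  # that would break exact permutation ties for shifted count data
  resp_c <- response - mean(response)
  Y <- matrix(resp_c[perm_idx], nrow = n)

  rss_full_obs <- rss_cols(full$Q, cbind(resp_c))
  rss_full_perm <- rss_cols(full$Q, Y)

  rows <- list()
  for (nm in names(factors)) {
    others <- setdiff(names(factors), nm)
    X_red <- if (length(others) == 0) {
      matrix(1, n, 1)
    } else {
      stats::model.matrix(stats::reformulate(others),
                          data = as.data.frame(factors))
    }
    red <- qr_basis(X_red)
    df_num <- full$rank - red$rank
    f_from_rss <- function(rss_red, rss_full) {
      num <- (rss_red - rss_full) / df_num
      den <- rss_full / df_res
      f <- num / den
      f[den == 0 & num > 0] <- Inf
      f[den == 0 & num <= 0] <- 0
      pmax(f, 0)
    }
    f_obs <- f_from_rss(rss_cols(red$Q, cbind(resp_c)), rss_full_obs)
    if (!is.finite(f_obs)) {
      warning("zero residual variance; F for '", nm, "' is infinite",
              call. = FALSE)
    }
    f_perm <- f_from_rss(rss_cols(red$Q, Y), rss_full_perm)
    # permutation ties are exact in theory; compare with a small slack
    eps <- if (is.finite(f_obs)) 1e-8 * max(1, abs(f_obs)) else 0
    p <- (sum(f_perm >= f_obs - eps) + 1) / (n_permutations + 1)
    rows[[nm]] <- data.frame(factor = nm, df = df_num, F = f_obs,
                             p_value = p)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  structure(
    list(table = table,
         df_residual = df_res,
         group_means = tapply(response, status, mean),
         n_permutations = n_permutations,
         seed = as.integer(seed)),
    class = "perm_anova"
  )
}

#' @export
print.perm_anova <- function(x, ...) {
  cat("Permutational ANOVA (", x$n_permutations, " permutations of plots)\n",
      sep = "")
  tb <- x$table
  tb$F <- signif(tb$F, 5)
  tb$p_value <- signif(tb$p_value, 4)
  print(tb, row.names = FALSE)
  cat("residual df:", x$df_residual, "\n")
  cat("group means:",
      paste(sprintf("%s %.3f", names(x$group_means), x$group_means),
            collapse = ", "), "\n")
  invisible(x)
}
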