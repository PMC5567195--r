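# Independent brute-force oracles and small fixtures shared by the tests.
# Oracles transliterate the printed assessment rules or enumerate/recount
# directly; they never call the implementation paths they check.

# literal transliteration of the structures & functions threshold text
sf_rule_oracle <- function(n_present, checklist_size) {
  pct <- 100 * n_present / checklist_size
  if (pct > 50) return("FV")
  if (pct < 25) return("U2")
  "U1"
}

# literal transliteration of the pressures & threats rule text
pt_rule_oracle <- function(intensities) {
  n <- length(intensities)
  low_med <- all(intensities %in% c("low", "medium"))
  if (n == 0 || (n == 1 && low_med)) return("FV")
  if (n <= 3 && low_med) return("U1")
  "U2"
}

# all multisets of sizes 0..max_n drawn from the intensity levels
intensity_multisets <- function(max_n = 5) {
  out <- list(character(0))
  for (n in seq_len(max_n)) {
    combos <- utils::combn(length(c("low", "medium", "high")) + n - 1, n)
    # stars-and-bars enumeration of multisets of size n over 3 levels
    for (j in seq_len(ncol(combos))) {
      idx <- combos[, j] - seq_len(n) + 1
      out[[length(out) + 1]] <- c("low", "medium", "high")[idx]
    }
  }
  out
}

# one-way F via the independent reference implementation
f_oracle <- function(y, g) {
  stats::anova(stats::lm(y ~ factor(g)))[["F value"]][1]
}

# all permutations of 1..n (n! x n matrix), built recursively
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# exhaustive permutation p-value of the one-way F (identity included);
# per-permutation F uses the textbook SSB/SSW arithmetic directly
exhaustive_perm_p <- function(y, g) {
  g <- as.factor(g)
  n <- length(y)
  k <- nlevels(g)
  idx_by_group <- split(seq_len(n), g)
  f_basic <- function(yy) {
    fitted <- numeric(n)
    gm <- numeric(k)
    for (j in seq_len(k)) {
      ix <- idx_by_group[[j]]
      gm[j] <- mean(yy[ix])
      fitted[ix] <- gm[j]
    }
    ssb <- sum(lengths(idx_by_group) * (gm - mean(yy))^2)
    ssw <- sum((yy - fitted)^2)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- f_basic(y)
  stopifnot(abs(f_obs - f_oracle(y, g)) < 1e-8)  # cross-check the oracle
  perms <- all_permutations(n)
  f_all <- apply(perms, 1, function(idx) f_basic(y[idx]))
  mean(f_all >= f_obs - 1e-9)
}

# dense boundary sampling distance oracle for a single-ring polygon
dense_edge_distance <- function(point, ring, n_per_edge = 4000) {
  n <- nrow(ring)
  best <- Inf
  for (i in seq_len(n)) {
    a <- ring[i, ]
    b <- ring[if (i == n) 1 else i + 1, ]
    t <- seq(0, 1, length.out = n_per_edge)
    px <- a[1] + t * (b[1] - a[1])
    py <- a[2] + t * (b[2] - a[2])
    best <- min(best, sqrt(min((point[1] - px)^2 + (point[2] - py)^2)))
  }
  best
}

# ---- fixtures ------------------------------------------------------------

make_test_protocol <- function(n_structures = 10, n_species = 3,
                               weights = NULL) {
  if (is.null(weights)) weights <- rep(1, n_species)
  habitat_protocol(
    "9560",
    sf_checklist = data.frame(
      item_id = sprintf("sf%02d", seq_len(n_structures)),
      label = sprintf("item %d", seq_len(n_structures)),
      item_class = rep_len(c("natural_feature", "degradation_absence"),
                           n_structures)),
    typical_species = data.frame(
      species_id = LETTERS[seq_len(n_species)],
      weight = weights,
      growth_form = rep_len(c("woody", "herbaceous"), n_species)),
    pressure_catalogue = data.frame(
      activity_code = sprintf("act%02d", 1:6),
      label = sprintf("activity %d", 1:6)))
}

make_plot <- function(plot_id = "p1", observer_id = "o1",
                      observer_status = "expert", x = 50, y = 50,
                      structures = character(),
                      species = species_observations(),
                      pressures = pressure_records(),
                      habitat_code = "9560") {
  plot_record(plot_id, habitat_code, observer_id, observer_status, x, y,
              structures_present = structures, species_obs = species,
              pressures = pressures)
}

unit_square_100 <- function() {
  habitat_polygon(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
}

# survey where both groups record prescribed item sets
make_survey <- function(expert_items, nonexpert_items,
                        protocol = make_test_protocol()) {
  plots <- c(
    lapply(seq_along(expert_items), function(i) {
      make_plot(sprintf("e%d", i), sprintf("exp%d", i), "expert",
                structures = expert_items[[i]])
    }),
    lapply(seq_along(nonexpert_items), function(i) {
      make_plot(sprintf("n%d", i), sprintf("cit%d", i), "non_expert",
                structures = nonexpert_items[[i]])
    }))
  survey_dataset("TEST", "9560", plots, protocol)
}
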