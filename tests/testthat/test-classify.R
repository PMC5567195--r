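test_that("structures & functions thresholds follow the printed rule", {
  expect_identical(classify_structures_functions(6, 10), "FV")
  expect_identical(classify_structures_functions(5, 10), "U1")  # 50% is not > 50%
  expect_identical(classify_structures_functions(2, 10), "U2")
  expect_identical(classify_structures_functions(0, 7), "U2")
  expect_identical(classify_structures_functions(1, 4), "U1")   # 25% boundary
  expect_error(classify_structures_functions(5, 4), "n_present")
  expect_error(classify_structures_functions(1, 0), "checklist_size")
  expect_error(classify_structures_functions(-1, 4), "n_present")
})

test_that("structures & functions classifier matches the rule-text oracle exhaustively", {
  for (size in 1:12) {
    for (n in 0:size) {
      expect_identical(classify_structures_functions(n, size),
                       sf_rule_oracle(n, size),
                       info = sprintf("n=%d size=%d", n, size))
    }
  }
})

test_that("future-prospects classifier follows the printed rule", {
  expect_identical(classify_future_prospects(pressure_records()), "FV")
  expect_identical(
    classify_future_prospects(pressure_records("a", "medium")), "FV")
  expect_identical(
    classify_future_prospects(
      pressure_records(c("a", "b", "c"), c("low", "low", "medium"))), "U1")
  expect_identical(
    classify_future_prospects(pressure_records("a", "high")), "U2")
  expect_identical(
    classify_future_prospects(
      pressure_records(letters[1:4], rep("medium", 4))), "U2")
})

test_that("future-prospects classifier matches the rule-text oracle on all small multisets", {
  for (ints in intensity_multisets(5)) {
    got <- classify_future_prospects(
      pressure_records(letters[seq_along(ints)], ints))
    expect_identical(got, pt_rule_oracle(ints),
                     info = paste(ints, collapse = ","))
  }
})

test_that("typical-species score matches hand arithmetic and handles edge cases", {
  prot <- make_test_protocol(n_species = 3, weights = c(2, 1, 1))
  obs <- species_observations(c("A", "C"), c("frequent", "rare"),
                              c("good", "moderate"))
  # (2 * 0.75 * 1.0 + 1 * 0.25 * 0.75) / 4
  expect_equal(score_typical_species(obs, prot), 0.421875)

  full <- species_observations(c("A", "B", "C"), rep("abundant", 3),
                               rep("good", 3))
  expect_equal(score_typical_species(full, prot), 1.0)
  expect_equal(score_typical_species(species_observations(), prot), 0.0)

  off_list <- species_observations(c("A", "Z"), c("abundant", "rare"),
                                   c("good", "poor"))
  expect_warning(s <- score_typical_species(off_list, prot), "Z")
  expect_equal(s, 2 / 4)

  empty_prot <- prot
  empty_prot$typical_species <- empty_prot$typical_species[0, ]
  expect_error(score_typical_species(obs, empty_prot), "typical_species")
})

test_that("typical-species classification reuses the 0.5 / 0.25 thresholds", {
  expect_identical(classify_typical_species(1.0), "FV")
  expect_identical(classify_typical_species(0.0), "U2")
  expect_identical(classify_typical_species(0.421875), "U1")
  expect_identical(classify_typical_species(0.5), "U1")
  expect_identical(classify_typical_species(0.25), "U1")
  expect_error(classify_typical_species(1.2), "ts_score")
})

test_that("plot assessment composes the criteria with a worst-case overall", {
  prot <- make_test_protocol(n_structures = 10, n_species = 3)
  full_sp <- species_observations(c("A", "B", "C"), rep("abundant", 3),
                                  rep("good", 3))
  p_fv <- make_plot(structures = sprintf("sf%02d", 1:6), species = full_sp)
  a <- assess_plot(p_fv, prot)
  expect_identical(c(a$sf_status, a$ts_status, a$pt_status,
                     a$overall_status), rep("FV", 4))
  expect_equal(a$sf_fraction, 0.6)

  p_nosp <- make_plot(structures = sprintf("sf%02d", 1:6))
  expect_identical(assess_plot(p_nosp, prot)$overall_status, "U2")

  p_bad <- make_plot(structures = sprintf("sf%02d", 1:2), species = full_sp,
                     pressures = pressure_records("x", "high"))
  a <- assess_plot(p_bad, prot)
  expect_identical(a$sf_status, "U2")
  expect_identical(a$pt_status, "U2")
  expect_identical(a$overall_status, "U2")

  p_wrong <- make_plot(habitat_code = "2120")
  expect_error(assess_plot(p_wrong, prot), "2120.*9560|9560.*2120")
})

test_that("assessment is deterministic and survey assessment is plot-wise", {
  prot <- make_test_protocol()
  sp <- species_observations("A", "frequent", "good")
  p <- make_plot(structures = sprintf("sf%02d", 1:4), species = sp)
  expect_identical(assess_plot(p, prot), assess_plot(p, prot))

  ds <- make_survey(list(sprintf("sf%02d", 1:6)), list("sf01"))
  out <- assess_survey(ds)
  expect_equal(nrow(out), 2)
  expect_identical(out$sf_status, c("FV", "U2"))
  expect_identical(out$overall_status, c("U2", "U2"))  # no species recorded
})

test_that("status helpers order FV < U1 < U2 by badness", {
  expect_identical(worst_status("FV", "U1", "FV"), "U1")
  expect_identical(worst_status("FV"), "FV")
  expect_identical(worst_status("U1", "U2"), "U2")
  expect_error(status_factor("XX"), "invalid status")
  expect_true(status_factor("FV") < status_factor("U2"))
})

test_that("classifiers are monotone in their inputs", {
  set.seed(42)
  prot <- make_test_protocol(n_species = 5, weights = c(3, 2, 1, 1, 2))
  badness <- function(s) match(s, STATUS_LEVELS)
  for (rep in 1:50) {
    size <- sample(3:12, 1)
    n <- sample(0:(size - 1), 1)
    expect_lte(
      badness(classify_structures_functions(n + 1, size)),
      badness(classify_structures_functions(n, size)))

    n_pr <- sample(0:4, 1)
    ints <- sample(c("low", "medium", "high"), n_pr, replace = TRUE)
    before <- classify_future_prospects(
      pressure_records(letters[seq_len(n_pr)], ints))
    after <- classify_future_prospects(
      pressure_records(letters[seq_len(n_pr + 1)],
                       c(ints, sample(c("low", "medium", "high"), 1))))
    expect_gte(badness(after), badness(before))

    k <- sample(1:5, 1)
    ids <- sample(LETTERS[1:5], k)
    lev <- c("rare", "occasional", "frequent", "abundant")
    ab <- sample(lev, k, replace = TRUE)
    vi <- sample(c("poor", "moderate", "good"), k, replace = TRUE)
    s0 <- score_typical_species(species_observations(ids, ab, vi), prot)
    j <- sample(k, 1)
    ab2 <- ab
    ab2[j] <- lev[min(match(ab[j], lev) + 1, 4)]
    s1 <- score_typical_species(species_observations(ids, ab2, vi), prot)
    expect_gte(s1, s0)
    # order invariance
    ord <- sample(k)
    expect_equal(
      score_typical_species(species_observations(ids[ord], ab[ord],
                                                 vi[ord]), prot), s0)
  }
})
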