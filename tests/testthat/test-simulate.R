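test_that("generated protocols have the requested shape and are seed-deterministic", {
  p <- generate_protocol(10, 8, 6, seed = 7)
  expect_equal(nrow(p$sf_checklist), 10)
  expect_equal(nrow(p$typical_species), 8)
  expect_equal(nrow(p$pressure_catalogue), 6)
  expect_true(all(p$typical_species$weight %in% 1:3))
  expect_equal(sum(p$typical_species$growth_form == "woody"), 4)

  expect_identical(generate_protocol(10, 8, 6, seed = 7), p)
  others <- vapply(1:100, function(s) {
    identical(generate_protocol(10, 8, 6, seed = s)$typical_species$weight,
              p$typical_species$weight)
  }, logical(1))
  expect_lt(mean(others), 0.5)  # different seeds give different weights
})

test_that("plot placement respects the polygon and the edge-bias scale", {
  sq <- unit_square_100()
  pts_unif <- sample_plot_locations(sq, 400, lambda = Inf, seed = 1)
  d_unif <- apply(pts_unif, 1, distance_to_edge, polygon = sq)
  expect_true(all(d_unif > 0))

  pts_edge <- sample_plot_locations(sq, 400, lambda = 1, seed = 1)
  d_edge <- apply(pts_edge, 1, distance_to_edge, polygon = sq)
  expect_lt(mean(d_edge), mean(d_unif))
  expect_lt(mean(d_edge), 5)          # lambda = 1 m hugs the boundary
  expect_gt(mean(d_unif), 15)         # uniform mean in a 100 m square = 50/3

  expect_identical(sample_plot_locations(sq, 10, lambda = 5, seed = 3),
                   sample_plot_locations(sq, 10, lambda = 5, seed = 3))
})

test_that("latent truth follows the condition gradient", {
  sq <- unit_square_100()
  prot <- generate_protocol(10, 8, 6, seed = 2)
  # steep gradient, interior point: logistic argument > 6 -> all present
  t_core <- generate_truth(c(50, 50), prot, sq,
                           gradient = list(alpha = 0, beta = 1), seed = 4)
  expect_setequal(t_core$items_true, prot$sf_checklist$item_id)
  expect_equal(nrow(t_core$species_true), 8)
  expect_equal(t_core$d_edge, 50)

  expect_identical(
    generate_truth(c(30, 40), prot, sq, seed = 9),
    generate_truth(c(30, 40), prot, sq, seed = 9))

  # flat gradient: presence probability independent of location
  set.seed(1)
  n_core <- mean(vapply(1:200, function(i) {
    length(generate_truth(c(50, 50), prot, sq,
                          gradient = list(alpha = 0.5, beta = 0),
                          seed = i)$items_true)
  }, numeric(1)))
  n_edge <- mean(vapply(1:200, function(i) {
    length(generate_truth(c(1, 50), prot, sq,
                          gradient = list(alpha = 0.5, beta = 0),
                          seed = 10000 + i)$items_true)
  }, numeric(1)))
  expect_lt(abs(n_core - n_edge), 1)
})

test_that("observation thins truth by detection probability", {
  sq <- unit_square_100()
  prot <- generate_protocol(20, 8, 6, seed = 2)
  truth <- generate_truth(c(50, 50), prot, sq,
                          gradient = list(alpha = 0, beta = 1), seed = 4)
  perfect <- observer_model("expert",
                            detect_prob = c(woody = 1, herbaceous = 1,
                                            structure = 1, pressure = 1),
                            false_positive_rate = 0)
  rec <- simulate_observation(truth, perfect, prot, "p1", "o1", seed = 5)
  expect_setequal(rec$structures_present, truth$items_true)
  expect_equal(sort(rec$species_obs$species_id),
               sort(truth$species_true$species_id))
  expect_setequal(rec$pressures$activity_code,
                  truth$pressures_true$activity_code)

  blind <- observer_model("non_expert",
                          detect_prob = c(woody = 0, herbaceous = 0,
                                          structure = 0, pressure = 0),
                          false_positive_rate = 0)
  rec0 <- simulate_observation(truth, blind, prot, "p1", "o1", seed = 5)
  expect_length(rec0$structures_present, 0)
  expect_equal(nrow(rec0$species_obs), 0)
  expect_equal(nrow(rec0$pressures), 0)

  # binomial thinning: 20-item truth at detection 0.5
  half <- observer_model("non_expert",
                         detect_prob = c(woody = 0.5, herbaceous = 0.5,
                                         structure = 0.5, pressure = 0.5),
                         false_positive_rate = 0)
  rich <- vapply(1:2000, function(i) {
    length(simulate_observation(truth, half, prot, "p", "o",
                                seed = i)$structures_present)
  }, numeric(1))
  expect_lt(abs(mean(rich) - 10), 0.3)
})

test_that("seasonal factor suppresses herbaceous but not woody detections", {
  sq <- unit_square_100()
  prot <- generate_protocol(5, 10, 6, prop_woody = 0.5, seed = 2)
  truth <- generate_truth(c(50, 50), prot, sq,
                          gradient = list(alpha = 0, beta = 1), seed = 4)
  autumn <- observer_model("non_expert",
                           detect_prob = c(woody = 1, herbaceous = 1,
                                           structure = 1, pressure = 1),
                           season_factor = 0, false_positive_rate = 0)
  rec <- simulate_observation(truth, autumn, prot, "p1", "o1", seed = 6)
  forms <- prot$typical_species$growth_form[
    match(rec$species_obs$species_id, prot$typical_species$species_id)]
  expect_true(all(forms == "woody"))
  expect_equal(sum(prot$typical_species$growth_form == "woody"),
               nrow(rec$species_obs))
})

test_that("false positives are recorded in the lowest condition classes", {
  sq <- unit_square_100()
  prot <- generate_protocol(10, 8, 6, seed = 2)
  # nothing truly present, observer hallucinating half the items
  truth <- generate_truth(c(1, 1), prot, sq,
                          gradient = list(alpha = -30, beta = 0,
                                          pressure_rate_edge = 0),
                          seed = 4)
  expect_length(truth$items_true, 0)
  fp <- observer_model("non_expert", false_positive_rate = 0.5)
  rec <- simulate_observation(truth, fp, prot, "p1", "o1", seed = 8)
  expect_gt(nrow(rec$species_obs), 0)
  expect_true(all(rec$species_obs$abundance == "rare"))
  expect_true(all(rec$species_obs$vitality == "poor"))
  expect_true(all(rec$pressures$intensity == "low"))
})

test_that("survey simulation keeps the observer bookkeeping of the design", {
  cfg <- simulation_config(n_expert_plots = 6, n_nonexpert_plots = 30,
                           n_experts = 2, seed = 123)
  ds <- simulate_survey(cfg)
  expect_s3_class(ds, "survey_dataset")
  expect_length(ds$plots, 36)
  st <- vapply(ds$plots, function(p) p$observer_status, character(1))
  expect_equal(sum(st == "expert"), 6)
  ids <- vapply(ds$plots, function(p) p$observer_id, character(1))
  expect_equal(length(unique(ids)), 32)   # 2 experts + 30 citizens
  expect_equal(length(unique(ids[st == "non_expert"])), 30)
  expect_length(attr(ds, "truths"), 36)

  # full determinism
  expect_identical(serialize(simulate_survey(cfg), NULL),
                   serialize(simulate_survey(cfg), NULL))
})

test_that("asymmetric detection yields expert-dominant per-plot richness", {
  hits <- vapply(1:25, function(s) {
    ds <- simulate_survey(simulation_config(
      n_expert_plots = 6, n_nonexpert_plots = 30, seed = 5000 + s))
    tab <- build_incidence(ds, "structure_function")
    rich <- per_plot_richness(tab)
    mean(rich[tab$observer_status == "expert"]) >
      mean(rich[tab$observer_status == "non_expert"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
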