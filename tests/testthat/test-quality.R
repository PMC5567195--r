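test_that("incidence table transcribes plots and keeps the full checklist", {
  prot <- make_test_protocol(n_structures = 3)
  ds <- make_survey(list(c("sf01", "sf02")), list("sf02"), prot)
  tab <- build_incidence(ds, "structure_function")
  expect_equal(dim(tab$matrix), c(2, 3))
  expect_equal(unname(tab$matrix["e1", ]), c(1L, 1L, 0L))
  expect_equal(unname(tab$matrix["n1", ]), c(0L, 1L, 0L))
  expect_identical(colnames(tab$matrix), c("sf01", "sf02", "sf03"))
  expect_error(build_incidence(ds, "bogus"))

  # empty plot gives an all-zero row; cardinality is preserved
  ds2 <- make_survey(list(character()), list("sf01", "sf03"), prot)
  tab2 <- build_incidence(ds2, "structure_function")
  expect_equal(nrow(tab2$matrix), 3)
  expect_equal(sum(tab2$matrix["e1", ]), 0)
})

test_that("per-plot richness equals an independent recount", {
  set.seed(7)
  items <- sprintf("sf%02d", 1:10)
  sets <- replicate(12, sample(items, sample(0:10, 1)), simplify = FALSE)
  ds <- make_survey(sets[1:4], sets[5:12])
  tab <- build_incidence(ds, "structure_function")
  rich <- per_plot_richness(tab)
  manual <- vapply(ds$plots, function(p) length(p$structures_present),
                   integer(1))
  expect_equal(unname(rich), manual)
})

test_that("pooled items are the union over a group's plots", {
  ds <- make_survey(list(c("sf01", "sf02"), c("sf02", "sf03")),
                    list("sf04"))
  tab <- build_incidence(ds, "structure_function")
  expect_setequal(pooled_items(tab, "expert"), c("sf01", "sf02", "sf03"))
  expect_setequal(pooled_items(tab, "non_expert"), "sf04")
  expect_gte(length(pooled_items(tab, "expert")),
             max(per_plot_richness(tab)[tab$observer_status == "expert"]))
})

test_that("completeness contrasts per-plot and pooled views", {
  same <- list(c("sf01", "sf02", "sf03"))
  ds <- make_survey(same, same)
  comp <- completeness(ds, "structure_function")
  expect_equal(comp$per_plot, 1.0)
  expect_equal(comp$pooled, 1.0)

  ds0 <- make_survey(same, list(character()))
  comp0 <- completeness(ds0, "structure_function")
  expect_equal(comp0$per_plot, 0.0)
  expect_equal(comp0$pooled, 0.0)

  ds_err <- make_survey(list(character()), same)
  expect_error(completeness(ds_err, "structure_function"), "expert")
})

test_that("accuracy is the corroborated fraction of distinct non-expert items", {
  ds <- make_survey(list(c("sf01", "sf02", "sf03")),
                    list(c("sf01", "sf02", "sf09")))
  expect_equal(accuracy(ds, "structure_function"), 2 / 3)
  expect_equal(accuracy(ds, "structure_function",
                        reference_set = "sf09"), 1.0)

  subset_ds <- make_survey(list(c("sf01", "sf02")), list("sf01"))
  expect_equal(accuracy(subset_ds, "structure_function"), 1.0)

  disjoint <- make_survey(list("sf01"), list("sf02"))
  expect_equal(accuracy(disjoint, "structure_function"), 0.0)

  silent <- make_survey(list("sf01"), list(character()))
  expect_error(accuracy(silent, "structure_function"), "no items")
})

test_that("support counts distinct observers, not plots or records", {
  prot <- make_test_protocol()
  plots <- list(
    make_plot("e1", "exp1", "expert", structures = "sf01"),
    make_plot("n1", "cit1", "non_expert", structures = c("sf01", "sf02")),
    make_plot("n2", "cit2", "non_expert", structures = "sf01"),
    make_plot("n3", "cit3", "non_expert", structures = "sf01"),
    make_plot("n4", "cit1", "non_expert", structures = "sf02"))
  ds <- survey_dataset("TEST", "9560", plots, prot)
  sup <- support_counts(ds, "structure_function")
  expect_equal(sup[["sf01"]], 3)   # three distinct non-expert observers
  expect_equal(sup[["sf02"]], 1)   # cit1 twice counts once
  expect_false("sf03" %in% names(sup))

  set.seed(11)
  # randomized recount oracle
  big <- survey_dataset("T", "9560", c(list(plots[[1]]), lapply(1:20,
    function(i) {
      make_plot(paste0("r", i), paste0("cit", sample(8, 1)), "non_expert",
                structures = sample(sprintf("sf%02d", 1:5),
                                    sample(1:4, 1)))
    })), prot)
  sup_big <- support_counts(big, "structure_function")
  for (item in names(sup_big)) {
    obs <- unique(unlist(lapply(big$plots, function(p) {
      if (p$observer_status == "non_expert" &&
          item %in% p$structures_present) p$observer_id else NULL
    })))
    expect_equal(unname(sup_big[item]), length(obs), info = item)
  }
})

test_that("low-support flagging is a monotone threshold scan that only marks", {
  sup <- c(A = 1, B = 3, C = 2)
  expect_identical(flag_low_support(sup, 2), "A")
  expect_identical(flag_low_support(sup, 1), character(0))
  expect_setequal(flag_low_support(sup, 4), c("A", "B", "C"))
  for (k in 1:4) {
    expect_true(all(flag_low_support(sup, k) %in%
                    flag_low_support(sup, k + 1)))
  }
  expect_error(flag_low_support(sup, 0), "min_observers")
  expect_identical(flag_low_support(integer(0), 2), character(0))
})

test_that("group comparison assembles a consistent report", {
  ds <- make_survey(list(c("sf01", "sf02"), c("sf02", "sf03")),
                    list(c("sf01", "sf09"), c("sf01")))
  rep <- compare_groups(ds, "structure_function")
  expect_setequal(rep$items_shared, "sf01")
  expect_setequal(rep$items_only_experts, c("sf02", "sf03"))
  expect_setequal(rep$items_only_nonexperts, "sf09")
  expect_length(intersect(rep$items_shared, rep$items_only_experts), 0)
  expect_identical(rep$flagged_items, "sf09")
  expect_equal(rep$accuracy, 1 / 2)  # of {sf01, sf09}, only sf01 corroborated

  same <- list(c("sf01", "sf02"))
  id <- compare_groups(make_survey(same, same), "structure_function")
  expect_equal(id$completeness_per_plot, 1)
  expect_equal(id$completeness_pooled, 1)
  expect_equal(id$accuracy, 1)
  expect_length(id$items_only_experts, 0)
  expect_length(id$items_only_nonexperts, 0)

  disjoint <- compare_groups(make_survey(list("sf01"), list("sf02")),
                             "structure_function")
  expect_length(disjoint$items_shared, 0)
})
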