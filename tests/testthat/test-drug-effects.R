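test_that("drugs map only to gene-associated reactions of analog metabolites", {
  m <- screening_model()
  drugs <- fixture_drugs()
  mets <- fixture_metabolites()
  # drug_syn is an analog of metabolite A -> uptake and both pathways,
  # but not the biomass sink (no gene association) even though A-derived
  # C participates there
  tm <- map_drug_to_reactions(drugs[drugs$id == "drug_syn", ], m, mets)
  expect_setequal(tm$reaction, c("EX_A", "P1", "P2"))
  expect_true(all(tm$provenance == "metabolite_analogy"))
  expect_false("BIO" %in% tm$reaction)

  # substrate-only narrows to reactions consuming the analog
  tms <- map_drug_to_reactions(drugs[drugs$id == "drug_syn", ], m, mets,
                               substrate_only = TRUE)
  expect_setequal(tms$reaction, c("P1", "P2"))

  # no analog and no annotation: empty map with a warning
  expect_warning(
    tm0 <- map_drug_to_reactions(drugs[drugs$id == "drug_far", ], m, mets),
    "no reaction")
  expect_identical(nrow(tm0), 0L)
})

test_that("currency metabolites are excluded from analogy mapping", {
  m <- screening_model()
  # pretend metabolite A is ATP: its analog must not yield targets
  m$metabolites$kegg_id[m$metabolites$id == "A"] <- "C00002"
  mets <- fixture_metabolites()
  mets$id[mets$id == "C90001"] <- "C00002"
  expect_warning(
    tm <- map_drug_to_reactions(fixture_drugs()[1, ], m, mets),
    "no reaction")
  expect_identical(nrow(tm), 0L)
})

test_that("annotated EC targets add reactions through the gene-EC map", {
  m <- screening_model()
  gene_ec <- tibble::tibble(gene = "g_hk", ec = "1.1.1.1")
  drugs <- fixture_drugs()
  tm <- map_drug_to_reactions(drugs[drugs$id == "drug_syn", ], m,
                              fixture_metabolites(),
                              gene_ec_map = gene_ec)
  ann <- tm[tm$provenance == "annotated_target", ]
  expect_identical(ann$reaction, "EX_D")
})

test_that("baseline modes agree on a unique-optimum model and are seeded", {
  m <- toy_chain_model()
  b1 <- baseline_rates(m, "R2", mode = "single_lp")
  b2 <- baseline_rates(m, "R2", mode = "vertex_mean", n = 10, seed = 1)
  expect_equal(unname(b1), 0.027, tolerance = 1e-9)
  expect_equal(unname(b2), 0.027, tolerance = 1e-4)
  expect_identical(baseline_rates(m, "R2", n = 5, seed = 2),
                   baseline_rates(m, "R2", n = 5, seed = 2))
})

test_that("inhibition rescales bounds by one minus i", {
  m <- toy_parallel_model()
  bl <- c(P1 = 0.05)
  g <- function(mm, id, col) mm$reactions[[col]][mm$reactions$id == id]
  expect_equal(g(apply_inhibition(m, bl, 0), "P1", "upper_bound"), 0.05)
  expect_equal(g(apply_inhibition(m, bl, 0.9), "P1", "upper_bound"), 0.005)
  expect_equal(g(apply_inhibition(m, bl, 1), "P1", "upper_bound"), 0)
  expect_error(apply_inhibition(m, bl, 1.2), "\\[0, 1\\]")
  # zero-baseline target is pinned at zero for any positive inhibition
  expect_equal(g(apply_inhibition(m, c(P1 = 0), 0.5), "P1", "upper_bound"), 0)
  # original model unmutated
  expect_equal(g(m, "P1", "upper_bound"), 0.05)
})

test_that("relative growth reproduces the hand LP values", {
  expect_equal(relative_growth(toy_chain_model(), "R2", 0),
               1, tolerance = 1e-5)
  expect_equal(relative_growth(toy_chain_model(), "R2", 0.9,
                               mode = "single_lp"),
               0.1, tolerance = 1e-7)
  # parallel-pathway compensation: 0.0525 / 0.075
  expect_equal(relative_growth(toy_parallel_model(), "P1", 0.9,
                               mode = "single_lp"),
               0.70, tolerance = 1e-7)
  # no growth to inhibit is an error
  m0 <- toy_chain_model()
  m0$reactions$upper_bound[1] <- 0
  expect_error(relative_growth(m0, "R2", 0.5), "no growth")
})

test_that("sweep uses a 1001-point default grid with correct endpoints", {
  sw <- inhibition_sweep(toy_chain_model(), "R2", mode = "single_lp")
  expect_identical(nrow(sw), 1001L)
  expect_equal(sw$inhibition[2] - sw$inhibition[1], 0.001)
  expect_equal(sw$relative_growth[1], 1, tolerance = 1e-6)
  # single pathway: the curve is exactly 1 - i
  expect_equal(sw$relative_growth, 1 - sw$inhibition, tolerance = 1e-6)
  expect_error(inhibition_sweep(toy_chain_model(), character(0)),
               "empty target set")
})

test_that("sweep curves are monotone and floored at 1 - i on every fixture", {
  grid <- seq(0, 1, by = 0.02)
  for (m in list(toy_chain_model(), toy_parallel_model(),
                 screening_model())) {
    targets <- if ("P1" %in% m$reactions$id) "P1" else "R2"
    sw <- inhibition_sweep(m, targets, grid = grid, mode = "single_lp")
    expect_true(all(diff(sw$relative_growth) <= 1e-7))
    expect_true(all(sw$relative_growth >= 1 - sw$inhibition - 1e-6))
    expect_true(all(sw$relative_growth <= 1 + 1e-6))
  }
  # parallel fixture: strict compensation above the floor at i = 0.9
  swp <- inhibition_sweep(toy_parallel_model(), "P1", grid = grid,
                          mode = "single_lp")
  expect_gt(swp$relative_growth[swp$inhibition == 0.9], 0.1 + 0.05)
})

test_that("targets with zero optimal flux are fully compensable", {
  # backup pathway carries no flux at the optimum; inhibiting it is free
  m <- make_toy_model(fixture_spec(n_pathways = 2,
                                   pathway_efficiencies = c(1, 2),
                                   pathway_bounds = c(10, 10),
                                   uptake_bound = 0.1))
  sw <- inhibition_sweep(m, "P2", grid = seq(0, 1, by = 0.1))
  expect_equal(sw$relative_growth, rep(1, 11), tolerance = 1e-6)
})

test_that("more backup capacity gives pointwise higher curves", {
  grid <- seq(0, 1, by = 0.05)
  weak <- make_toy_model(fixture_spec(pathway_bounds = c(0.05, 0.01),
                                      pathway_efficiencies = c(1, 2)))
  strong <- make_toy_model(fixture_spec(pathway_bounds = c(0.05, 10),
                                        pathway_efficiencies = c(1, 2)))
  sww <- inhibition_sweep(weak, "P1", grid = grid, mode = "single_lp")
  sws <- inhibition_sweep(strong, "P1", grid = grid, mode = "single_lp")
  expect_true(all(sws$relative_growth >= sww$relative_growth - 1e-7))
})
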