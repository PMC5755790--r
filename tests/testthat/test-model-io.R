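test_that("model construction enforces id uniqueness and stoichiometry", {
  mets <- tibble::tibble(id = c("A", "B"))
  rxns <- tibble::tibble(
    id = c("R1", "R1"),
    stoichiometry = list(c(A = 1), c(A = -1, B = 1))
  )
  expect_error(metabolic_model(mets, rxns, biomass = "R1"),
               "duplicate reaction id")

  rxns2 <- tibble::tibble(id = "R1", stoichiometry = list(c(X = 1)))
  expect_error(metabolic_model(mets, rxns2, biomass = "R1"),
               "unknown metabolite")
})

test_that("biomass resolution: pattern match, ambiguity, explicit id", {
  mets <- tibble::tibble(id = "A")
  rxns <- tibble::tibble(
    id = c("R1", "biomass_rxn"),
    stoichiometry = list(c(A = 1), c(A = -1))
  )
  m <- metabolic_model(mets, rxns)
  expect_equal(m$biomass_reaction_id, "biomass_rxn")

  rxns$id <- c("biomass_a", "biomass_b")
  expect_error(metabolic_model(mets, rxns), "ambiguous")
  expect_equal(
    metabolic_model(mets, rxns, biomass = "biomass_a")$biomass_reaction_id,
    "biomass_a")
  expect_error(metabolic_model(mets, rxns, biomass = "nope"),
               "not in model")
})

test_that("stoichiometric matrix matches construction and excludes boundary rows", {
  m <- toy_chain_model()
  S <- stoichiometric_matrix(m)
  expect_identical(dim(S), c(2L, 3L))
  expect_equal(unname(S), rbind(c(1, -1, 0), c(0, 1, -1)))

  # boundary metabolite dropped as row; exchange column single nonzero
  mets <- tibble::tibble(id = c("A", "Ax"), boundary = c(FALSE, TRUE))
  rxns <- tibble::tibble(
    id = c("EX", "BIO"),
    stoichiometry = list(c(Ax = -1, A = 1), c(A = -1))
  )
  m2 <- metabolic_model(mets, rxns, biomass = "BIO")
  S2 <- stoichiometric_matrix(m2)
  expect_identical(rownames(S2), "A")
  expect_equal(sum(S2[, "EX"] != 0), 1)
  expect_true("EX" %in% m2$exchange_reaction_ids)
})

test_that("validate_model reports inversions and orphans, never mutates", {
  m <- toy_chain_model()
  expect_identical(nrow(validate_model(m)), 0L)

  m$reactions$lower_bound[2] <- 1
  m$reactions$upper_bound[2] <- 0.5
  d <- validate_model(m)
  expect_identical(d$type, "bound_inversion")
  expect_identical(d$id, "R2")

  mets <- tibble::tibble(id = c("A", "Z"))
  rxns <- tibble::tibble(id = c("R1", "BIO"),
                         stoichiometry = list(c(A = 1), c(A = -1)),
                         genes = list("g1", character(0)))
  m2 <- metabolic_model(mets, rxns, biomass = "BIO")
  d2 <- validate_model(m2)
  expect_true(any(d2$type == "orphan_metabolite" & d2$id == "Z"))
})

test_that("SBML round trip preserves stoichiometry, bounds, genes, KEGG ids", {
  for (m in list(toy_chain_model(), toy_parallel_model())) {
    f <- withr::local_tempfile(fileext = ".xml")
    write_sbml_model(m, f)
    m2 <- read_sbml_model(f)
    expect_identical(stoichiometric_matrix(m2), stoichiometric_matrix(m))
    expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
    expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
    expect_identical(m2$reactions$genes, m$reactions$genes)
    expect_identical(m2$metabolites$kegg_id, m$metabolites$kegg_id)
    expect_identical(m2$biomass_reaction_id, m$biomass_reaction_id)
  }
})

test_that("SBML reader defaults bounds when the file declares none", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="m"><listOfCompartments><compartment id="c"/>',
    '</listOfCompartments><listOfSpecies>',
    '<species id="A" compartment="c"/><species id="B" compartment="c"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R_rev" reversible="true">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R_irr" reversible="false">',
    '<listOfProducts><speciesReference species="A"/></listOfProducts>',
    '</reaction>',
    '<reaction id="biomass" reversible="false">',
    '<listOfReactants><speciesReference species="B"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), f)
  m <- read_sbml_model(f)
  rev <- m$reactions[m$reactions$id == "R_rev", ]
  irr <- m$reactions[m$reactions$id == "R_irr", ]
  expect_equal(c(rev$lower_bound, rev$upper_bound), c(-1000, 1000))
  expect_equal(c(irr$lower_bound, irr$upper_bound), c(0, 1000))
  expect_identical(m$biomass_reaction_id, "biomass")
})

test_that("SBML reader rejects duplicate reaction ids", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="m"><listOfSpecies><species id="A" compartment="c"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R1"><listOfProducts>',
    '<speciesReference species="A"/></listOfProducts></reaction>',
    '<reaction id="R1"><listOfReactants>',
    '<speciesReference species="A"/></listOfReactants></reaction>',
    '</listOfReactions></model></sbml>'), f)
  expect_error(read_sbml_model(f), "duplicate reaction id")
})

test_that("expression profiles parse TSV and CSV, reject bad values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\trpkm", "g1\t25", "g2\t0"), f)
  p <- read_expression_profile(f)
  expect_equal(p$rpkm[match(c("g1", "g2"), p$gene)], c(25, 0))

  fc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,rpkm", "g1,3.5"), fc)
  expect_equal(read_expression_profile(fc)$rpkm, 3.5)

  fneg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\trpkm", "g1\t-3"), fneg)
  expect_error(read_expression_profile(fneg), "negative")

  fbad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\trpkm", "g1\tabc"), fbad)
  expect_error(read_expression_profile(fbad), "non-numeric")

  femp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), femp)
  expect_error(read_expression_profile(femp), "empty")
})

test_that("duplicate gene rows keep the maximum with a warning", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\trpkm", "g1\t5", "g1\t9", "g2\t1"), f)
  expect_warning(p <- read_expression_profile(f), "duplicate")
  expect_equal(p$rpkm[p$gene == "g1"], 9)
})
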