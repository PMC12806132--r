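test_that("JSON round-trip preserves structure", {
  m <- five_rxn_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(nrow(m2$metabolites), 3)
  expect_length(m2$reactions, 5)
  expect_equal(length(model_genes(m2)), 5)
  expect_equal(m2$objective_id, "BIO")
  for (id in reaction_ids(m)) {
    expect_equal(sort(m2$reactions[[id]]$stoichiometry),
                 sort(m$reactions[[id]]$stoichiometry))
    expect_equal(m2$reactions[[id]]$lower_bound, m$reactions[[id]]$lower_bound)
    expect_equal(m2$reactions[[id]]$upper_bound, m$reactions[[id]]$upper_bound)
    expect_equal(m2$reactions[[id]]$subsystem, m$reactions[[id]]$subsystem)
    expect_identical(m2$reactions[[id]]$gpr, m$reactions[[id]]$gpr)
  }
})

test_that("model invariants are enforced", {
  mets <- data.frame(id = "A", name = "A", compartment = "c",
                     stringsAsFactors = FALSE)
  bad_stoich <- list(list(id = "R1", stoichiometry = c(ZZZ = 1),
                          lower_bound = 0, upper_bound = 1,
                          subsystem = NA_character_, gpr = NULL))
  expect_error(metabolic_model(mets, bad_stoich, "R1"),
               "unknown metabolite")
  bad_bounds <- list(list(id = "R1", stoichiometry = c(A = 1),
                          lower_bound = 5, upper_bound = 1,
                          subsystem = NA_character_, gpr = NULL))
  expect_error(metabolic_model(mets, bad_bounds, "R1"), "lower_bound")
  ok <- list(list(id = "R1", stoichiometry = c(A = 1), lower_bound = 0,
                  upper_bound = 1, subsystem = NA_character_, gpr = NULL))
  expect_error(metabolic_model(mets, ok, "nope"), "objective")
})

test_that("read_model reports a parse error for malformed files", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites": [{"id": "A", "compartment": "c"}],
    "reactions": [{"id": "R1", "metabolites": {"B": 1},
    "objective_coefficient": 1}]}', path)
  expect_error(read_model(path), "unknown metabolite")
  writeLines("{not json", path)
  expect_error(read_model(path), "malformed")
  expect_error(read_model("/nonexistent/file.json"), "not found")
})

test_that("SBML L3 FBC models are read", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
<model id="mini" fbc:strict="true">
 <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
 <listOfSpecies>
  <species id="A" compartment="c" name="metA" hasOnlySubstanceUnits="false"
           boundaryCondition="false" constant="false"/>
  <species id="B" compartment="c" name="metB" hasOnlySubstanceUnits="false"
           boundaryCondition="false" constant="false"/>
 </listOfSpecies>
 <listOfParameters>
  <parameter id="lb0" value="0" constant="true"/>
  <parameter id="ub10" value="10" constant="true"/>
  <parameter id="ubbig" value="1000" constant="true"/>
 </listOfParameters>
 <fbc:listOfGeneProducts>
  <fbc:geneProduct fbc:id="gp1" fbc:label="geneA"/>
  <fbc:geneProduct fbc:id="gp2" fbc:label="geneB"/>
 </fbc:listOfGeneProducts>
 <listOfReactions>
  <reaction id="EXA" reversible="false" fast="false"
            fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub10">
   <listOfProducts>
    <speciesReference species="A" stoichiometry="1" constant="true"/>
   </listOfProducts>
  </reaction>
  <reaction id="R1" reversible="false" fast="false"
            fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ubbig">
   <listOfReactants>
    <speciesReference species="A" stoichiometry="1" constant="true"/>
   </listOfReactants>
   <listOfProducts>
    <speciesReference species="B" stoichiometry="1" constant="true"/>
   </listOfProducts>
   <fbc:geneProductAssociation>
    <fbc:and>
     <fbc:geneProductRef fbc:geneProduct="gp1"/>
     <fbc:geneProductRef fbc:geneProduct="gp2"/>
    </fbc:and>
   </fbc:geneProductAssociation>
  </reaction>
  <reaction id="BIO" reversible="false" fast="false"
            fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ubbig">
   <listOfReactants>
    <speciesReference species="B" stoichiometry="1" constant="true"/>
   </listOfReactants>
  </reaction>
 </listOfReactions>
 <fbc:listOfObjectives fbc:activeObjective="obj">
  <fbc:objective fbc:id="obj" fbc:type="maximize">
   <fbc:listOfFluxObjectives>
    <fbc:fluxObjective fbc:reaction="BIO" fbc:coefficient="1"/>
   </fbc:listOfFluxObjectives>
  </fbc:objective>
 </fbc:listOfObjectives>
</model>
</sbml>', path)
  m <- read_model(path)
  expect_length(m$reactions, 3)
  expect_equal(m$objective_id, "BIO")
  expect_equal(m$reactions[["EXA"]]$upper_bound, 10)
  expect_equal(gpr_to_string(m$reactions[["R1"]]$gpr), "(geneA and geneB)")
  sol <- solve_fba(m)
  expect_equal(sol$objective, 10)
})

test_that("make_irreversible splits reversible reactions correctly", {
  m <- five_rxn_model()   # R1, R2 reversible out of 5
  irr <- make_irreversible(m)
  expect_length(irr$model$reactions, 7)
  expect_true(all(vapply(irr$model$reactions,
                         function(r) r$lower_bound >= 0, logical(1))))
  expect_equal(irr$split_map[["R1"]], c("R1_f", "R1_b"))
  rb <- irr$model$reactions[["R1_b"]]
  rf <- irr$model$reactions[["R1_f"]]
  expect_equal(rb$stoichiometry, -rf$stoichiometry)
  expect_equal(rb$upper_bound, 10)
  expect_equal(rf$subsystem, "P1")
  expect_identical(rb$gpr, m$reactions[["R1"]]$gpr)
  # irreversible reactions pass through untouched
  expect_identical(irr$model$reactions[["R3"]], m$reactions[["R3"]])
  # split copies are adjacent, order preserved
  expect_equal(unname(reaction_ids(irr$model)),
               c("EX_A", "R1_f", "R1_b", "R2_f", "R2_b", "R3", "BIO"))
})

test_that("split-model optima recombine to feasible original fluxes", {
  m <- five_rxn_model()
  irr <- make_irreversible(m)
  sol <- solve_fba(irr$model)
  expect_equal(sol$status, "optimal")
  v <- stats::setNames(numeric(length(m$reactions)), reaction_ids(m))
  for (id in names(irr$split_map)) {
    ids <- irr$split_map[[id]]
    v[id] <- if (length(ids) == 2) sol$fluxes[ids[1]] - sol$fluxes[ids[2]]
             else sol$fluxes[ids]
  }
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% v)), 1e-6)
  for (r in m$reactions) {
    expect_gte(v[r$id], r$lower_bound - 1e-9)
    expect_lte(v[r$id], r$upper_bound + 1e-9)
  }
  expect_equal(sum(v["BIO"]), solve_fba(m)$objective)
})

test_that("collapse_split_ids strips split suffixes", {
  expect_equal(collapse_split_ids(c("R1_f", "R1_b", "R3")),
               c("R1", "R1", "R3"))
  sm <- list(R1 = c("R1_f", "R1_b"), W_f = "W_f")
  # with a split map, only genuinely split ids collapse
  expect_equal(collapse_split_ids(c("R1_b", "W_f"), sm), c("R1", "W_f"))
})
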