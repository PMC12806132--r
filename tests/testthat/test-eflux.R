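test_that("assign_eflux_bounds caps bounds proportionally to scores", {
  m <- make_irreversible(five_rxn_model())$model
  ev <- c(g1 = 0.5, g2 = 0.8, g3 = 0.1, g4 = 0.3, g5 = 0.2)
  con <- assign_eflux_bounds(m, ev, vmax = 1000)
  # R1 (g1 and g2): min = 0.5 -> both split copies capped at 500
  expect_equal(con$model$reactions[["R1_f"]]$upper_bound, 500)
  expect_equal(con$model$reactions[["R1_b"]]$upper_bound, 500)
  # R2 (g3 or g4): sum = 0.4
  expect_equal(con$model$reactions[["R2_f"]]$upper_bound, 400)
  # R3 ((g1 and g3) or g5): max over routes? no - OR sums: 0.1 + 0.2
  expect_equal(con$model$reactions[["R3"]]$upper_bound, 300)
  # GPR-bearing split reactions count individually
  expect_equal(con$n_constrained, 5L)
  # reactions without GPR keep defaults
  expect_equal(con$model$reactions[["BIO"]]$upper_bound, 1000)
})

test_that("OR-sum scores are capped at 1 before scaling", {
  m <- make_irreversible(five_rxn_model())$model
  ev <- c(g1 = 1, g2 = 1, g3 = 0.9, g4 = 0.8, g5 = 1)
  con <- assign_eflux_bounds(m, ev, vmax = 1000)
  expect_equal(con$model$reactions[["R2_f"]]$upper_bound, 1000)
})

test_that("eflux requires an irreversible model and respects the medium", {
  m <- five_rxn_model()
  expect_error(assign_eflux_bounds(m, c(g1 = 1)), "irreversible")
  irr <- make_irreversible(m)$model
  med <- medium_spec("EX_A", uptake_limit = 7)
  con <- assign_eflux_bounds(irr, c(g1 = 1, g2 = 1, g3 = 1, g4 = 1, g5 = 1),
                             medium = med)
  expect_equal(con$model$reactions[["EX_A"]]$upper_bound, 7)
  sol <- solve_fba(con$model)
  expect_equal(sol$objective, 7)   # uptake-limited
  expect_error(medium_spec("EX_A", uptake_limit = 0), "> 0")
})

test_that("a zero score on an essential reaction blocks growth", {
  m <- make_irreversible(chain_model())$model
  mets <- m$metabolites
  rxns <- m$reactions
  rxns[["AtoB"]]$gpr <- parse_gpr("gx")
  m2 <- metabolic_model(mets, rxns, "BIO")
  con <- assign_eflux_bounds(m2, c(gx = 0))
  sol <- solve_fba(con$model)
  expect_equal(sol$objective, 0)
})

test_that("solve_fba satisfies mass balance and reports failures", {
  m <- chain_model()
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 5)
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  expect_equal(solve_fba(parallel_model())$objective, 7)
  expect_error(solve_fba(m, objective_id = "nope"), "unknown objective")
})

test_that("raising an upper bound never decreases the optimum", {
  withr::with_seed(11, {
    for (i in 1:10) {
      ub2 <- stats::runif(1, 1, 9)
      base <- solve_fba(chain_model(ub2 = ub2))$objective
      raised <- solve_fba(chain_model(ub2 = ub2 + stats::runif(1, 0, 5)))$objective
      expect_gte(raised, base - 1e-9)
    }
  })
})

test_that("fluxome_for_cohort is deterministic and tracks expression", {
  model <- five_rxn_model()
  irr <- make_irreversible(model)$model
  genes <- c("g1", "g2", "g3", "g4", "g5")
  # two identical samples and one with P1 silenced
  v <- cbind(s1 = c(0.6, 0.6, 0.3, 0.3, 0.4),
             s2 = c(0.6, 0.6, 0.3, 0.3, 0.4),
             s3 = c(0.0, 0.0, 0.0, 0.0, 0.4))
  rownames(v) <- genes
  expr <- omic_matrix(v)
  jx <- fluxome_for_cohort(irr, expr, medium = medium_spec("EX_A", 1000))
  expect_equal(omic_layer(jx), "JX")
  expect_equal(unclass(jx)[, "s1"], unclass(jx)[, "s2"])
  expect_true(all(attr(jx, "solver_status") == "optimal"))
  # silencing pathway genes strictly lowers flux through that pathway
  expect_lt(unclass(jx)["R1_f", "s3"], unclass(jx)["R1_f", "s1"])
  expect_lt(attr(jx, "objective_values")["s3"],
            attr(jx, "objective_values")["s1"])
  # mass balance on every optimal column
  S <- stoich_matrix(irr)
  expect_lt(max(abs(S %*% unclass(jx))), 1e-6)
})

test_that("reaction_expression matches per-reaction minSum rows", {
  model <- five_rxn_model()
  genes <- c("g1", "g2", "g3", "g4", "g5")
  v <- matrix(stats::runif(10), 5, 2, dimnames = list(genes, c("a", "b")))
  expr <- omic_matrix(v)
  rx <- reaction_expression(model, expr)
  expect_equal(omic_layer(rx), "reaction_expression")
  expect_equal(nrow(rx), 3)  # only GPR-bearing reactions
  expect_equal(unclass(rx)["R1", "a"], min(v["g1", "a"], v["g2", "a"]))
  expect_equal(unclass(rx)["R2", "b"], v["g3", "b"] + v["g4", "b"])
  # single-gene GPR row equals the gene's row
  m2 <- five_rxn_model()
  m2$reactions[["R3"]]$gpr <- parse_gpr("g5")
  rx2 <- reaction_expression(m2, expr)
  expect_equal(unclass(rx2)["R3", ], v["g5", ])
})
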