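# simulator: normalized-Hill dynamics vs the fixed-point oracle, bounds,
# invariances, determinism.

test_that("a node with no regulators relaxes to its basal activity", {
  m <- networkModel(data.frame(id = "lone"), data.frame()[0, ])
  st <- integrateNetwork(m, NULL, list(), fastConfig())$state
  expect_true(isConverged(st))
  expect_equal(unname(activities(st)["lone"]), 0.5, tolerance = 1e-8)
})

test_that("two-node chain matches the fixed-point oracle to 1e-8", {
  m <- chainModel(2)
  st <- integrateNetwork(m, NULL, list(), fastConfig())$state
  expect_true(isConverged(st))
  expect_equal(unname(activities(st)), unname(fpOracle(m)), tolerance = 1e-8)
  # and x_B solves x_B = phi(x_A) directly
  phi <- hillActivation(0.5, 1.4, 0.5)
  expect_equal(unname(activities(st)["n2"]), phi, tolerance = 1e-8)
})

test_that("longer chains, inhibiting chains and perturbed chains match the oracle", {
  cfg <- fastConfig()
  for (m in list(chainModel(4),
                 chainModel(3, sign = "inhibiting", weight = 0.7),
                 pathFixture())) {
    st <- integrateNetwork(m, NULL, list(), cfg)$state
    expect_equal(unname(activities(st)), unname(fpOracle(m)),
                 tolerance = 1e-8)
  }
  m <- chainModel(3)
  p <- data.frame(gene = "n1", direction = "knockdown", magnitude = 0.4)
  st <- integrateNetwork(m, p, list(), cfg)$state
  expect_equal(unname(activities(st)), unname(fpOracle(m, p)),
               tolerance = 1e-8)
})

test_that("all sampled activities stay in [0, 1]", {
  sc <- plantedDriverScenario(scenarioSpec(nNodes = 14, seed = 7),
                              config = fastConfig())
  res <- integrateNetwork(sc$model, sc$avatar, list(), fastConfig(),
                          trajectory = TRUE)
  expect_true(all(res$trajectory@states >= -1e-9))
  expect_true(all(res$trajectory@states <= 1 + 1e-9))
  # per-node ceiling: x_max scaled by the avatar factor, capped at 1
  nd <- networkNodes(sc$model)
  ceiling <- stats::setNames(nd$x_max, nd$id)
  p <- perturbations(sc$avatar)
  ceiling[p$gene] <- pmin(1, ceiling[p$gene] * p$magnitude)
  expect_true(all(sweep(res$trajectory@states, 2,
                        ceiling[colnames(res$trajectory@states)], "-")
                  <= 1e-6))
})

test_that("packaged fixtures converge at default horizons", {
  m <- mmCoreNetwork()
  cfg <- simulationConfig()
  for (i in 1:4) {
    st <- controlAndDiseaseStates(m, caseStudyAvatar(i, m), cfg)
    expect_true(isConverged(st$control))
    expect_true(isConverged(st$disease))
    expect_lt(residual(st$disease), cfg@convergenceEps)
  }
})

test_that("scaling tau and horizons together leaves steady states unchanged", {
  m <- pathFixture()
  av <- pathAvatar()
  a <- controlAndDiseaseStates(m, av, simulationConfig(
    preTriggerHorizon = 5000, postTriggerHorizon = 10000, tau = 10))
  b <- controlAndDiseaseStates(m, av, simulationConfig(
    preTriggerHorizon = 50000, postTriggerHorizon = 100000, tau = 100))
  expect_equal(activities(a$disease), activities(b$disease),
               tolerance = 1e-6)
})

test_that("deepening an upstream knockdown never raises the target", {
  m <- chainModel(3)
  cfg <- fastConfig()
  eff <- vapply(c(0.9, 0.6, 0.3, 0.1), function(mag) {
    p <- data.frame(gene = "n1", direction = "knockdown", magnitude = mag)
    unname(activities(integrateNetwork(m, p, list(), cfg)$state)["n3"])
  }, 0)
  expect_true(all(diff(eff) <= 1e-10))
})

test_that("identical inputs give bitwise-identical states", {
  m <- mmCoreNetwork()
  av <- caseStudyAvatar(3, m)
  cfg <- simulationConfig()
  a <- controlAndDiseaseStates(m, av, cfg)
  b <- controlAndDiseaseStates(m, av, cfg)
  expect_identical(activities(a$control), activities(b$control))
  expect_identical(activities(a$disease), activities(b$disease))
})

test_that("an empty avatar reproduces the control state within 1e-6", {
  m <- mmCoreNetwork()
  st <- controlAndDiseaseStates(m, avatarSpec("none"), simulationConfig())
  expect_lt(max(abs(activities(st$disease) - activities(st$control))), 1e-6)
})

test_that("drugs act on functional output, not the node level readout", {
  m <- pathFixture()
  cfg <- fastConfig()
  base <- integrateNetwork(m, NULL, list(), cfg)$state
  blocker <- drugSpec("blockRELAY", "RELAY")
  app <- drugApplication(blocker, 9)  # 90% functional inhibition
  st <- treatedState(m, avatarSpec("none"), list(app), base, cfg)
  # downstream nodes feel the block ...
  expect_lt(activities(st)["PRO"], activities(base)["PRO"] - 0.05)
  # ... while the target's own level is untouched (its input is unchanged)
  expect_equal(activities(st)["RELAY"], activities(base)["RELAY"],
               tolerance = 1e-6)
  # and the reported functional output of the target is suppressed
  fo <- functionalOutputs(st, list(app))
  expect_lt(fo[["RELAY"]], 0.1 * activities(st)[["RELAY"]] + 1e-6)
})

test_that("perturbing a gene absent from the model errors by name", {
  m <- chainModel(2)
  p <- data.frame(gene = "GHOST", direction = "knockdown", magnitude = 0.5)
  expect_error(integrateNetwork(m, p, list(), fastConfig()), "GHOST")
})

test_that("drugs targeting absent nodes error by name", {
  m <- chainModel(2)
  d <- drugApplication(drugSpec("x", "GHOST"), 1)
  expect_error(integrateNetwork(m, NULL, list(d), fastConfig()), "GHOST")
})

test_that("initial states lacking nodes are rejected", {
  m <- chainModel(2)
  st <- sysState(c(zz = 0.5))
  expect_error(integrateNetwork(m, NULL, list(), fastConfig(),
                                initialState = st), "n1")
})

test_that("trajectories sample both phases with increasing times", {
  m <- chainModel(2)
  res <- integrateNetwork(m, NULL, list(), fastConfig(), trajectory = TRUE)
  tr <- res$trajectory
  expect_s4_class(tr, "Trajectory")
  expect_equal(length(tr@times), 401)  # 201 per phase, shared boundary
  expect_true(!is.unsorted(tr@times, strictly = TRUE))
  p <- tempfile(fileext = ".tsv")
  writeTrajectory(tr, p)
  back <- read.delim(p)
  expect_equal(nrow(back), 401)
  expect_true(all(c("time", "n1", "n2") %in% names(back)))
})

test_that("hillActivation is normalized, bounded and monotone", {
  expect_equal(hillActivation(1, 2, 0.3), 1)
  expect_equal(hillActivation(0, 2, 0.3), 0)
  x <- seq(0, 1, by = 0.01)
  y <- hillActivation(x, 1.7, 0.25)
  expect_true(all(y >= 0 & y <= 1))
  expect_true(all(diff(y) >= 0))
})
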