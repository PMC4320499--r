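# screening: synergy rules, single-agent and combination screens, clones.

test_that("synergy scores match the worked examples", {
  s <- synergyScores(0.15, 0.25, 0.60)
  expect_equal(s$bliss_excess, 0.60 - (0.15 + 0.25 - 0.15 * 0.25))
  expect_equal(s$bliss_excess, 0.2375)
  expect_true(s$synergistic)
  expect_false(s$dominated)

  s2 <- synergyScores(0.10, 0.20, 0.35)
  expect_equal(s2$bliss_excess, 0.07)
  expect_true(s2$synergistic)

  s3 <- synergyScores(0.5, 0, 0.5)
  expect_equal(s3$hsa_excess, 0)
  expect_true(s3$dominated)
  expect_false(s3$synergistic)

  expect_error(synergyScores(-0.1, 0.2, 0.3), "fraction")
  expect_error(synergyScores(0.1, 0.2, 1.3), "fraction")
})

test_that("synergy scores are symmetric in the single agents", {
  a <- synergyScores(0.12, 0.31, 0.5)
  b <- synergyScores(0.31, 0.12, 0.5)
  expect_identical(a, b)
})

test_that("dominance margin delta is honoured", {
  expect_true(synergyScores(0.2, 0.2, 0.24, delta = 0.05)$dominated)
  expect_false(synergyScores(0.2, 0.2, 0.26, delta = 0.05)$dominated)
  # synergistic requires both positive Bliss excess and non-dominance
  expect_false(synergyScores(0.2, 0.2, 0.26, delta = 0.05)$synergistic)
  expect_true(synergyScores(0.2, 0.2, 0.45, delta = 0.05)$synergistic)
  expect_false(synergyScores(0.2, 0.2, 0.45, delta = 0.30)$synergistic)
})

test_that("a control avatar yields near-zero efficacy, not shortlisted", {
  m <- pathFixture()
  lib <- list(blockRELAY = drugSpec("blockRELAY", "RELAY"))
  scr <- singleAgentScreen(m, avatarSpec("ctl"), lib, fastConfig(),
                           pathMarkers())
  # the disease baseline IS control here; treatment still suppresses the
  # relay, so efficacy is positive but the record structure must hold
  expect_equal(scr$drug, "blockRELAY")
  expect_equal(scr$shortlisted, scr$efficacy_pct > 30)
})

test_that("per-drug failures are reported without aborting the screen", {
  m <- pathFixture()
  lib <- list(good = drugSpec("good", "RELAY"),
              ghost = drugSpec("ghost", "NOT_A_NODE"))
  scr <- singleAgentScreen(m, pathAvatar(), lib, fastConfig(), pathMarkers())
  expect_equal(nrow(scr), 2)
  bad <- scr[scr$drug == "ghost", ]
  expect_true(is.na(bad$efficacy_pct))
  expect_false(bad$shortlisted)
  expect_match(bad$failure, "NOT_A_NODE")
  expect_true(is.na(scr$failure[scr$drug == "good"]))
})

test_that("screen records are sorted by efficacy and flag the threshold", {
  m <- pathFixture()
  lib <- list(strong = drugSpec("strong", "RELAY"),
              weak = drugSpec("weak", "RELAY", ec50 = 50))
  scr <- singleAgentScreen(m, pathAvatar(), lib, fastConfig(), pathMarkers())
  expect_true(!is.unsorted(rev(scr$efficacy_pct)))
  expect_equal(scr$shortlisted, scr$efficacy_pct > 30)
  expect_error(singleAgentScreen(m, pathAvatar(), list(), fastConfig(),
                                 pathMarkers()), "empty")
})

test_that("adding a clone can never raise a drug's reported efficacy", {
  m <- pathFixture()
  lib <- list(blockRELAY = drugSpec("blockRELAY", "RELAY"))
  cfg <- fastConfig()
  noClone <- avatarSpec("p", perturbations(pathAvatar()))
  # clone without the driver lesion responds less to the relay blocker
  withClone <- avatarSpec("p", perturbations(pathAvatar()),
                          clones = list(resistant = data.frame(
                            gene = "DRV", direction = "knockdown",
                            magnitude = 0.9, stringsAsFactors = FALSE)))
  a <- singleAgentScreen(m, noClone, lib, cfg, pathMarkers())
  b <- singleAgentScreen(m, withClone, lib, cfg, pathMarkers())
  expect_lte(b$efficacy_pct, a$efficacy_pct)
})

test_that("sham self-combinations are never synergistic on the path fixture", {
  m <- pathFixture()
  av <- pathAvatar()
  cfg <- fastConfig()
  mk <- pathMarkers()
  lib <- list(inhA = drugSpec("inhA", "RELAY"),
              inhB = drugSpec("inhB", "RELAY"))  # identical target/potency
  cs <- combinationScreen(m, av, lib, config = cfg, markers = mk)
  expect_equal(nrow(cs), 1)
  expect_false(cs$synergistic)
  # the same holds at the other exposed dose levels
  for (xx in c(15, 30)) {
    cs2 <- combinationScreen(m, av, lib, xxLevels = xx, config = cfg,
                             markers = mk)
    expect_false(any(cs2$synergistic))
  }
})

test_that("combination records honour their internal invariants", {
  m <- pathFixture()
  av <- pathAvatar()
  cfg <- fastConfig()
  mk <- pathMarkers()
  lib <- list(onDRV = drugSpec("onDRV", "DRV"),
              onRELAY = drugSpec("onRELAY", "RELAY"))
  cs <- combinationScreen(m, av, lib, config = cfg, markers = mk)
  expect_equal(cs$bliss_excess,
               cs$E_ab - (cs$E_a + cs$E_b - cs$E_a * cs$E_b))
  expect_equal(cs$hsa_excess, cs$E_ab - pmax(cs$E_a, cs$E_b))
  expect_equal(cs$dominated, cs$hsa_excess < 0.05)
  expect_equal(cs$synergistic, cs$bliss_excess > 0 & !cs$dominated)
  expect_equal(cs$shortlisted, cs$synergistic & cs$E_ab > 0.5)
  expect_equal(cs$xx, rep(20, nrow(cs)))
})

test_that("combination screens are order-independent and deterministic", {
  m <- pathFixture()
  av <- pathAvatar()
  cfg <- fastConfig()
  mk <- pathMarkers()
  lib <- list(onDRV = drugSpec("onDRV", "DRV"),
              onRELAY = drugSpec("onRELAY", "RELAY"))
  a <- combinationScreen(m, av, lib, config = cfg, markers = mk)
  b <- combinationScreen(m, av, rev(lib), config = cfg, markers = mk)
  key <- function(x) paste(pmin(x$drug_a, x$drug_b), pmax(x$drug_a, x$drug_b))
  expect_setequal(key(a), key(b))
  for (col in c("E_ab", "bliss_excess", "hsa_excess", "synergistic"))
    expect_equal(a[[col]][order(key(a))], b[[col]][order(key(b))])
  expect_identical(a, combinationScreen(m, av, lib, config = cfg,
                                        markers = mk))
})

test_that("unreachable ICxx drugs are skipped with a logged reason", {
  m <- pathFixture()
  av <- pathAvatar()
  cfg <- fastConfig()
  mk <- pathMarkers()
  lib <- list(onRELAY = drugSpec("onRELAY", "RELAY"),
              dud = drugSpec("dud", "APO"))  # inhibiting APO helps the tumor
  cs <- combinationScreen(m, av, lib, config = cfg, markers = mk)
  sk <- attr(cs, "skipped")
  expect_true("dud" %in% sk$drug)
  expect_match(sk$reason[sk$drug == "dud"], "unreachable")
  expect_false("dud" %in% c(cs$drug_a, cs$drug_b))
})

test_that("combination screen argument errors are informative", {
  m <- pathFixture()
  av <- pathAvatar()
  lib <- list(onRELAY = drugSpec("onRELAY", "RELAY"))
  expect_error(combinationScreen(m, av, lib), "at least two")
  lib2 <- c(lib, list(onDRV = drugSpec("onDRV", "DRV")))
  expect_error(combinationScreen(m, av, lib2, anchor = "nope"), "anchor")
  expect_error(combinationScreen(m, av, lib2, xxLevels = 50), "15, 20, 30")
})
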