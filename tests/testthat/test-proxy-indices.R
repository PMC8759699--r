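# Hand-evaluated index values at the two anchor baselines:
# a foal-like pair (166 mg/dL, 8.3 uIU/mL) and a horse-like pair (104, 8).
hand <- list(
  foal = list(g = 166, i = 8.3,
              mmol = 166 / 18.016,
              homa_ir = (166 / 18.016) * 8.3 / 22.5,
              homa_bc = 20 * 8.3 / (166 / 18.016 - 3.5),
              quicki = 1 / (log10(8.3) + log10(166)),
              risqi = 8.3^(-0.5),
              mirg = (800 - 0.3 * (8.3 - 50)^2) / (166 - 30)),
  horse = list(g = 104, i = 8,
               mmol = 104 / 18.016,
               homa_ir = (104 / 18.016) * 8 / 22.5,
               homa_bc = 20 * 8 / (104 / 18.016 - 3.5),
               quicki = 1 / (log10(8) + log10(104)),
               risqi = 8^(-0.5),
               mirg = (800 - 0.3 * (8 - 50)^2) / (104 - 30)))

test_that("unit conversion divides by the molar-mass factor", {
  expect_equal(mgdl_to_mmoll(0), 0)
  expect_equal(mgdl_to_mmoll(63), 3.497, tolerance = 1e-3)  # ~3.5 mmol/L
  expect_equal(mgdl_to_mmoll(166), 9.214, tolerance = 1e-3)
  expect_error(mgdl_to_mmoll(-1), ">= 0")
})

test_that("indices match hand evaluation at the anchor baselines", {
  for (h in hand) {
    expect_equal(homa_ir(h$g, h$i), h$homa_ir, tolerance = 1e-12)
    expect_equal(homa_bc_pct(h$g, h$i), h$homa_bc, tolerance = 1e-12)
    expect_equal(quicki(h$g, h$i), h$quicki, tolerance = 1e-12)
    expect_equal(risqi(h$i), h$risqi, tolerance = 1e-12)
    expect_equal(mirg(h$g, h$i), h$mirg, tolerance = 1e-12)
  }
  # spot magnitudes: these are the scales the indices live on
  expect_equal(hand$foal$homa_ir, 3.40, tolerance = 1e-2)
  expect_equal(hand$foal$homa_bc, 29.1, tolerance = 1e-2)
  expect_equal(hand$foal$quicki, 0.319, tolerance = 1e-2)
  expect_equal(hand$horse$quicki, 0.342, tolerance = 1e-2)
  expect_equal(hand$foal$mirg, 2.05, tolerance = 1e-2)
})

test_that("trivial closed forms hold", {
  expect_equal(homa_ir(166, 0), 0)
  expect_equal(quicki(10, 10), 0.5)
  expect_equal(risqi(1), 1)
  expect_equal(risqi(4), 0.5)
  expect_equal(mirg(130, 50), 800 / 100)  # quadratic term vanishes at 50
})

test_that("domain errors are raised at the poles", {
  expect_error(homa_bc_pct(63, 8), "glucose > 63")
  expect_error(homa_bc_pct(50, 8), "glucose > 63")
  expect_error(quicki(0, 8), "positive")
  expect_error(quicki(100, 0), "positive")
  expect_error(risqi(0), "insulin > 0")
  expect_error(mirg(30, 8), "glucose > 30")
})

test_that("HOMA-BC% variants agree up to the rounded 63 mg/dL constant", {
  # the mg/dL rendering uses the printed constant 63 (= 3.5 mmol/L
  # rounded); exactly: 20 i / (g - 63)
  expect_equal(homa_bc_pct(166, 8.3, variant = "mgdl"),
               20 * 8.3 / (166 - 63), tolerance = 1e-12)
  ratio <- homa_bc_pct(166, 8.3, variant = "mgdl") * 18.016 /
    homa_bc_pct(166, 8.3, variant = "mmol")
  expect_equal(ratio, 1, tolerance = 1e-3)
})

test_that("monotonicity and algebraic identities hold across random pairs", {
  set.seed(404)
  g <- runif(50, 70, 250)
  i <- runif(50, 1, 40)
  # homa_ir increasing in each argument
  expect_true(all(homa_ir(g + 1, i) > homa_ir(g, i)))
  expect_true(all(homa_ir(g, i + 1) > homa_ir(g, i)))
  # quicki decreasing in each; risqi decreasing in insulin
  expect_true(all(quicki(g + 1, i) < quicki(g, i)))
  expect_true(all(quicki(g, i + 1) < quicki(g, i)))
  expect_true(all(risqi(i + 1) < risqi(i)))
  # scale identity: mmol route equals direct mg/dL arithmetic
  expect_equal(homa_ir(g, i), g * i / (22.5 * 18.016), tolerance = 1e-12)
  # mirg maximal over insulin at 50 for fixed glucose
  expect_true(all(mirg(g, 50) >= mirg(g, i)))
})

test_that("the proxy panel uses the time-0 pair and labels failures", {
  s <- subject_series("f", "foal", c(-60, 0, 2), c(150, 166, 320),
                      c(10, 8.3, 70))
  panel <- proxy_panel(s)
  expect_equal(panel$baseline_glucose, 166)   # time 0, not the -60 draw
  expect_equal(panel$baseline_insulin, 8.3)
  expect_equal(panel$homa_ir, hand$foal$homa_ir, tolerance = 1e-12)
  expect_equal(panel$mirg, hand$foal$mirg, tolerance = 1e-12)

  # identical baseline pair => identical panel
  s2 <- subject_series("g", "foal", c(0, 2), c(166, 300), c(8.3, 80))
  p2 <- proxy_panel(s2)
  expect_equal(unlist(p2[3:9]), unlist(panel[3:9]), tolerance = 0)

  miss <- subject_series("m", "foal", c(0, 2), c(166, 300), c(NA, 80))
  expect_error(proxy_panel(miss), "time-0")

  low <- subject_series("l", "horse", c(0, 2), c(60, 300), c(8, 80))
  expect_error(proxy_panel(low), "homa_bc_pct")
})
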