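test_that("consumption rate covers the no-loss and total-loss extremes and errors", {
  expect_equal(consumption_rate(4, 4), 0)
  expect_equal(consumption_rate(4, 0), 1)
  expect_error(consumption_rate(4, 5), "negative consumption")
  expect_error(consumption_rate(0, 0), "initial substrate")
  # independent arithmetic: 11.5 % of 4 g/L xylose as a molar concentration
  expect_equal(consumed_molar_conc(4, 0.115), 0.115 * 4 / 150.13 * 1e6)
  expect_equal(round(consumed_molar_conc(4, 0.115)), 3064)
})

test_that("metabolite coulombs follow C = F b V dC and are linear", {
  # published per-product charges: ethanol across the four powered reactors
  eth <- c(567, 2093, 764, 2000)
  expect_equal(round(coulombs_from_metabolite(eth, 0.1, "ethanol")),
               c(19, 69, 25, 66))
  ace <- c(1380, 1594, 632, 1874)
  expect_equal(round(coulombs_from_metabolite(ace, 0.1, "acetate")),
               c(8, 9, 4, 11))
  expect_equal(coulombs_from_metabolite(0, 0.1, "ethanol"), 0)
  expect_error(coulombs_from_metabolite(100, 0.1, "butanol"), "unknown species")
  expect_error(coulombs_from_metabolite(100, 0.1, "biomass"), "coulomb_b")
  # linearity in concentration and volume
  c1 <- coulombs_from_metabolite(500, 0.1, "acetate")
  expect_equal(coulombs_from_metabolite(1500, 0.1, "acetate"), 3 * c1)
  expect_equal(coulombs_from_metabolite(500, 0.3, "acetate"), 3 * c1)
})

test_that("hydrogen coulombs use two electrons per mole", {
  expect_equal(round(coulombs_from_h2(c(0.20, 0.36, 0.11)), 3),
               c(0.039, 0.069, 0.021))
  expect_equal(coulombs_from_h2(0), 0)
  expect_equal(coulombs_from_h2(2), 2 * coulombs_from_h2(1))
  expect_error(coulombs_from_h2(-1), ">= 0")
})

test_that("charge integration is trapezoidal in seconds with sign preserved", {
  flat <- data.frame(time_h = seq(0, 150, by = 1), current_A = 1e-6)
  expect_equal(integrate_current(flat), 0.54)
  ramp <- data.frame(time_h = c(0, 100), current_A = c(0, 2e-6))
  expect_equal(integrate_current(ramp), 0.36)
  neg <- data.frame(time_h = c(0, 100), current_A = c(-1e-6, -1e-6))
  expect_lt(integrate_current(neg), 0)
  expect_error(integrate_current(data.frame(time_h = c(1, 1), current_A = c(0, 0))),
               "strictly increasing")
  expect_error(integrate_current(flat[1, ]), "at least 2")
  # additivity over a time partition and linearity in current
  set.seed(7)
  t <- sort(runif(40, 0, 150))
  i <- runif(40, 0, 5e-6)
  whole <- data.frame(time_h = t, current_A = i)
  left <- whole[1:20, ]; right <- whole[20:40, ]
  expect_equal(integrate_current(left) + integrate_current(right),
               integrate_current(whole))
  doubled <- data.frame(time_h = t, current_A = 2 * i)
  expect_equal(integrate_current(doubled), 2 * integrate_current(whole))
  # time reversal of a non-negative trace leaves the charge unchanged
  rev_tr <- data.frame(time_h = max(t) - rev(t), current_A = rev(i))
  expect_equal(integrate_current(rev_tr), integrate_current(whole))
})

test_that("Coulombic efficiency follows its defining ratio and is linear in charge", {
  expect_equal(coulombic_efficiency(0, 0.046), 0)
  # independent arithmetic oracle for the +0.842 V inputs
  expect_equal(coulombic_efficiency(1.06, 0.046),
               1.06 / (96485 * 20 * 0.046 / 150.13) * 100)
  expect_equal(round(coulombic_efficiency(1.06, 0.046), 3), 0.179)
  expect_equal(coulombic_efficiency(2.12, 0.046),
               2 * coulombic_efficiency(1.06, 0.046))
  # magnitude convention: net-negative charge reports a positive CE
  expect_equal(coulombic_efficiency(-0.58, 0.1172),
               coulombic_efficiency(0.58, 0.1172))
  expect_error(coulombic_efficiency(1, 0), "undefined CE")
})

test_that("cathodic gas recovery reproduces the published recoveries", {
  expect_equal(round(cathodic_gas_recovery(coulombs_from_h2(0.11), 1.06), 1), 2.0)
  expect_equal(round(cathodic_gas_recovery(0.118, 0.17), 1), 69.4)
  expect_equal(cathodic_gas_recovery(0, 1), 0)
  # |C_I| convention makes the net-negative reactor representable
  expect_equal(cathodic_gas_recovery(0.039, -0.58),
               cathodic_gas_recovery(0.039, 0.58))
  expect_error(cathodic_gas_recovery(0.1, 0), "no charge")
})

test_that("product yields are per mole of substrate consumed", {
  expect_equal(round(product_yield(2000, 3064), 3), 0.653)
  consumed_ctrl <- 0.0275 * 26644
  expect_equal(round(product_yield(148, consumed_ctrl), 3), 0.202)
  expect_equal(product_yield(0, 1000), 0)
  expect_error(product_yield(100, 0), "yield undefined")
})

test_that("carbon shares partition consumed carbon over the pools", {
  consumed <- consumed_molar_conc(4, 0.115)
  cs <- carbon_shares(list(ethanol = 2000, acetate = 1874), consumed)
  expect_equal(round(cs$share_pct[cs$pool == "ethanol"], 1), 26.1)
  cs_ctrl <- carbon_shares(list(ethanol = 148, acetate = 805),
                           consumed_molar_conc(4, 0.0275))
  expect_equal(round(cs_ctrl$share_pct[cs_ctrl$pool == "acetate"], 1), 43.9,
               tolerance = 0.011)
  empty <- carbon_shares(list(), 1000)
  expect_equal(empty$share_pct[empty$pool != "unaccounted"], rep(0, 3))
  expect_equal(sum(empty$share_pct), 100) # unaccounted completes to 100
  expect_error(carbon_shares(list(ethanol = 1), 0), "no substrate consumed")
})

test_that("electron shares use the full-oxidation equivalents and volume-scaled H2", {
  consumed <- consumed_molar_conc(4, 0.115)
  es <- electron_shares(list(ethanol = 2000, acetate = 1874, hydrogen = 0.11),
                        consumed, c_i = 1.06, volume = 0.1)
  expect_equal(round(es$share_pct[es$pool == "ethanol"], 1), 39.2,
               tolerance = 0.011)
  es_ctrl <- electron_shares(list(ethanol = 148, acetate = 805),
                             consumed_molar_conc(4, 0.0275), volume = 0.1)
  expect_equal(round(es_ctrl$share_pct[es_ctrl$pool == "ethanol"], 1), 12.1)
  expect_false("current" %in% es_ctrl$pool) # no charge supplied
  # H2 share equals 2 * n_h2 / (20 * moles consumed), moles via the volume
  n_cons <- consumed * 1e-6 * 0.1
  expect_equal(es$share_pct[es$pool == "hydrogen"],
               2 * 0.11e-6 / (20 * n_cons) * 100)
  # current share equals |C_I| / (F * 20 * moles consumed)
  expect_equal(es$share_pct[es$pool == "current"],
               1.06 / (96485 * 20 * n_cons) * 100)
})

test_that("electron and carbon partitions obey the exact stoichiometric identities", {
  set.seed(11)
  for (rep in 1:25) {
    consumed <- runif(1, 500, 30000)
    panel <- list(ethanol = runif(1, 0, 3000), acetate = runif(1, 0, 3000),
                  biomass = runif(1, 0, 1000), hydrogen = runif(1, 0, 1))
    cs <- carbon_shares(panel, consumed)
    es <- electron_shares(panel, consumed, volume = 0.1)
    pick <- function(tab, p) tab$share_pct[tab$pool == p]
    # ethanol: 12 e/20 e vs 2 C/5 C gives an exact 1.5 ratio
    expect_equal(pick(es, "ethanol"), 1.5 * pick(cs, "ethanol"))
    # acetate 8/20 = 2/5 and biomass 20/20 = 5/5: shares coincide exactly
    expect_equal(pick(es, "acetate"), pick(cs, "acetate"))
    expect_equal(pick(es, "biomass"), pick(cs, "biomass"))
    expect_true(all(cs$share_pct[cs$pool != "unaccounted"] >= 0))
  }
})
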