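# Synthetic duplex melt-curve simulator.

test_that("two-state melt fraction matches the closed form", {
  expect_equal(two_state_fraction(84.0, 84.0, 0.4), 0.5)
  expect_lt(abs(two_state_fraction(70.0, 84.0, 0.4) - 1.0), 1e-12)
  # frozen: 1 / (1 + exp(2.5))
  expect_equal(two_state_fraction(85.0, 84.0, 0.4), 0.07585818002124355,
               tolerance = 1e-10)
  expect_true(all(diff(two_state_fraction(seq(70, 95, 0.5), 84, 0.4)) <= 0))
  expect_error(two_state_fraction(84, 84, 0), class = "meltsex_value_error")
  expect_error(two_state_fraction(84, 84, -1), class = "meltsex_value_error")
})

test_that("simulated wells show the duplex melt signatures", {
  # non-amplified well: near-flat baseline trace carrying the flag
  flat <- simulate_well(fixture_scenario("W1", list(), amplified = FALSE),
                        default_grid)
  expect_false(flat$amplified)
  drop <- (max(flat$rfu) - min(flat$rfu)) / max(flat$rfu)
  expect_lt(drop, 0.25) # only the linear dye response remains

  # male: exactly one derivative peak near the ACTB tm
  m <- male_well("M1")
  pm <- estimate_tms(negative_derivative(m))
  expect_identical(nrow(pm$peaks), 1L)
  expect_lt(abs(pm$peaks$tm - 85.5), 0.25)

  # female: two peaks >= 1 C apart
  f <- female_well("F1")
  pf <- estimate_tms(negative_derivative(f))
  expect_identical(nrow(pf$peaks), 2L)
  expect_gte(diff(pf$peaks$tm), 1.0)
})

test_that("identical scenario and seed give bit-identical curves", {
  sc <- fixture_scenario("W", female_products(), noise_sd = 0.004, seed = 77)
  c1 <- simulate_well(sc, default_grid)
  c2 <- simulate_well(sc, default_grid)
  expect_identical(c1$rfu, c2$rfu)
  sc2 <- sc
  sc2$seed <- 78
  expect_false(identical(simulate_well(sc2, default_grid)$rfu, c1$rfu))
})

test_that("two-product wells compose from single-product melt terms", {
  a <- product_spec("ACTB", 85.5, 0.2, 1.0)
  x <- product_spec("XIST", 84.0, 0.2, 0.55)
  both <- simulate_well(fixture_scenario("AB", list(a, x)), default_grid)
  only_a <- simulate_well(fixture_scenario("A", list(a)), default_grid)
  only_x_no_resid <- well_scenario("X", "X", list(x),
                                   baseline_intercept = 3000,
                                   baseline_slope = -15,
                                   residual_fraction = 0, noise_sd = 0)
  expect_equal(both$rfu,
               only_a$rfu + simulate_well(only_x_no_resid, default_grid)$rfu,
               tolerance = 1e-12)
})

test_that("noiseless single-product peak lies within half a grid step", {
  for (tm in c(84.0, 85.25, 85.5)) {
    sc <- fixture_scenario("W", list(product_spec("P", tm, 0.2, 1.0)))
    pk <- estimate_tms(negative_derivative(simulate_well(sc, default_grid)))
    expect_identical(nrow(pk$peaks), 1L)
    expect_lte(abs(pk$peaks$tm - tm), 0.25)
  }
})

test_that("simulate_well validates its grid", {
  sc <- fixture_scenario("W", male_products())
  expect_error(simulate_well(sc, numeric(0)), class = "meltsex_value_error")
  expect_error(simulate_well(sc, c(70, 70.5, 71.5)),
               class = "meltsex_value_error")
})

test_that("scenarios encode assay semantics and failure modes", {
  cfg <- sim_config()
  fem <- list(sample_id = "S1", true_sex = "female", karyotype = "XX",
              rna_yield = 71, het_actb = FALSE)
  sc <- make_scenario(fem, 1, cfg, seed = 1)
  nm <- vapply(sc$products, function(p) p$name, character(1))
  tms <- vapply(sc$products, function(p) p$tm, numeric(1))
  expect_setequal(nm, c("ACTB", "XIST"))
  expect_lt(abs(tms[nm == "XIST"] - 84.0), 0.1)
  expect_lt(abs(tms[nm == "ACTB"] - 85.5), 0.1)

  # low yield with dropout forced: female renders male-like
  cfg_drop <- sim_config(dropout_prob = 1, dimer_prob = 0, nonamp_prob = 0)
  fem_low <- modifyList(fem, list(rna_yield = 4))
  sc2 <- make_scenario(fem_low, 1, cfg_drop, seed = 2)
  expect_false("XIST" %in% vapply(sc2$products, function(p) p$name,
                                  character(1)))
  expect_true(sc2$amplified)

  # heterozygous ACTB male: two closely spaced sub-products
  mal <- list(sample_id = "S2", true_sex = "male", karyotype = "XY",
              rna_yield = 71, het_actb = TRUE)
  sc3 <- make_scenario(mal, 1, cfg, seed = 3)
  atm <- sort(vapply(sc3$products, function(p) p$tm, numeric(1)))
  expect_identical(length(atm), 2L)
  expect_equal(diff(atm), cfg$het_split, tolerance = 1e-9)

  # XXY karyotype: XIST present while DNA-based sex would be male
  xxy <- list(sample_id = "S3", true_sex = "male", karyotype = "XXY",
              rna_yield = 71, het_actb = FALSE)
  sc4 <- make_scenario(xxy, 1, cfg, seed = 4)
  expect_true("XIST" %in% vapply(sc4$products, function(p) p$name,
                                 character(1)))

  expect_error(
    make_scenario(list(sample_id = "S", true_sex = "hermaphrodite",
                       rna_yield = 50), 1, cfg, seed = 1),
    class = "meltsex_value_error"
  )
})

test_that("quantification cycles follow the standard-curve model", {
  # ten-fold template difference at 100% efficiency: delta Cq = 3.32
  expect_equal(simulate_cq(0) - simulate_cq(1), 3.32)
  expect_true(is.na(simulate_cq((24 - 46) / 3.32)))   # beyond 45 cycles
  expect_identical(simulate_cq(24 / 3.32), 0)          # clamped boundary
  expect_error(simulate_cq(0, slope = 0), class = "meltsex_value_error")
  expect_error(simulate_cq(0, slope = -1), class = "meltsex_value_error")
})

test_that("cohort simulation honours its contract and is seed-stable", {
  sim <- simulate_cohort(10, sex_ratio = 0.5, cohort_profile = "2021",
                         seed = 7)
  expect_identical(length(sim$curves), 30L)
  expect_identical(nrow(sim$truth), 10L)
  expect_identical(nrow(sim$layout), 30L)
  expect_true(all(table(sim$layout$sample_id) == 3L))
  expect_true(any(sim$truth$known_female_anchor))

  sim2 <- simulate_cohort(10, sex_ratio = 0.5, cohort_profile = "2021",
                          seed = 7)
  expect_identical(lapply(sim$curves, `[[`, "rfu"),
                   lapply(sim2$curves, `[[`, "rfu"))
  expect_identical(sim$truth, sim2$truth)

  # forced single female: every well carries an XIST product
  one <- simulate_cohort(1, sex_ratio = 1.0, seed = 3)
  expect_identical(one$truth$true_sex, "female")
  for (sc in one$scenarios) {
    expect_true("XIST" %in% vapply(sc$products, function(p) p$name,
                                   character(1)))
  }

  expect_error(simulate_cohort(10, sex_ratio = 1.5),
               class = "meltsex_value_error")
  expect_error(simulate_cohort(40, seed = 1, multi_plate = FALSE),
               class = "meltsex_value_error")
})

test_that("female wells without dropout carry XIST; male wells never do", {
  sim <- simulate_cohort(20, sex_ratio = 0.5, seed = 19)
  for (w in names(sim$scenarios)) {
    sc <- sim$scenarios[[w]]
    s <- sim$truth[sim$truth$sample_id == sc$sample_id, ]
    has_xist <- "XIST" %in% vapply(sc$products, function(p) p$name,
                                   character(1))
    if (s$karyotype == "XY") expect_false(has_xist)
    if (s$karyotype == "XX" && s$rna_yield >= 9) expect_true(has_xist)
  }
})

test_that("per-well seeds are stable hashes independent of order", {
  expect_identical(derive_seed(42, "A01"), derive_seed(42, "A01"))
  expect_false(derive_seed(42, "A01") == derive_seed(42, "A02"))
  expect_false(derive_seed(42, "A01") == derive_seed(43, "A01"))
  expect_gte(derive_seed(1, "x"), 1L)
})
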