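# Well QC, cluster -> sex mapping, majority-rule per-sample calls.

# A hand-built plate: A = 3 female wells (anchor sample), B = 2 female +
# 1 male well, C = 1 female + 1 male + 1 flat well, D/E = male triplicates.
caller_fixture <- function() {
  wells <- list(
    A1 = female_well("A1", 0.004, 401), A2 = female_well("A2", 0.004, 402),
    A3 = female_well("A3", 0.004, 403),
    B1 = female_well("B1", 0.004, 404), B2 = female_well("B2", 0.004, 405),
    B3 = male_well("B3", 0.004, 406),
    C1 = female_well("C1", 0.004, 407), C2 = male_well("C2", 0.004, 408),
    C3 = simulate_well(fixture_scenario("C3", list(), amplified = FALSE,
                                        noise_sd = 0.004, seed = 409),
                       default_grid),
    D1 = male_well("D1", 0.004, 410), D2 = male_well("D2", 0.004, 411),
    D3 = male_well("D3", 0.004, 412),
    E1 = male_well("E1", 0.004, 413), E2 = male_well("E2", 0.004, 414),
    E3 = male_well("E3", 0.004, 415)
  )
  layout <- data.frame(
    well = names(wells),
    sample_id = rep(c("A", "B", "C", "D", "E"), each = 3),
    replicate = rep(1:3, 5), stringsAsFactors = FALSE
  )
  metadata <- data.frame(
    sample_id = c("A", "B", "C", "D", "E"),
    rna_yield = c(70, 55, 40, 80, 6.5),
    dna_sex = c("female", "female", "unknown", "male", "male"),
    known_female_anchor = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    cohort = "2021", stringsAsFactors = FALSE
  )
  list(curves = wells, layout = layout, metadata = metadata)
}

test_that("well QC assigns one primary failure reason per well", {
  fx <- caller_fixture()
  run <- run_hrm_pipeline(fx$curves, fx$layout, fx$metadata)
  qc <- run$qc
  expect_identical(qc$reason[qc$well_id == "C3"], "non_amplified")
  expect_false(qc$passed[qc$well_id == "C3"])
  expect_true(all(qc$passed[qc$well_id %in% c("A1", "B1", "D1")]))
  expect_true(all(qc$reason[qc$passed] == "none"))

  # explicit Cq beyond the cycle limit marks a well non-amplified
  cq <- data.frame(well = names(fx$curves), cq = 24)
  cq$cq[cq$well == "D1"] <- 46
  qc2 <- qc_wells(fx$curves, cq = cq)
  expect_identical(qc2$reason[qc2$well_id == "D1"], "non_amplified")
})

test_that("anchors map the female cluster; the other cluster is male", {
  fx <- caller_fixture()
  run <- run_hrm_pipeline(fx$curves, fx$layout, fx$metadata)
  expect_setequal(unname(run$sex_map), c("female", "male"))
  fem_cluster <- names(run$sex_map)[run$sex_map == "female"]
  expect_true(all(run$clusters$labels[c("A1", "A2", "A3")] ==
                    as.integer(fem_cluster)))
  ev <- attr(run$sex_map, "evidence")
  expect_gte(ev$anchor_wells[ev$cluster == as.integer(fem_cluster)], 3L)
})

test_that("signature fallback identifies the two-peak cluster as female", {
  fx <- caller_fixture()
  md <- fx$metadata
  md$known_female_anchor <- FALSE
  run <- run_hrm_pipeline(fx$curves, fx$layout, md)
  fem_cluster <- names(run$sex_map)[run$sex_map == "female"]
  expect_identical(length(fem_cluster), 1L)
  expect_true(all(run$clusters$labels[c("A1", "A2", "B1")] ==
                    as.integer(fem_cluster)))
})

test_that("evenly split anchors leave the mapping unassigned", {
  fx <- caller_fixture()
  md <- fx$metadata
  md$known_female_anchor <- md$sample_id %in% c("A", "D") # one per cluster
  norm <- lapply(fx$curves[names(fx$curves) != "C3"], normalize_curve)
  peaks <- lapply(fx$curves[names(fx$curves) != "C3"], function(cv)
    estimate_tms(negative_derivative(cv)))
  cl <- cluster_wells(norm, peaks)
  expect_warning(
    map <- map_clusters_to_sex(cl, fx$layout, md, peaks),
    "split"
  )
  expect_true(all(map == "unassigned"))
})

test_that("calls follow the two-thirds majority rule", {
  fx <- caller_fixture()
  run <- run_hrm_pipeline(fx$curves, fx$layout, fx$metadata)
  calls <- run$calls
  rownames(calls) <- calls$sample_id
  expect_identical(calls["A", "call"], "female")
  expect_equal(calls["A", "fraction_modal"], 1.0)
  expect_identical(calls["B", "call"], "female")
  expect_equal(calls["B", "fraction_modal"], 2 / 3, tolerance = 1e-12)
  # C: one well excluded, remaining split 1/1 -> below two-thirds
  expect_identical(calls["C", "call"], "inconclusive")
  expect_identical(calls["C", "n_wells_pass"], 2L)
  expect_identical(calls["D", "call"], "male")
  # E is male and low yield: call unchanged, advisory flag attached
  expect_identical(calls["E", "call"], "male")
  expect_match(calls["E", "flags"], "low_yield")
})

test_that("a sample with no passing wells is insufficient", {
  fx <- caller_fixture()
  curves <- fx$curves
  for (w in c("E1", "E2", "E3")) {
    curves[[w]] <- simulate_well(
      fixture_scenario(w, list(), amplified = FALSE, noise_sd = 0.004,
                       seed = 500 + match(w, c("E1", "E2", "E3"))),
      default_grid
    )
  }
  run <- run_hrm_pipeline(curves, fx$layout, fx$metadata)
  calls <- run$calls
  expect_identical(calls$call[calls$sample_id == "E"], "insufficient")
  expect_identical(calls$n_wells_pass[calls$sample_id == "E"], 0L)
})

test_that("calls are invariant to well order and cluster relabeling", {
  fx <- caller_fixture()
  run1 <- run_hrm_pipeline(fx$curves, fx$layout, fx$metadata)
  perm <- rev(names(fx$curves))
  lay2 <- fx$layout[rev(seq_len(nrow(fx$layout))), ]
  run2 <- run_hrm_pipeline(fx$curves[perm], lay2, fx$metadata)
  c1 <- run1$calls[order(run1$calls$sample_id),
                   c("sample_id", "call", "n_wells_pass", "fraction_modal")]
  c2 <- run2$calls[order(run2$calls$sample_id),
                   c("sample_id", "call", "n_wells_pass", "fraction_modal")]
  rownames(c1) <- rownames(c2) <- NULL
  expect_identical(c1, c2)
})

test_that("all-well XIST dropout on a low-yield female is called male", {
  # the documented failure mode: XIST present but below detection, so the
  # melt profile is indistinguishable from a male's
  cfg <- sim_config(dropout_prob = 1, dimer_prob = 0, nonamp_prob = 0)
  sim <- simulate_cohort(8, sex_ratio = 0.5, seed = 61)
  curves <- sim$curves
  layout <- sim$layout
  md <- sim$metadata
  low_fem <- list(sample_id = "LOWF", true_sex = "female",
                  karyotype = "XX", rna_yield = 4, het_actb = FALSE)
  for (r in 1:3) {
    w <- sprintf("LOWF-r%d", r)
    sc <- make_scenario(low_fem, r, cfg, seed = 700 + r, well_id = w)
    curves[[w]] <- simulate_well(sc, cfg$grid)
    layout <- rbind(layout, data.frame(well = w, sample_id = "LOWF",
                                       replicate = r))
  }
  md <- rbind(md, data.frame(sample_id = "LOWF", rna_yield = 4,
                             dna_sex = "female", known_female_anchor = FALSE,
                             cohort = "2021"))
  run <- run_hrm_pipeline(curves, layout, md)
  call <- run$calls[run$calls$sample_id == "LOWF", ]
  expect_identical(call$call, "male")
  expect_match(call$flags, "low_yield")
  disc <- run$concordance$discordant
  expect_identical(disc$reason[disc$sample_id == "LOWF"],
                   "xist_dropout_suspected")
})

test_that("the yield gate is advisory with a strict cutoff", {
  md <- data.frame(
    sample_id = c("P", "Q", "R", "S"),
    rna_yield = c(3.1, 71.4, 9.0, NA)
  )
  g <- yield_gate(md, cutoff = 9.0)
  expect_true(g$low_yield[g$sample_id == "P"])
  expect_identical(g$advisory[g$sample_id == "P"], "repeat extraction")
  expect_false(g$low_yield[g$sample_id == "Q"])
  expect_false(g$low_yield[g$sample_id == "R"]) # boundary: strict less-than
  expect_false(g$low_yield[g$sample_id == "S"])
  expect_null(yield_gate(NULL))
  expect_error(yield_gate(md, cutoff = 0), class = "meltsex_value_error")
})
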