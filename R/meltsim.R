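# meltsim: synthetic duplex qPCR melt curves, plates and sample metadata with
# ground-truth labels. The simulator emulates a duplex assay in which every
# valid reaction contains the housekeeping ACTB amplicon and XX/XXY reactions
# additionally contain the female-specific XIST amplicon, which melts ~1.5 C
# lower. Failure modes (XIST dropout, primer dimers, non-amplification) are
# concentrated in low-RNA-yield samples.

#' Simulator configuration
#'
#' Collects every tunable parameter of the melt-curve simulator. Defaults are
#' the study conditions the rest of the package is tested against: a 70-95 C
#' grid read every 0.5 C, an ACTB amplicon melting at 85.5 C and an XIST
#' amplicon at 84.0 C (transition widths 0.2 C), XIST fluorescence 0.55 of
#' ACTB, and low-yield failure modes switched on below 9 ng/ul.
#'
#' @param grid Temperature grid in degrees C (ascending, uniform step).
#' @param actb_tm,xist_tm Amplicon melting temperatures (C).
#' @param product_width Two-state transition width (C) for both amplicons.
#' @param actb_abundance,xist_abundance Relative fluorescence contributions.
#' @param tm_jitter_sd Per-well s.d. of amplicon Tm (C), instrument/allele
#'   variation.
#' @param baseline_intercept,baseline_slope Linear dye/background response
#'   (RFU at 0 C, RFU per C); the slope is negative (dye fluorescence falls
#'   with temperature).
#' @param residual_fraction Non-melting residual fluorescence fraction.
#' @param noise_sd Additive Gaussian noise s.d. as a fraction of the pre-melt
#'   amplitude.
#' @param gain_sdlog Per-well multiplicative log-normal gain s.d. (log scale),
#'   reproducing well-to-well RFU spread.
#' @param het_prob Probability that an individual is heterozygous for an ACTB
#'   polymorphism (its ACTB melts as two half-abundance sub-products).
#' @param het_split Tm separation (C) between heterozygous ACTB sub-products.
#' @param dropout_threshold RNA yield (ng/ul) below which low-template failure
#'   modes are drawn.
#' @param dropout_prob Per-well probability, below the threshold, that XIST
#'   fails to amplify (a female well renders male-like).
#' @param dimer_prob Per-well probability, below the threshold, of a
#'   primer-dimer product.
#' @param dimer_tm,dimer_width,dimer_abundance Primer-dimer melt parameters;
#'   the dimer melts several degrees below both amplicons.
#' @param lowyield_template_scale Factor applied to amplicon abundances in
#'   dimer-bearing wells (inadequate template favours the dimer).
#' @param nonamp_prob Per-well probability, below the threshold, of complete
#'   non-amplification.
#' @param xxy_prob Probability that an individual carries an XXY karyotype
#'   (XIST expressed, DNA-based sex male). Default 0.
#' @param anchor_prob Probability that a female is a known-female anchor
#'   (e.g. observed with a calf); at least one anchor is forced whenever any
#'   female is simulated.
#' @param cq_slope,cq_intercept Standard-curve slope (cycles per log10
#'   template) and intercept used by [simulate_cq()].
#' @param max_cycles Number of PCR cycles; computed Cq beyond this is reported
#'   as non-amplified.
#' @param yield_ref RNA yield (ng/ul) mapping to relative template 1
#'   (log10 template 0).
#' @param cohort_profiles Named list of log-normal yield profiles
#'   (`mean` ng/ul, `sdlog`), calibrated so cohort mean yields match the
#'   pilot (5.6), optimized 2020 (55.0) and 2021 (71.4) collections.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid = seq(70, 95, by = 0.5),
                       actb_tm = 85.5,
                       xist_tm = 84.0,
                       product_width = 0.2,
                       actb_abundance = 1.0,
                       xist_abundance = 0.55,
                       tm_jitter_sd = 0.005,
                       baseline_intercept = 3000,
                       baseline_slope = -15,
                       residual_fraction = 0.05,
                       noise_sd = 0.004,
                       gain_sdlog = 0.1,
                       het_prob = 0.15,
                       het_split = 0.3,
                       dropout_threshold = 9.0,
                       dropout_prob = 0.5,
                       dimer_prob = 0.3,
                       dimer_tm = 77.5,
                       dimer_width = 0.2,
                       dimer_abundance = 0.6,
                       lowyield_template_scale = 0.4,
                       nonamp_prob = 0.2,
                       xxy_prob = 0,
                       anchor_prob = 0.3,
                       cq_slope = 3.32,
                       cq_intercept = 24,
                       max_cycles = 45L,
                       yield_ref = 50,
                       cohort_profiles = list(
                         `pilot-2020` = list(mean = 5.6, sdlog = 0.35),
                         `optimized-2020` = list(mean = 55.0, sdlog = 0.6),
                         `2021` = list(mean = 71.4, sdlog = 0.55)
                       )) {
  cfg <- as.list(environment())
  stopifnot(
    is_uniform_grid(cfg$grid), cfg$product_width > 0, cfg$noise_sd >= 0,
    cfg$residual_fraction >= 0, cfg$dropout_threshold > 0,
    cfg$het_prob >= 0, cfg$het_prob <= 1, cfg$xxy_prob >= 0, cfg$xxy_prob <= 1
  )
  structure(cfg, class = "sim_config")
}

#' Amplicon melt product specification
#'
#' @param name Short label (e.g. `"ACTB"`).
#' @param tm Melting temperature (C).
#' @param width Two-state transition width (C), > 0.
#' @param abundance Relative fluorescence contribution, >= 0.
#' @return A list of class `product_spec`.
#' @export
product_spec <- function(name, tm, width, abundance) {
  if (!is.numeric(width) || width <= 0) {
    abort("product width must be > 0", "meltsex_value_error")
  }
  if (!is.numeric(abundance) || abundance < 0) {
    abort("product abundance must be >= 0", "meltsex_value_error")
  }
  structure(
    list(name = as.character(name), tm = as.numeric(tm),
         width = as.numeric(width), abundance = as.numeric(abundance)),
    class = "product_spec"
  )
}

#' Ground-truth scenario for one well
#'
#' @param well_id,sample_id Identifiers.
#' @param products List of [product_spec()] objects.
#' @param baseline_intercept,baseline_slope Linear background response.
#' @param residual_fraction Non-melting residual fluorescence fraction, >= 0.
#' @param noise_sd Additive noise s.d. (fraction of pre-melt amplitude), >= 0.
#' @param template_log10 log10 relative cDNA input.
#' @param amplified If `FALSE`, products contribute nothing (failed reaction).
#' @param seed Optional integer seed making the simulated curve reproducible.
#' @return A list of class `well_scenario`.
#' @export
well_scenario <- function(well_id, sample_id, products,
                          baseline_intercept = 3000, baseline_slope = -15,
                          residual_fraction = 0.05, noise_sd = 0.004,
                          template_log10 = 0, amplified = TRUE, seed = NULL) {
  if (noise_sd < 0) abort("noise_sd must be >= 0", "meltsex_value_error")
  if (residual_fraction < 0) {
    abort("residual_fraction must be >= 0", "meltsex_value_error")
  }
  stopifnot(all(vapply(products, inherits, logical(1), "product_spec")))
  structure(
    list(well_id = as.character(well_id), sample_id = as.character(sample_id),
         products = products, baseline_intercept = baseline_intercept,
         baseline_slope = baseline_slope,
         residual_fraction = residual_fraction, noise_sd = noise_sd,
         template_log10 = template_log10, amplified = isTRUE(amplified),
         seed = seed),
    class = "well_scenario"
  )
}

#' Two-state (helix-coil) melt fraction
#'
#' Fraction of double-stranded product remaining at a temperature, under the
#' standard two-state model `1 / (1 + exp((T - tm) / width))`. Monotonically
#' non-increasing in temperature; equals 1/2 at `tm`.
#'
#' @param temperature Temperature(s) in C.
#' @param tm Melting temperature (C).
#' @param width Transition width (C), > 0.
#' @return Fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' two_state_fraction(84, 84, 0.4) # 0.5 at the midpoint
two_state_fraction <- function(temperature, tm, width) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    abort("width must be a single positive number", "meltsex_value_error")
  }
  1 / (1 + exp((temperature - tm) / width))
}

#' Simulate one well's melt curve
#'
#' The raw fluorescence trace is
#' `RFU(T) = (b0 + b1 T) * (residual + sum_k a_k f_k(T)) + noise`, where
#' `f_k` is the two-state melt fraction of product k and the additive noise
#' s.d. is `noise_sd` times the pre-melt amplitude. A non-amplified scenario
#' contributes only baseline and residual.
#'
#' @param scenario A [well_scenario()].
#' @param grid Ascending uniform temperature grid (C).
#' @return A [melt_curve()] carrying the scenario's `amplified` flag.
#' @export
simulate_well <- function(scenario, grid = seq(70, 95, by = 0.5)) {
  stopifnot(inherits(scenario, "well_scenario"))
  if (length(grid) == 0L) abort("empty temperature grid", "meltsex_value_error")
  if (!is_uniform_grid(grid)) {
    abort("temperature grid must be ascending with a uniform step",
          "meltsex_value_error")
  }
  base <- scenario$baseline_intercept + scenario$baseline_slope * grid
  melt <- rep(scenario$residual_fraction, length(grid))
  total_ab <- 0
  if (scenario$amplified) {
    for (p in scenario$products) {
      melt <- melt + p$abundance * two_state_fraction(grid, p$tm, p$width)
      total_ab <- total_ab + p$abundance
    }
  }
  amplitude <- (scenario$baseline_intercept + scenario$baseline_slope * grid[1L]) *
    (scenario$residual_fraction + total_ab)
  rfu <- base * melt
  if (scenario$noise_sd > 0) {
    noise <- with_seed(scenario$seed,
                       stats::rnorm(length(grid), 0, scenario$noise_sd))
    rfu <- rfu + noise * abs(amplitude)
  }
  melt_curve(scenario$well_id, grid, rfu, amplified = scenario$amplified)
}

#' Build a well scenario from a sample's ground truth
#'
#' Encodes the assay semantics: every valid reaction carries the ACTB
#' amplicon; XX and XXY karyotypes additionally carry the XIST amplicon.
#' Heterozygous-ACTB individuals melt their control product as two closely
#' spaced sub-products. Samples whose RNA yield falls below
#' `config$dropout_threshold` draw low-template failure modes: complete
#' non-amplification, XIST dropout (the well renders male-like), and/or a
#' primer-dimer product with reduced amplicon abundance.
#'
#' @param sample One row of a sample-truth table (list or data.frame row)
#'   with at least `sample_id`, `true_sex`, `karyotype`, `rna_yield`;
#'   optionally `het_actb`.
#' @param replicate Replicate index (used only for labelling).
#' @param config A [sim_config()].
#' @param seed Integer seed for this well's draws.
#' @param well_id Well identifier; defaults to `<sample_id>-r<replicate>`.
#' @return A [well_scenario()].
#' @export
make_scenario <- function(sample, replicate = 1L, config = sim_config(),
                          seed = NULL, well_id = NULL) {
  sample <- as.list(sample)
  karyotype <- as.character(sample$karyotype %||% switch(
    as.character(sample$true_sex),
    female = "XX", male = "XY",
    abort(sprintf("unknown sex label '%s'", sample$true_sex),
          "meltsex_value_error")
  ))
  if (!karyotype %in% c("XX", "XY", "XXY")) {
    abort(sprintf("unknown karyotype '%s'", karyotype), "meltsex_value_error")
  }
  yield <- as.numeric(sample$rna_yield %||% config$yield_ref)
  if (is.null(well_id)) {
    well_id <- sprintf("%s-r%d", sample$sample_id, as.integer(replicate))
  }

  with_seed(seed, {
    gain <- stats::rlnorm(1, 0, config$gain_sdlog)
    actb_jit <- stats::rnorm(1, 0, config$tm_jitter_sd)
    xist_jit <- stats::rnorm(1, 0, config$tm_jitter_sd)
    het <- if (!is.null(sample$het_actb) && !is.na(sample$het_actb)) {
      isTRUE(as.logical(sample$het_actb))
    } else {
      stats::runif(1) < config$het_prob
    }

    low <- yield < config$dropout_threshold
    amplified <- TRUE
    dropout <- FALSE
    dimer <- FALSE
    if (low) {
      amplified <- stats::runif(1) >= config$nonamp_prob
      dropout <- stats::runif(1) < config$dropout_prob
      dimer <- stats::runif(1) < config$dimer_prob
    }

    scale <- if (dimer) config$lowyield_template_scale else 1
    products <- list()
    actb_ab <- config$actb_abundance * scale
    if (het) {
      products <- c(products, list(
        product_spec("ACTB-a", config$actb_tm - config$het_split / 2 + actb_jit,
                     config$product_width, actb_ab / 2),
        product_spec("ACTB-b", config$actb_tm + config$het_split / 2 + actb_jit,
                     config$product_width, actb_ab / 2)
      ))
    } else {
      products <- c(products, list(
        product_spec("ACTB", config$actb_tm + actb_jit,
                     config$product_width, actb_ab)
      ))
    }
    if (karyotype %in% c("XX", "XXY") && !dropout) {
      products <- c(products, list(
        product_spec("XIST", config$xist_tm + xist_jit,
                     config$product_width, config$xist_abundance * scale)
      ))
    }
    if (dimer) {
      products <- c(products, list(
        product_spec("dimer", config$dimer_tm, config$dimer_width,
                     config$dimer_abundance)
      ))
    }

    well_scenario(
      well_id = well_id, sample_id = sample$sample_id, products = products,
      baseline_intercept = config$baseline_intercept * gain,
      baseline_slope = config$baseline_slope * gain,
      residual_fraction = config$residual_fraction,
      noise_sd = config$noise_sd,
      template_log10 = log10(yield / config$yield_ref),
      amplified = amplified,
      seed = if (is.null(seed)) NULL else derive_seed(seed, "noise")
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantification cycle from relative template input
#'
#' Standard-curve model `Cq = intercept - slope * log10(template)`; a Cq
#' beyond `max_cycles` is reported as non-amplified (`NA`). A slope of 3.32
#' cycles per ten-fold dilution corresponds to 100% PCR efficiency.
#'
#' @param template_log10 log10 relative template input (vectorized).
#' @param slope Standard-curve slope, > 0.
#' @param intercept Cq at log10 template 0.
#' @param max_cycles Number of cycles run.
#' @return Numeric Cq values, `NA` where the reaction never crosses threshold
#'   within `max_cycles`; negative computed Cq is clamped to 0.
#' @export
simulate_cq <- function(template_log10, slope = 3.32, intercept = 24,
                        max_cycles = 45L) {
  if (!is.numeric(slope) || slope <= 0) {
    abort("standard-curve slope must be > 0", "meltsex_value_error")
  }
  cq <- intercept - slope * template_log10
  cq[cq > max_cycles] <- NA_real_
  pmax(cq, 0)
}

cohort_yields <- function(n, profile, config) {
  prof <- config$cohort_profiles[[profile]]
  if (is.null(prof)) {
    abort(sprintf("unknown cohort profile '%s'", profile),
          "meltsex_value_error")
  }
  meanlog <- log(prof$mean) - prof$sdlog^2 / 2
  stats::rlnorm(n, meanlog, prof$sdlog)
}

#' Simulate a cohort: plates of melt curves, layout and sample truth
#'
#' Draws per-sample ground truth (sex, karyotype, RNA yield, ACTB
#' heterozygosity, known-female anchors), then simulates `replicates` wells
#' per sample on 96-well plates. Yields follow the cohort profile's
#' log-normal; at least one known-female anchor is present whenever any
#' female is simulated. All output is reproducible from `seed`; per-well
#' seeds are derived by stable hashing of `(seed, well_id)`.
#'
#' @param n_samples Number of individuals, >= 1.
#' @param sex_ratio Proportion of females in `[0, 1]`. The default 0.4
#'   mirrors a wild cohort with ~38 females per 101 sexed individuals.
#' @param cohort_profile One of `names(config$cohort_profiles)`.
#' @param seed Integer master seed.
#' @param replicates Wells per sample (default triplicate).
#' @param config A [sim_config()].
#' @param multi_plate Allow more than one 96-well plate; if `FALSE`,
#'   exceeding capacity is an error.
#' @param min_yield Optional lower truncation (ng/ul) for drawn RNA yields:
#'   yields below it are redrawn. Use to represent an adequate-yield cohort
#'   (every extraction above the reliability threshold); `NULL` leaves the
#'   profile untruncated.
#' @return A list with `curves` (named list of [melt_curve()]), `layout`
#'   (`well`, `sample_id`, `replicate`), `truth` (sample table including
#'   ground-truth and metadata columns), `metadata` (the metadata view of
#'   `truth`), `scenarios` (named list of [well_scenario()]) and `cq`
#'   (`well`, `cq`).
#' @export
simulate_cohort <- function(n_samples, sex_ratio = 0.4,
                            cohort_profile = "2021", seed = 1L,
                            replicates = 3L, config = sim_config(),
                            multi_plate = TRUE, min_yield = NULL) {
  if (n_samples < 1L) abort("n_samples must be >= 1", "meltsex_value_error")
  if (sex_ratio < 0 || sex_ratio > 1) {
    abort("sex_ratio must be in [0, 1]", "meltsex_value_error")
  }
  n_wells <- n_samples * replicates
  n_plates <- ceiling(n_wells / 96)
  if (n_plates > 1L && !multi_plate) {
    abort(sprintf("%d wells exceed one 96-well plate; set multi_plate = TRUE",
                  n_wells), "meltsex_value_error")
  }

  truth <- with_seed(seed, {
    sample_id <- sprintf("S%03d", seq_len(n_samples))
    n_female <- round(sex_ratio * n_samples)
    sex <- rep("male", n_samples)
    if (n_female > 0) {
      sex[sample.int(n_samples, n_female)] <- "female"
    }
    karyotype <- ifelse(sex == "female", "XX", "XY")
    if (config$xxy_prob > 0) {
      xxy <- sex == "male" & stats::runif(n_samples) < config$xxy_prob
      karyotype[xxy] <- "XXY"
    }
    yield <- cohort_yields(n_samples, cohort_profile, config)
    if (!is.null(min_yield)) {
      for (tries in seq_len(100L)) {
        low <- yield < min_yield
        if (!any(low)) break
        yield[low] <- cohort_yields(sum(low), cohort_profile, config)
      }
      yield <- pmax(yield, min_yield)
    }
    het <- stats::runif(n_samples) < config$het_prob
    anchor <- sex == "female" & stats::runif(n_samples) < config$anchor_prob
    if (any(sex == "female") && !any(anchor)) {
      anchor[which(sex == "female")[1L]] <- TRUE
    }
    data.frame(
      sample_id = sample_id,
      true_sex = sex,
      karyotype = karyotype,
      rna_yield = yield,
      cohort = cohort_profile,
      known_female_anchor = anchor,
      dna_sex = ifelse(karyotype == "XY", "male",
                       ifelse(karyotype == "XXY", "male", "female")),
      het_actb = het,
      stringsAsFactors = FALSE
    )
  })

  well_ids <- character(n_wells)
  layout <- data.frame(
    well = character(n_wells), sample_id = character(n_wells),
    replicate = integer(n_wells), stringsAsFactors = FALSE
  )
  k <- 0L
  for (i in seq_len(n_samples)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      plate <- (k - 1L) %/% 96L + 1L
      pos <- (k - 1L) %% 96L
      wid <- sprintf("%s%02d", LETTERS[pos %/% 12L + 1L], pos %% 12L + 1L)
      if (n_plates > 1L) wid <- sprintf("P%02d-%s", plate, wid)
      well_ids[k] <- wid
      layout$well[k] <- wid
      layout$sample_id[k] <- truth$sample_id[i]
      layout$replicate[k] <- r
    }
  }

  scenarios <- vector("list", n_wells)
  curves <- vector("list", n_wells)
  cq <- numeric(n_wells)
  for (k in seq_len(n_wells)) {
    i <- match(layout$sample_id[k], truth$sample_id)
    ws <- derive_seed(seed, layout$well[k])
    sc <- make_scenario(truth[i, ], replicate = layout$replicate[k],
                        config = config, seed = ws,
                        well_id = layout$well[k])
    scenarios[[k]] <- sc
    curves[[k]] <- simulate_well(sc, config$grid)
    cq[k] <- if (sc$amplified) {
      simulate_cq(sc$template_log10, config$cq_slope, config$cq_intercept,
                  config$max_cycles)
    } else {
      NA_real_
    }
  }
  names(scenarios) <- well_ids
  names(curves) <- well_ids

  metadata <- truth[, c("sample_id", "rna_yield", "dna_sex",
                        "known_female_anchor", "cohort")]
  list(
    curves = curves, layout = layout, truth = truth, metadata = metadata,
    scenarios = scenarios,
    cq = data.frame(well = well_ids, cq = cq, stringsAsFactors = FALSE)
  )
}
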