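# End-to-end orchestration: raw curves -> QC -> normalization -> peaks ->
# clustering -> sex mapping -> majority-rule calls -> concordance/report.

#' Run the full HRM sex-determination pipeline
#'
#' Steps: (1) amplitude/Cq well QC; (2) two-line normalization of passing
#' wells (degenerate baselines fail QC); (3) derivative melt-peak calling
#' with a plate-wide prominence floor; (4) shape/Tm agglomerative
#' clustering, flagging outlier clusters (which then fail QC); (5) medoid
#' reference selection and difference curves; (6) anchor/signature cluster
#' sex mapping; (7) per-sample >= 2/3 majority calls; (8) concordance
#' against DNA truth when metadata carries `dna_sex` labels.
#'
#' @param curves Named list of [melt_curve()] objects.
#' @param layout Plate layout (`well`, `sample_id`, `replicate`).
#' @param metadata Optional sample metadata (`sample_id`, `rna_yield`,
#'   `dna_sex`, `known_female_anchor`, `cohort`).
#' @param cq Optional Cq table (`well`, `cq`).
#' @param cluster_parameters A [cluster_params()].
#' @param hrm A [hrm_params()].
#' @param yield_cutoff Advisory low-yield cutoff (ng/ul).
#' @param seed Recorded in the report (the pipeline itself is
#'   deterministic).
#' @return A list of class `hrm_run` with elements `qc`, `normalized`,
#'   `peaks`, `clusters`, `reference_well_id`, `differences`, `sex_map`,
#'   `calls`, `concordance` (or `NULL`), `diagnostics`, `report`.
#' @export
run_hrm_pipeline <- function(curves, layout, metadata = NULL, cq = NULL,
                             cluster_parameters = cluster_params(),
                             hrm = hrm_params(), yield_cutoff = 9.0,
                             seed = NULL) {
  qc0 <- qc_wells(curves, cq = cq, params = hrm)
  pass <- qc0$well_id[qc0$passed]

  normalized <- list()
  norm_failed <- character(0)
  for (w in pass) {
    nc <- tryCatch(
      normalize_curve(curves[[w]], hrm$pre_window, hrm$post_window),
      meltsex_degenerate_baseline = function(e) NULL
    )
    if (is.null(nc)) norm_failed <- c(norm_failed, w) else
      normalized[[w]] <- nc
  }

  derivs <- lapply(curves[names(normalized)], negative_derivative,
                   sg_window = hrm$sg_window, sg_order = hrm$sg_order)
  global_max <- max(vapply(derivs, function(d) max(d$dfdt), numeric(1)), 0)
  floor_prom <- hrm$peak_prominence_frac * global_max
  peaks <- lapply(derivs, estimate_tms, min_prominence = floor_prom,
                  min_separation = hrm$min_peak_separation)

  clusters <- cluster_wells(normalized, peaks, cluster_parameters)
  qc <- qc_wells(curves, cq = cq, clusters = clusters, params = hrm,
                 norm_failed = norm_failed)

  final_pass <- qc$well_id[qc$passed]
  reference <- select_reference(normalized, qc_pass = final_pass)
  differences <- lapply(normalized, difference_curve,
                        reference = normalized[[reference]])

  sex_map <- map_clusters_to_sex(clusters, layout, metadata, peaks)
  calls <- call_sample_sex(layout, qc, clusters, sex_map,
                           metadata = metadata, yield_cutoff = yield_cutoff)
  diagnostics <- cluster_diagnostics(clusters, differences, peaks)

  conc <- NULL
  if (!is.null(metadata) && "dna_sex" %in% names(metadata) &&
      any(tolower(metadata$dna_sex) %in% c("female", "male"))) {
    conc <- concordance(calls, metadata)
  }
  yields <- if (!is.null(metadata) && "rna_yield" %in% names(metadata) &&
                any(!is.na(metadata$rna_yield))) {
    summarize_yields(metadata)
  } else {
    NULL
  }

  report <- run_report(
    qc = qc, clusters = clusters, calls = calls,
    concordance_report = conc, sex_map = sex_map, yield_summary = yields,
    params = list(
      shape_sensitivity = cluster_parameters$shape_sensitivity,
      tm_threshold = cluster_parameters$tm_threshold,
      min_cluster_size = cluster_parameters$min_cluster_size,
      theta_max = cluster_parameters$theta_max,
      pre_window = hrm$pre_window, post_window = hrm$post_window,
      yield_cutoff = yield_cutoff,
      reference_well_id = reference
    ),
    seed = seed
  )

  structure(
    list(qc = qc, normalized = normalized, peaks = peaks,
         clusters = clusters, reference_well_id = reference,
         differences = differences, sex_map = sex_map, calls = calls,
         concordance = conc, diagnostics = diagnostics, report = report),
    class = "hrm_run"
  )
}

#' @export
print.hrm_run <- function(x, ...) {
  tab <- x$clusters$clusters
  cat(sprintf(
    "HRM run: %d wells (%d pass QC), %d cluster(s) (%d primary), reference well %s\n",
    nrow(x$qc), sum(x$qc$passed), nrow(tab), sum(!tab$outlier),
    x$reference_well_id
  ))
  for (k in seq_len(nrow(tab))) {
    cat(sprintf("  cluster %d: %d wells, mean Tm %.2f C, sex %s%s\n",
                tab$cluster[k], tab$size[k], tab$mean_tm[k],
                x$sex_map[as.character(tab$cluster[k])],
                if (tab$outlier[k]) " [outlier]" else ""))
  }
  calls <- table(factor(x$calls$call,
                        levels = c("female", "male", "inconclusive",
                                   "insufficient")))
  cat("Calls:", paste(sprintf("%s=%d", names(calls), calls), collapse = " "),
      "\n")
  if (!is.null(x$concordance)) {
    cat(sprintf("Agreement with DNA truth: %.2f%% (%d/%d)\n",
                x$concordance$agreement_percent, x$concordance$n_agree,
                x$concordance$n_compared))
  }
  invisible(x)
}
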