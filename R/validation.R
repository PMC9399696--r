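# validation: agreement between RNA-based (XIST) sex calls and DNA-based
# truth labels, discordance characterization (including XXY candidates),
# cohort yield summaries and the machine-readable run report.

#' Concordance of sex calls with DNA-based truth
#'
#' Counts exact female/male matches; `inconclusive` and `insufficient`
#' calls count as disagreement but are itemized separately. Discordances
#' are tagged: RNA female with DNA male is an `xxy_candidate` (XIST
#' expression plus Y-chromosome presence); RNA male with DNA female on a
#' low-yield sample is `xist_dropout_suspected`; inconclusive or
#' insufficient calls on low-yield samples are `low_yield`; anything else
#' is `unexplained`. Samples without a usable truth label are excluded from
#' `n_compared` and listed.
#'
#' @param calls [call_sample_sex()] output.
#' @param truth Data frame with `sample_id`, `dna_sex`
#'   (`female|male|unknown`).
#' @return A list of class `concordance_report`: `n_compared`, `n_agree`,
#'   `agreement_percent`, `confusion` (truth x call table), `discordant`
#'   (data frame with per-sample `reason`), `excluded` (sample ids without
#'   truth labels).
#' @export
concordance <- function(calls, truth) {
  m <- match(calls$sample_id, truth$sample_id)
  dna <- tolower(truth$dna_sex[m])
  usable <- !is.na(dna) & dna %in% c("female", "male")
  excluded <- calls$sample_id[!usable]
  cmp <- calls[usable, , drop = FALSE]
  dna <- dna[usable]
  if (nrow(cmp) == 0L) {
    abort("no samples with usable DNA truth labels to compare",
          "meltsex_value_error")
  }
  agree <- cmp$call == dna
  n_compared <- nrow(cmp)
  n_agree <- sum(agree)

  confusion <- table(
    dna = factor(dna, levels = c("female", "male")),
    call = factor(cmp$call,
                  levels = c("female", "male", "inconclusive", "insufficient"))
  )

  disc <- cmp[!agree, , drop = FALSE]
  reason <- character(nrow(disc))
  if (nrow(disc) > 0L) {
    dna_d <- dna[!agree]
    low <- grepl("low_yield", disc$flags)
    for (k in seq_len(nrow(disc))) {
      reason[k] <- if (disc$call[k] == "female" && dna_d[k] == "male") {
        "xxy_candidate"
      } else if (disc$call[k] == "male" && dna_d[k] == "female" && low[k]) {
        "xist_dropout_suspected"
      } else if (disc$call[k] %in% c("inconclusive", "insufficient") &&
                 low[k]) {
        "low_yield"
      } else {
        "unexplained"
      }
    }
  }
  discordant <- data.frame(
    sample_id = disc$sample_id, call = disc$call,
    dna_sex = dna[!agree], flags = disc$flags, reason = reason,
    stringsAsFactors = FALSE
  )

  structure(
    list(
      n_compared = n_compared, n_agree = n_agree,
      agreement_percent = 100 * n_agree / n_compared,
      confusion = confusion, discordant = discordant, excluded = excluded
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance: %d / %d samples agree (%.2f%%)\n",
              x$n_agree, x$n_compared, x$agreement_percent))
  print(x$confusion)
  if (nrow(x$discordant) > 0L) {
    cat("Discordant samples:\n")
    print(x$discordant, row.names = FALSE)
  }
  if (length(x$excluded) > 0L) {
    cat("Excluded (no DNA truth):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-cohort RNA yield summaries
#'
#' Five-number summary plus mean of RNA yields (ng/ul), grouped by cohort.
#'
#' @param metadata Data frame with `rna_yield` and `cohort`.
#' @return Data frame `cohort`, `n`, `mean`, `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @export
summarize_yields <- function(metadata) {
  keep <- !is.na(metadata$rna_yield)
  md <- metadata[keep, , drop = FALSE]
  if (nrow(md) == 0L) abort("no yields to summarize", "meltsex_value_error")
  cohorts <- unique(md$cohort)
  out <- lapply(cohorts, function(ch) {
    y <- md$rna_yield[md$cohort == ch | (is.na(md$cohort) & is.na(ch))]
    q <- stats::quantile(y, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(
      cohort = ch, n = length(y), mean = mean(y),
      min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Machine-readable run report
#'
#' Collects parameters, QC counts, the cluster table, per-sample calls,
#' concordance (when truth labels were available — marked absent otherwise,
#' never zero), yield summaries and the package version into one list,
#' serializable as JSON by [write_outputs()]. Deterministic given the same
#' inputs (no timestamps).
#'
#' @param qc [qc_wells()] output.
#' @param clusters A [cluster_wells()] result.
#' @param calls [call_sample_sex()] output.
#' @param concordance_report Optional [concordance()] result.
#' @param sex_map Optional [map_clusters_to_sex()] output.
#' @param yield_summary Optional [summarize_yields()] output.
#' @param params Optional named list of run parameters to record.
#' @param seed Optional seed to record.
#' @return A nested list (the documented report schema).
#' @export
run_report <- function(qc, clusters, calls, concordance_report = NULL,
                       sex_map = NULL, yield_summary = NULL, params = NULL,
                       seed = NULL) {
  qc_counts <- as.list(table(qc$reason))
  rep_list <- list(
    package = "meltsex",
    version = as.character(utils::packageVersion("meltsex")),
    seed = seed,
    parameters = params,
    n_wells = nrow(qc),
    n_wells_pass = sum(qc$passed),
    qc_exclusions = qc_counts[names(qc_counts) != "none"],
    clusters = clusters$clusters,
    theta_shape = clusters$theta_shape,
    cluster_sex_map = if (is.null(sex_map)) NULL else as.list(sex_map),
    calls = calls,
    concordance = if (is.null(concordance_report)) {
      list(available = FALSE)
    } else {
      list(
        available = TRUE,
        n_compared = concordance_report$n_compared,
        n_agree = concordance_report$n_agree,
        agreement_percent = concordance_report$agreement_percent,
        confusion = as.data.frame(concordance_report$confusion),
        discordant = concordance_report$discordant,
        excluded = concordance_report$excluded
      )
    },
    yields = yield_summary
  )
  rep_list
}
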