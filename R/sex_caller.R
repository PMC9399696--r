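# sex_caller: well QC, cluster -> sex mapping via known-female anchors (with
# a melt-signature fallback), and per-sample calls under the >= 2/3 majority
# rule. Wells that did not amplify any product, wells with degenerate
# normalization baselines, and wells in outlier clusters are excluded from
# further analysis.

#' Well-level quality control
#'
#' A well fails as `non_amplified` when its amplified flag is `FALSE`, its
#' Cq is absent or at/beyond `max_cycles`, or its relative fluorescence drop
#' from the pre-melt to the post-melt region falls below `amplitude_floor`.
#' Wells whose normalization failed (degenerate baselines) and wells sorted
#' into outlier clusters are also excluded, each with its reason.
#'
#' @param curves Named list of [melt_curve()] objects.
#' @param cq Optional data frame (`well`, `cq`) or named numeric vector.
#' @param clusters Optional [cluster_wells()] result (fills the
#'   `outlier_cluster` reason).
#' @param params An [hrm_params()].
#' @param norm_failed Character vector of well ids whose normalization hit
#'   degenerate baselines.
#' @return Data frame `well_id`, `passed`, `reason`
#'   (`none|non_amplified|degenerate_baseline|outlier_cluster`).
#' @export
qc_wells <- function(curves, cq = NULL, clusters = NULL,
                     params = hrm_params(), norm_failed = character()) {
  ids <- names(curves)
  cqv <- rep(NA_real_, length(ids))
  has_cq <- rep(FALSE, length(ids))
  if (!is.null(cq)) {
    if (is.data.frame(cq)) {
      m <- match(ids, cq$well)
      cqv <- cq$cq[m]
      has_cq <- !is.na(m)
    } else {
      m <- match(ids, names(cq))
      cqv <- unname(cq[m])
      has_cq <- !is.na(m)
    }
  }
  reason <- rep("none", length(ids))
  for (k in seq_along(ids)) {
    cv <- curves[[ids[k]]]
    non_amp <- isFALSE(cv$amplified)
    if (!non_amp && has_cq[k] &&
        (is.na(cqv[k]) || cqv[k] >= params$max_cycles)) {
      non_amp <- TRUE
    }
    if (!non_amp) {
      pre <- mean(cv$rfu[cv$temperature >= params$pre_window[1] &
                           cv$temperature <= params$pre_window[2]])
      post <- mean(cv$rfu[cv$temperature >= params$post_window[1] &
                            cv$temperature <= params$post_window[2]])
      if (!is.finite(pre) || pre <= 0 ||
          (pre - post) / pre < params$amplitude_floor) {
        non_amp <- TRUE
      }
    }
    if (non_amp) {
      reason[k] <- "non_amplified"
    } else if (ids[k] %in% norm_failed) {
      reason[k] <- "degenerate_baseline"
    } else if (!is.null(clusters) && ids[k] %in% names(clusters$outlier) &&
               isTRUE(clusters$outlier[[ids[k]]])) {
      reason[k] <- "outlier_cluster"
    }
  }
  data.frame(well_id = ids, passed = reason == "none", reason = reason,
             stringsAsFactors = FALSE)
}

#' Map melt clusters to sexes
#'
#' Anchor rule first: the primary (non-outlier) cluster holding the majority
#' of known-female-anchor wells is the female cluster; with two primary
#' clusters the other is male. Fallback signature rule: a cluster whose
#' medoid shows >= 2 derivative peaks (secondary melt transition present)
#' is female, one with a single peak male. Anchors split evenly between
#' clusters, or anchor and signature rules pointing at different clusters,
#' leave all clusters unassigned with a warning rather than guessing.
#'
#' @param clusters A [cluster_wells()] result.
#' @param layout Plate layout (`well`, `sample_id`, `replicate`).
#' @param metadata Sample metadata with `known_female_anchor` (may be
#'   `NULL`: signature rule only).
#' @param peaks Named list of [estimate_tms()] outputs.
#' @return Named character vector cluster id -> `"female"|"male"|"unassigned"`
#'   with an `evidence` attribute (anchor well counts and medoid peak counts
#'   per cluster).
#' @export
map_clusters_to_sex <- function(clusters, layout, metadata = NULL,
                                peaks = NULL) {
  tab <- clusters$clusters
  primary <- tab$cluster[!tab$outlier]
  map <- rep("unassigned", nrow(tab))
  names(map) <- as.character(tab$cluster)

  medoid_peaks <- vapply(tab$medoid, function(w) {
    pk <- peaks[[w]]
    if (is.null(pk)) NA_integer_ else nrow(pk$peaks)
  }, integer(1))

  anchor_counts <- setNames(rep(0L, nrow(tab)), as.character(tab$cluster))
  anchor_samples <- character(0)
  if (!is.null(metadata) && any(isTRUE_vec(metadata$known_female_anchor))) {
    anchor_samples <-
      metadata$sample_id[isTRUE_vec(metadata$known_female_anchor)]
    anchor_wells <- layout$well[layout$sample_id %in% anchor_samples]
    anchor_wells <- anchor_wells[anchor_wells %in% names(clusters$labels)]
    anchor_wells <-
      anchor_wells[clusters$labels[anchor_wells] %in% primary]
    if (length(anchor_wells) > 0L) {
      tt <- table(clusters$labels[anchor_wells])
      anchor_counts[names(tt)] <- as.integer(tt)
    }
  }

  evidence <- data.frame(
    cluster = tab$cluster, size = tab$size, outlier = tab$outlier,
    anchor_wells = unname(anchor_counts[as.character(tab$cluster)]),
    medoid_n_peaks = medoid_peaks, stringsAsFactors = FALSE
  )
  finish <- function(map) {
    attr(map, "evidence") <- evidence
    map
  }

  if (length(primary) == 0L) {
    warning("no primary clusters; all clusters left unassigned")
    return(finish(map))
  }

  sig_female <- primary[!is.na(medoid_peaks[match(primary, tab$cluster)]) &
                          medoid_peaks[match(primary, tab$cluster)] >= 2L]

  prim_counts <- anchor_counts[as.character(primary)]
  if (sum(prim_counts) > 0L) {
    top <- which(prim_counts == max(prim_counts))
    if (length(top) > 1L) {
      warning("known-female anchor wells split evenly between clusters; sex mapping unassigned")
      return(finish(map))
    }
    fem <- primary[top]
    if (length(sig_female) > 0L && !(fem %in% sig_female)) {
      warning("anchor rule and melt-signature rule identify different female clusters; sex mapping unassigned")
      return(finish(map))
    }
    map[as.character(fem)] <- "female"
    others <- setdiff(primary, fem)
    if (length(others) == 1L) {
      map[as.character(others)] <- "male"
    } else if (length(others) > 1L) {
      for (cl in others) {
        npk <- medoid_peaks[match(cl, tab$cluster)]
        map[as.character(cl)] <-
          if (!is.na(npk) && npk >= 2L) "unassigned" else "male"
      }
    }
    return(finish(map))
  }

  # No anchors: signature rule only.
  sig <- ifelse(is.na(medoid_peaks[match(primary, tab$cluster)]), NA,
                ifelse(medoid_peaks[match(primary, tab$cluster)] >= 2L,
                       "female", "male"))
  if (length(primary) >= 2L && length(unique(sig[!is.na(sig)])) <= 1L) {
    warning("no anchors and no melt-signature separation between primary clusters; sex mapping unassigned")
    return(finish(map))
  }
  for (k in seq_along(primary)) {
    if (!is.na(sig[k])) map[as.character(primary[k])] <- sig[k]
  }
  finish(map)
}

#' Per-sample sex calls under the >= 2/3 majority rule
#'
#' For each sample the denominator is its QC-passing wells (outlier-cluster
#' wells are excluded from both numerator and denominator). The modal
#' cluster is the sex-mapped cluster holding most of those wells; the
#' sample is called that cluster's sex when the modal fraction is >= 2/3,
#' `inconclusive` otherwise, and `insufficient` when no well passes QC.
#' Samples with RNA yield below `yield_cutoff` carry an advisory
#' `low_yield` flag that never changes the call.
#'
#' @param layout Plate layout (`well`, `sample_id`, `replicate`).
#' @param qc [qc_wells()] output.
#' @param clusters A [cluster_wells()] result.
#' @param sex_map [map_clusters_to_sex()] output.
#' @param metadata Optional metadata with `rna_yield`.
#' @param yield_cutoff Advisory RNA-yield cutoff (ng/ul), strict less-than.
#' @return Data frame `sample_id`, `call`
#'   (`female|male|inconclusive|insufficient`), `n_wells_pass`, `n_modal`,
#'   `fraction_modal`, `cluster_label`, `flags`.
#' @export
call_sample_sex <- function(layout, qc, clusters, sex_map, metadata = NULL,
                            yield_cutoff = 9.0) {
  samples <- unique(layout$sample_id)
  missing_wells <- setdiff(layout$well, qc$well_id)
  if (length(missing_wells) > 0L) {
    abort(sprintf("layout well(s) absent from QC/clustering inputs: %s",
                  paste(missing_wells, collapse = ", ")),
          "meltsex_value_error")
  }
  gate <- yield_gate(metadata, cutoff = yield_cutoff)
  out <- lapply(samples, function(s) {
    wells <- layout$well[layout$sample_id == s]
    passed <- wells[qc$passed[match(wells, qc$well_id)]]
    n_pass <- length(passed)
    flags <- character(0)
    if (!is.null(gate) && s %in% gate$sample_id[gate$low_yield]) {
      flags <- c(flags, "low_yield")
    }
    if (n_pass == 0L) {
      return(data.frame(
        sample_id = s, call = "insufficient", n_wells_pass = 0L,
        n_modal = 0L, fraction_modal = NA_real_,
        cluster_label = NA_integer_,
        flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE
      ))
    }
    labs <- clusters$labels[passed]
    tt <- sort(table(labs), decreasing = TRUE)
    modal <- as.integer(names(tt)[1L])
    n_modal <- as.integer(tt[1L])
    frac <- n_modal / n_pass
    sex <- unname(sex_map[as.character(modal)])
    call <- if (!is.na(sex) && sex %in% c("female", "male") &&
                frac >= 2 / 3 - 1e-9) {
      sex
    } else {
      "inconclusive"
    }
    if (is.na(sex) || sex == "unassigned") {
      flags <- c(flags, "unassigned_cluster")
    }
    data.frame(
      sample_id = s, call = call, n_wells_pass = n_pass, n_modal = n_modal,
      fraction_modal = frac, cluster_label = modal,
      flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Advisory low-RNA-yield flags
#'
#' Samples with RNA yield strictly below `cutoff` are flagged `low_yield`
#' with the advisory to repeat the extraction; flags annotate but never
#' change sex calls. Below roughly 9-10 ng/ul, XIST detection becomes
#' unreliable (low-template dropout renders female wells male-like).
#'
#' @param metadata Data frame with `sample_id` and `rna_yield` (or `NULL`).
#' @param cutoff Yield cutoff in ng/ul (default 9.0), strict less-than.
#' @return Data frame `sample_id`, `rna_yield`, `low_yield`, `advisory`
#'   (or `NULL` when `metadata` is `NULL`).
#' @export
yield_gate <- function(metadata, cutoff = 9.0) {
  if (is.null(metadata)) return(NULL)
  if (cutoff <= 0) abort("cutoff must be > 0", "meltsex_value_error")
  low <- !is.na(metadata$rna_yield) & metadata$rna_yield < cutoff
  data.frame(
    sample_id = metadata$sample_id,
    rna_yield = metadata$rna_yield,
    low_yield = low,
    advisory = ifelse(low, "repeat extraction", ""),
    stringsAsFactors = FALSE
  )
}
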