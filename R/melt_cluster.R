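# melt_cluster: group wells into melt-profile clusters from two user-facing
# parameters, curve-shape sensitivity (%) and a Tm difference threshold (C),
# as HRM genotyping software exposes them. Agglomerative complete-linkage
# merging under both constraints; clusters below a minimum size are flagged
# as outliers (aberrant reactions such as primer dimers).

#' Clustering parameters
#'
#' @param shape_sensitivity Percent in `[1, 100]`. Low sensitivity merges
#'   broadly (presence/absence discrimination); high sensitivity splits on
#'   fine shape differences. The mapping to the merge threshold is
#'   `theta = theta_max * (1 - (s - 1) / 99)`, so the minimum (1%) gives the
#'   broadest clusters.
#' @param tm_threshold Maximum difference (C) in cluster mean primary Tm for
#'   a merge, in `(0, 2]`.
#' @param min_cluster_size Clusters smaller than this are flagged outliers
#'   (default 3, one sample's triplicate).
#' @param theta_max Shape-distance threshold at minimum sensitivity.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(shape_sensitivity = 1, tm_threshold = 1.0,
                           min_cluster_size = 3L, theta_max = 0.10) {
  if (shape_sensitivity < 1 || shape_sensitivity > 100) {
    abort("shape_sensitivity must be in [1, 100]", "meltsex_value_error")
  }
  if (tm_threshold <= 0 || tm_threshold > 2) {
    abort("tm_threshold must be in (0, 2]", "meltsex_value_error")
  }
  structure(as.list(environment()), class = "cluster_params")
}

shape_threshold <- function(params) {
  params$theta_max * (1 - (params$shape_sensitivity - 1) / 99)
}

#' Shape distance between two normalized melt curves
#'
#' Maximum absolute pointwise difference of the normalized values — the
#' dimensionless realization of "melt curve shape sensitivity".
#'
#' @param a,b [normalize_curve()] outputs on identical analysis windows.
#' @return A distance in `[0, 1]`.
#' @export
shape_distance <- function(a, b) {
  if (length(a$temperature) != length(b$temperature) ||
      any(abs(a$temperature - b$temperature) > 1e-9)) {
    abort("shape_distance requires identical analysis grids",
          "meltsex_value_error")
  }
  max(abs(a$values - b$values))
}

primary_tm_of <- function(pk) {
  if (is.null(pk) || nrow(pk$peaks) == 0L) return(NA_real_)
  pk$peaks$tm[which.max(pk$peaks$prominence)]
}

#' Cluster wells by melt-curve shape and Tm
#'
#' Agglomerative merging from singletons: at each step the pair of clusters
#' with the smallest complete-linkage shape distance is merged, provided the
#' distance does not exceed the sensitivity-derived threshold AND the
#' clusters' mean primary Tms differ by at most `tm_threshold`; merging
#' stops when no pair qualifies. Deterministic and invariant to well input
#' order: wells are processed in lexicographic id order and ties break
#' toward the smallest cluster pair. Final cluster ids are assigned by
#' decreasing size (ties by smallest member well id); clusters smaller than
#' `min_cluster_size` are flagged outliers.
#'
#' @param normalized Named list of [normalize_curve()] outputs (QC-passing
#'   wells).
#' @param peaks Named list of [estimate_tms()] outputs for the same wells
#'   (used for per-well primary Tm = highest-prominence peak).
#' @param params A [cluster_params()].
#' @return A list of class `cluster_result`: `labels` (named integer vector
#'   well -> cluster), `outlier` (named logical), `primary_tm` (named
#'   numeric per well), `clusters` (per-cluster summary data frame with
#'   size, mean primary Tm, medoid well, outlier flag), `theta_shape`,
#'   `params`.
#' @export
cluster_wells <- function(normalized, peaks, params = cluster_params()) {
  ids <- sort(names(normalized))
  if (length(ids) == 0L) abort("no wells to cluster", "meltsex_value_error")
  theta <- shape_threshold(params)
  V <- do.call(rbind, lapply(normalized[ids], function(x) x$values))
  rownames(V) <- ids
  D <- as.matrix(stats::dist(V, method = "maximum"))
  well_tm <- vapply(ids, function(w) primary_tm_of(peaks[[w]]), numeric(1))

  n <- length(ids)
  alive <- rep(TRUE, n)
  members <- as.list(seq_len(n))
  M <- D
  diag(M) <- Inf
  tm_sum <- ifelse(is.na(well_tm), 0, well_tm)
  tm_n <- as.numeric(!is.na(well_tm))

  mean_tm <- function() ifelse(tm_n > 0, tm_sum / pmax(tm_n, 1), NA_real_)

  while (sum(alive) > 1L) {
    mt <- mean_tm()
    dt <- abs(outer(mt, mt, `-`))
    ok_tm <- is.na(dt) | dt <= params$tm_threshold
    Q <- M <= theta & ok_tm
    Q[!alive, ] <- FALSE
    Q[, !alive] <- FALSE
    Q[lower.tri(Q, diag = TRUE)] <- FALSE
    if (!any(Q)) break
    cand <- which(Q, arr.ind = TRUE)
    d <- M[cand]
    best <- cand[order(d, cand[, 1L], cand[, 2L])[1L], ]
    a <- best[1L]; b <- best[2L]
    members[[a]] <- c(members[[a]], members[[b]])
    alive[b] <- FALSE
    tm_sum[a] <- tm_sum[a] + tm_sum[b]
    tm_n[a] <- tm_n[a] + tm_n[b]
    newrow <- pmax(M[a, ], M[b, ])
    M[a, ] <- newrow
    M[, a] <- newrow
    M[a, a] <- Inf
    M[b, ] <- Inf
    M[, b] <- Inf
  }

  groups <- members[alive]
  sizes <- vapply(groups, length, integer(1))
  firsts <- vapply(groups, function(g) ids[min(g)], character(1))
  ord <- order(-sizes, firsts)
  groups <- groups[ord]
  sizes <- sizes[ord]

  labels <- integer(n)
  for (k in seq_along(groups)) labels[groups[[k]]] <- k
  names(labels) <- ids
  outlier_cluster <- sizes < params$min_cluster_size
  outlier <- outlier_cluster[labels]
  names(outlier) <- ids

  medoids <- vapply(groups, function(g) {
    gw <- ids[sort(g)]
    if (length(gw) == 1L) return(gw)
    sub <- D[gw, gw, drop = FALSE]
    gw[which.min(rowSums(sub))]
  }, character(1))
  mtm <- vapply(groups, function(g) {
    v <- well_tm[g]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))

  structure(
    list(
      labels = labels,
      outlier = outlier,
      primary_tm = well_tm,
      clusters = data.frame(
        cluster = seq_along(groups), size = sizes, mean_tm = mtm,
        medoid = medoids, outlier = outlier_cluster,
        stringsAsFactors = FALSE
      ),
      theta_shape = theta,
      params = params
    ),
    class = "cluster_result"
  )
}

#' Per-cluster melt-signature diagnostics
#'
#' Summarizes the features that distinguish sex clusters: presence of a
#' secondary melt transition (the cluster medoid shows >= 2 derivative
#' peaks), the temperature and depth of the largest negative
#' difference-curve excursion (cluster mean), and the mean number of
#' derivative peaks per well.
#'
#' @param result A [cluster_wells()] result.
#' @param differences Named list of [difference_curve()] outputs.
#' @param peaks Named list of [estimate_tms()] outputs.
#' @return A data frame, one row per cluster.
#' @export
cluster_diagnostics <- function(result, differences, peaks) {
  out <- result$clusters
  out$mean_n_peaks <- NA_real_
  out$secondary_transition <- NA
  out$min_diff_temperature <- NA_real_
  out$min_diff_value <- NA_real_
  for (k in seq_len(nrow(out))) {
    wells <- names(result$labels)[result$labels == out$cluster[k]]
    npk <- vapply(wells, function(w) {
      pk <- peaks[[w]]
      if (is.null(pk)) NA_real_ else as.numeric(nrow(pk$peaks))
    }, numeric(1))
    out$mean_n_peaks[k] <- mean(npk, na.rm = TRUE)
    med <- peaks[[out$medoid[k]]]
    out$secondary_transition[k] <- !is.null(med) && nrow(med$peaks) >= 2L
    dws <- wells[wells %in% names(differences)]
    if (length(dws) > 0L) {
      dm <- colMeans(do.call(rbind,
                             lapply(differences[dws], function(x) x$values)))
      temp <- differences[[dws[1L]]]$temperature
      i <- which.min(dm)
      out$min_diff_temperature[k] <- temp[i]
      out$min_diff_value[k] <- dm[i]
    }
  }
  out
}
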