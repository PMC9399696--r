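# Independent oracles and fixture builders shared across tests. These
# re-implement checks by brute force / naive scanning, deliberately sharing
# no code with the package internals they verify.

default_grid <- seq(70, 95, by = 0.5)

# Noiseless single- or multi-product well built directly from the melt model.
fixture_scenario <- function(well_id, products, noise_sd = 0, seed = NULL,
                             sample_id = well_id, amplified = TRUE,
                             b0 = 3000, b1 = -15) {
  well_scenario(
    well_id = well_id, sample_id = sample_id, products = products,
    baseline_intercept = b0, baseline_slope = b1,
    residual_fraction = 0.05, noise_sd = noise_sd, amplified = amplified,
    seed = seed
  )
}

female_products <- function(xist_ab = 0.55, width = 0.2) {
  list(product_spec("ACTB", 85.5, width, 1.0),
       product_spec("XIST", 84.0, width, xist_ab))
}
male_products <- function(width = 0.2) {
  list(product_spec("ACTB", 85.5, width, 1.0))
}

female_well <- function(well_id, noise_sd = 0, seed = NULL, ...) {
  simulate_well(fixture_scenario(well_id, female_products(),
                                 noise_sd = noise_sd, seed = seed, ...),
                default_grid)
}
male_well <- function(well_id, noise_sd = 0, seed = NULL, ...) {
  simulate_well(fixture_scenario(well_id, male_products(),
                                 noise_sd = noise_sd, seed = seed, ...),
                default_grid)
}

# Dense-grid argmax oracle for the derivative-peak temperature of a
# noiseless scenario: evaluates the melt model analytically on a fine grid
# and differentiates numerically.
oracle_peak_tms <- function(products, b0 = 3000, b1 = -15, residual = 0.05,
                            step = 0.005) {
  tt <- seq(70, 95, by = step)
  s <- rep(residual, length(tt))
  for (p in products) {
    s <- s + p$abundance / (1 + exp((tt - p$tm) / p$width))
  }
  f <- (b0 + b1 * tt) * s
  d <- -(f[-1] - f[-length(f)]) / step
  tmid <- (tt[-1] + tt[-length(tt)]) / 2
  # local maxima on the dense grid, strongest first
  i <- which(d[2:(length(d) - 1)] > d[1:(length(d) - 2)] &
               d[2:(length(d) - 1)] >= d[3:length(d)]) + 1L
  i <- i[order(d[i], decreasing = TRUE)]
  tmid[i]
}

# Brute-force medoid: well minimizing summed max-abs distance, ties by
# lexicographic well id.
oracle_medoid <- function(normalized, ids = names(normalized)) {
  ids <- sort(ids)
  best <- NULL
  best_sum <- Inf
  for (a in ids) {
    s <- 0
    for (b in ids) {
      s <- s + max(abs(normalized[[a]]$values - normalized[[b]]$values))
    }
    if (s < best_sum - 1e-12) {
      best_sum <- s
      best <- a
    }
  }
  best
}

# From-scratch re-implementation of the dual-constraint complete-linkage
# agglomeration: recomputes all linkage distances from the raw value matrix
# at every step (no incremental updates).
oracle_cluster <- function(normalized, tms, theta, tm_thr) {
  ids <- sort(names(normalized))
  V <- do.call(rbind, lapply(normalized[ids], function(x) x$values))
  groups <- lapply(seq_along(ids), function(i) i)
  link <- function(g1, g2) {
    m <- 0
    for (i in g1) for (j in g2) {
      m <- max(m, max(abs(V[i, ] - V[j, ])))
    }
    m
  }
  gtm <- function(g) {
    v <- tms[ids[g]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  repeat {
    best <- NULL
    best_d <- Inf
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (b <= a) next
        d <- link(groups[[a]], groups[[b]])
        if (d > theta) next
        ta <- gtm(groups[[a]])
        tb <- gtm(groups[[b]])
        if (!is.na(ta) && !is.na(tb) && abs(ta - tb) > tm_thr) next
        if (d < best_d - 1e-15) {
          best_d <- d
          best <- c(a, b)
        }
      }
    }
    if (is.null(best)) break
    groups[[best[1]]] <- sort(c(groups[[best[1]]], groups[[best[2]]]))
    groups <- groups[-best[2]]
  }
  canonical_partition(lapply(groups, function(g) ids[g]))
}

# Exhaustive enumeration of all qualifying merge orders (small n): returns
# the set of terminal partitions reachable under the same merge predicate.
oracle_reachable_partitions <- function(normalized, tms, theta, tm_thr) {
  ids <- sort(names(normalized))
  V <- do.call(rbind, lapply(normalized[ids], function(x) x$values))
  link <- function(g1, g2) {
    m <- 0
    for (i in g1) for (j in g2) m <- max(m, max(abs(V[i, ] - V[j, ])))
    m
  }
  gtm <- function(g) {
    v <- tms[ids[g]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  seen <- new.env(parent = emptyenv())
  terminals <- list()
  recurse <- function(groups) {
    key <- paste(vapply(lapply(groups, function(g) ids[g]), paste,
                        character(1), collapse = ","), collapse = "|")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    any_merge <- FALSE
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (b <= a) next
        if (link(groups[[a]], groups[[b]]) > theta) next
        ta <- gtm(groups[[a]])
        tb <- gtm(groups[[b]])
        if (!is.na(ta) && !is.na(tb) && abs(ta - tb) > tm_thr) next
        any_merge <- TRUE
        ng <- groups
        ng[[a]] <- sort(c(ng[[a]], ng[[b]]))
        ng <- ng[-b]
        recurse(ng)
      }
    }
    if (!any_merge) {
      terminals[[length(terminals) + 1L]] <<-
        canonical_partition(lapply(groups, function(g) ids[g]))
    }
    invisible()
  }
  recurse(lapply(seq_along(ids), function(i) i))
  unique(terminals)
}

# Canonical representation of a partition (order-free comparison).
canonical_partition <- function(groups) {
  out <- unname(lapply(groups, function(g) unname(sort(as.character(g)))))
  out[order(vapply(out, `[`, character(1), 1L))]
}

partition_of <- function(labels) {
  canonical_partition(split(names(labels), labels))
}

# Naive O(n*m) exact scan for in-silico PCR hits on the plus strand of a
# template given as a character string; returns 0-based half-open hits.
naive_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
naive_find_all <- function(template, pattern) {
  n <- nchar(template)
  m <- nchar(pattern)
  out <- integer(0)
  if (m > n) return(out)
  for (i in seq_len(n - m + 1L)) {
    if (substr(template, i, i + m - 1L) == pattern) out <- c(out, i)
  }
  out
}
naive_pcr_plus <- function(template, fwd, rev, max_len = 2000L) {
  fs <- naive_find_all(template, fwd)
  rs <- naive_find_all(template, naive_revcomp(rev))
  hits <- list()
  for (s in fs) {
    for (r in rs) {
      e <- r + nchar(rev) - 1L
      if (r >= s + nchar(fwd) && (e - s + 1L) <= max_len) {
        hits[[length(hits) + 1L]] <- c(start = s - 1L, end = e)
      }
    }
  }
  hits
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
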