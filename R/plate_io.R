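# plate_io: tabular artifacts — long-format melt CSVs, plate layouts, sample
# metadata, per-well cluster tables, per-sample calls and machine-readable
# run reports. All parsers are strict: malformed numerics are errors, never
# silent coercions.

#' Raw melt curve for one well
#'
#' @param well_id Well identifier.
#' @param temperature Ascending uniform temperature grid (C), >= 20 points.
#' @param rfu Fluorescence values (arbitrary units), same length, all finite.
#' @param amplified Logical flag; `NA` means unknown (inferred later by QC).
#' @return A list of class `melt_curve`.
#' @export
melt_curve <- function(well_id, temperature, rfu, amplified = NA) {
  temperature <- as.numeric(temperature)
  rfu <- as.numeric(rfu)
  if (length(temperature) < 20L) {
    abort(sprintf("well '%s': melt curve needs >= 20 points", well_id),
          "meltsex_format_error")
  }
  if (length(rfu) != length(temperature)) {
    abort(sprintf("well '%s': temperature/RFU length mismatch", well_id),
          "meltsex_format_error")
  }
  if (!is_uniform_grid(temperature)) {
    abort(sprintf(
      "well '%s': temperatures must be strictly increasing on a uniform grid",
      well_id
    ), "meltsex_format_error")
  }
  if (!all(is.finite(rfu))) {
    abort(sprintf("well '%s': non-finite RFU values", well_id),
          "meltsex_format_error")
  }
  structure(
    list(well_id = as.character(well_id), temperature = temperature,
         rfu = rfu, amplified = amplified),
    class = "melt_curve"
  )
}

#' Read long-format melt curves
#'
#' Expects a CSV with header `well,temperature,rfu` and optionally
#' `amplified`. Each well must sit on the same uniform temperature grid;
#' ragged wells are rejected with an error naming the offending well.
#'
#' @param path CSV path.
#' @return A named list of [melt_curve()] objects, ordered by well id.
#' @export
read_melt_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("well", "temperature", "rfu")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("melt CSV '%s' lacks column(s): %s", path,
                  paste(missing_cols, collapse = ", ")),
          "meltsex_format_error")
  }
  temperature <- parse_numeric(raw$temperature, "temperature", path)
  rfu <- parse_numeric(raw$rfu, "rfu", path)
  amplified <- if ("amplified" %in% names(raw)) {
    parse_logical(raw$amplified, "amplified", path)
  } else {
    rep(NA, nrow(raw))
  }
  wells <- sort(unique(raw$well))
  lengths <- table(raw$well)
  if (length(unique(as.integer(lengths))) > 1L) {
    modal <- as.integer(names(sort(table(as.integer(lengths)),
                                   decreasing = TRUE))[1L])
    bad <- names(lengths)[as.integer(lengths) != modal]
    abort(sprintf("melt CSV '%s': ragged temperature grid for well(s): %s",
                  path, paste(bad, collapse = ", ")),
          "meltsex_format_error")
  }
  curves <- lapply(wells, function(w) {
    idx <- which(raw$well == w)
    idx <- idx[order(temperature[idx])]
    amp <- amplified[idx]
    amp <- if (all(is.na(amp))) NA else all(amp, na.rm = TRUE)
    melt_curve(w, temperature[idx], rfu[idx], amplified = amp)
  })
  names(curves) <- wells
  curves
}

fmt_num <- function(x) sprintf("%.10g", x)

#' Write long-format melt curves
#'
#' Inverse of [read_melt_csv()]: temperatures at 2 decimals, RFU at full
#' working precision so write/read round-trips preserve values.
#'
#' @param curves Named list of [melt_curve()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_melt_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(
      well = cv$well_id,
      temperature = sprintf("%.2f", cv$temperature),
      rfu = fmt_num(cv$rfu),
      amplified = if (is.na(cv$amplified)) "" else tolower(cv$amplified),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read plate layout and sample metadata
#'
#' The layout CSV maps wells to samples (`well,sample_id,replicate`); the
#' metadata CSV carries per-sample annotation
#' (`sample_id,rna_yield,dna_sex,known_female_anchor,cohort`). Duplicate
#' well or sample ids are errors. Layout samples missing from the metadata
#' produce a warning and a stub row with unknown DNA sex.
#'
#' @param layout_path,metadata_path CSV paths.
#' @return `list(layout =, metadata =)` of data frames.
#' @export
read_layout_and_metadata <- function(layout_path, metadata_path) {
  lay <- utils::read.csv(layout_path, colClasses = "character",
                         check.names = FALSE)
  need <- c("well", "sample_id", "replicate")
  if (length(setdiff(need, names(lay))) > 0L) {
    abort(sprintf("layout CSV '%s' must have columns %s", layout_path,
                  paste(need, collapse = ",")), "meltsex_format_error")
  }
  if (anyDuplicated(lay$well)) {
    abort(sprintf("duplicate well id '%s' in layout",
                  lay$well[duplicated(lay$well)][1L]),
          "meltsex_format_error")
  }
  layout <- data.frame(
    well = lay$well, sample_id = lay$sample_id,
    replicate = as.integer(parse_numeric(lay$replicate, "replicate",
                                         layout_path)),
    stringsAsFactors = FALSE
  )

  md <- utils::read.csv(metadata_path, colClasses = "character",
                        check.names = FALSE)
  if (!"sample_id" %in% names(md)) {
    abort(sprintf("metadata CSV '%s' lacks column sample_id", metadata_path),
          "meltsex_format_error")
  }
  if (anyDuplicated(md$sample_id)) {
    abort(sprintf("duplicate sample id '%s' in metadata",
                  md$sample_id[duplicated(md$sample_id)][1L]),
          "meltsex_format_error")
  }
  yield_chr <- if ("rna_yield" %in% names(md)) md$rna_yield else
    rep("", nrow(md))
  yield <- rep(NA_real_, nrow(md))
  has <- !(trimws(yield_chr) %in% c("", "NA", "na"))
  yield[has] <- parse_numeric(yield_chr[has], "rna_yield", metadata_path)
  if (any(yield[has] <= 0)) {
    abort("rna_yield must be > 0 when present", "meltsex_format_error")
  }
  metadata <- data.frame(
    sample_id = md$sample_id,
    rna_yield = yield,
    dna_sex = if ("dna_sex" %in% names(md)) tolower(md$dna_sex) else "unknown",
    known_female_anchor = if ("known_female_anchor" %in% names(md)) {
      isTRUE_vec(parse_logical(md$known_female_anchor, "known_female_anchor",
                               metadata_path))
    } else {
      rep(FALSE, nrow(md))
    },
    cohort = if ("cohort" %in% names(md)) md$cohort else NA_character_,
    stringsAsFactors = FALSE
  )
  bad_sex <- !metadata$dna_sex %in% c("female", "male", "unknown")
  if (any(bad_sex)) {
    abort(sprintf("dna_sex must be female|male|unknown (got '%s')",
                  metadata$dna_sex[bad_sex][1L]), "meltsex_format_error")
  }

  orphans <- setdiff(layout$sample_id, metadata$sample_id)
  if (length(orphans) > 0L) {
    warning(sprintf(
      "sample(s) %s present in layout but absent from metadata; stub rows with unknown DNA sex added",
      paste(orphans, collapse = ", ")
    ))
    stub <- data.frame(
      sample_id = orphans, rna_yield = NA_real_, dna_sex = "unknown",
      known_female_anchor = FALSE, cohort = NA_character_,
      stringsAsFactors = FALSE
    )
    metadata <- rbind(metadata, stub)
  }
  list(layout = layout, metadata = metadata)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write a plate layout CSV
#' @param layout Data frame with `well`, `sample_id`, `replicate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(layout[, c("well", "sample_id", "replicate")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sample metadata CSV
#' @param metadata Data frame with `sample_id`, `rna_yield`, `dna_sex`,
#'   `known_female_anchor`, `cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata_csv <- function(metadata, path) {
  out <- metadata[, c("sample_id", "rna_yield", "dna_sex",
                      "known_female_anchor", "cohort")]
  out$rna_yield <- ifelse(is.na(out$rna_yield), "", fmt_num(out$rna_yield))
  out$known_female_anchor <- tolower(out$known_female_anchor)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-well cluster table
#'
#' Flattens a [cluster_wells()] result into the exported cluster CSV dialect
#' (`well,sample_id,cluster,outlier,primary_tm`).
#'
#' @param clusters A `cluster_result`.
#' @param layout Plate layout data frame.
#' @return A data frame, one row per clustered well.
#' @export
cluster_table <- function(clusters, layout) {
  wells <- names(clusters$labels)
  data.frame(
    well = wells,
    sample_id = layout$sample_id[match(wells, layout$well)],
    cluster = unname(clusters$labels),
    outlier = unname(clusters$outlier[wells]),
    primary_tm = unname(clusters$primary_tm[wells]),
    stringsAsFactors = FALSE
  )
}

#' Write pipeline outputs
#'
#' Writes `calls.csv` (per-sample sex calls), `clusters.csv` (per-well
#' cluster assignments) and `report.json` (machine-readable run report) into
#' `out_dir`. Deterministic: rerunning with the same inputs produces
#' byte-identical data rows.
#'
#' @param calls Sex-call data frame from [call_sample_sex()].
#' @param clusters Per-well cluster data frame (see [cluster_table()]).
#' @param report Run report list from [run_report()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_outputs <- function(calls, clusters, report, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      abort(sprintf("cannot create output directory '%s'", out_dir),
            "meltsex_io_error")
    }
  }
  calls_path <- file.path(out_dir, "calls.csv")
  clusters_path <- file.path(out_dir, "clusters.csv")
  report_path <- file.path(out_dir, "report.json")
  cols <- c("sample_id", "call", "n_wells_pass", "n_modal", "fraction_modal",
            "cluster_label", "flags")
  out_calls <- calls[, cols, drop = FALSE]
  out_calls$fraction_modal <- ifelse(is.na(out_calls$fraction_modal), "",
                                     fmt_num(out_calls$fraction_modal))
  utils::write.csv(out_calls, calls_path, row.names = FALSE, quote = FALSE)
  out_cl <- clusters
  out_cl$primary_tm <- ifelse(is.na(out_cl$primary_tm), "",
                              fmt_num(out_cl$primary_tm))
  utils::write.csv(out_cl, clusters_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(calls = calls_path, clusters = clusters_path,
              report = report_path))
}
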