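# assay_design: exact-match in-silico PCR on user-provided templates and
# empirical amplicon Tm prediction. Supports simulator calibration and
# primer sanity checks; deliberately not a genome-scale or mismatch-tolerant
# search.

#' Primer pair
#'
#' @param name Assay label.
#' @param forward,reverse 5'->3' sequences over `{A, C, G, T}`, >= 15 nt.
#' @return A list of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse) {
  forward <- toupper(forward)
  reverse <- toupper(reverse)
  for (s in c(forward, reverse)) {
    if (nchar(s) < 15L) {
      abort("primers must be >= 15 nt", "meltsex_value_error")
    }
    if (grepl("[^ACGT]", s)) {
      abort(sprintf("primer '%s' contains non-ACGT characters", s),
            "meltsex_value_error")
    }
  }
  structure(list(name = as.character(name), forward = forward,
                 reverse = reverse), class = "primer_pair")
}

#' Duplex assay primers
#'
#' The humpback-whale duplex sex assay primer pairs: an ACTB (beta-actin)
#' control pair and the female-specific XIST pair.
#'
#' @return Named list of two [primer_pair()] objects.
#' @export
duplex_assay_primers <- function() {
  list(
    ACTB = primer_pair("ACTB_mn01", "AAGATCCTCACGGAGCGTGG",
                       "TGATCACCTGACCATCGGGC"),
    XIST = primer_pair("XIST_mn01", "CCGTTACATTCTTGGCGGGC",
                       "TCCTCCACTAACTGGCTGCG")
  )
}

#' Exact-match in-silico PCR
#'
#' Finds all loci where the forward primer matches one strand and the
#' reverse complement of the reverse primer matches downstream within
#' `max_len`; both orientations are searched. Coordinates are 0-based,
#' half-open, on the forward strand of the template; minus-strand hits
#' carry `strand = "-"`.
#'
#' @param template A nucleotide sequence (character scalar,
#'   `Biostrings::DNAString`, or a named character vector / `DNAStringSet`
#'   of several templates).
#' @param pair A [primer_pair()].
#' @param max_len Maximum product length in bp (default 2000).
#' @return Data frame `template`, `start`, `end`, `strand`, `length`, `gc`,
#'   `predicted_tm` (C, via [product_tm()]).
#' @export
find_amplicons <- function(template, pair, max_len = 2000L) {
  stopifnot(inherits(pair, "primer_pair"))
  if (inherits(template, "DNAString")) {
    template <- stats::setNames(as.character(template), "template")
  } else if (inherits(template, "DNAStringSet")) {
    template <- stats::setNames(as.character(template), names(template))
  } else {
    template <- as.character(template)
    if (is.null(names(template))) {
      names(template) <- if (length(template) == 1L) "template" else
        sprintf("template%d", seq_along(template))
    }
  }
  out <- lapply(names(template), function(tid) {
    seq_chr <- toupper(template[[tid]])
    plus <- scan_strand(seq_chr, pair, max_len)
    minus <- scan_strand(revcomp_chr(seq_chr), pair, max_len)
    L <- nchar(seq_chr)
    if (nrow(minus) > 0L) {
      # map rc coordinates (0-based half-open) back to the forward strand
      s <- L - minus$end
      e <- L - minus$start
      minus$start <- s
      minus$end <- e
      minus$strand <- "-"
    }
    hits <- rbind(plus, minus)
    if (nrow(hits) == 0L) {
      return(data.frame(
        template = character(0), start = integer(0), end = integer(0),
        strand = character(0), length = integer(0), gc = numeric(0),
        predicted_tm = numeric(0), stringsAsFactors = FALSE
      ))
    }
    hits$template <- tid
    amp <- substring(seq_chr, hits$start + 1L, hits$end)
    hits$gc <- vapply(amp, function(a) {
      n <- nchar(a)
      if (n == 0L) return(NA_real_)
      sum(strsplit(a, "")[[1]] %in% c("G", "C")) / n
    }, numeric(1), USE.NAMES = FALSE)
    hits$predicted_tm <- vapply(seq_len(nrow(hits)), function(k) {
      if (hits$length[k] >= 40L) {
        product_tm(hits$length[k], hits$gc[k])
      } else {
        NA_real_
      }
    }, numeric(1))
    hits[order(hits$start, hits$end),
         c("template", "start", "end", "strand", "length", "gc",
           "predicted_tm")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# One-strand exact scan via Biostrings pattern matching; returns 0-based
# half-open hits on the scanned strand.
scan_strand <- function(seq_chr, pair, max_len) {
  subj <- Biostrings::DNAString(seq_chr)
  f <- Biostrings::matchPattern(Biostrings::DNAString(pair$forward), subj)
  rrc <- Biostrings::reverseComplement(Biostrings::DNAString(pair$reverse))
  r <- Biostrings::matchPattern(rrc, subj)
  fs <- Biostrings::start(f)   # 1-based forward primer starts
  re <- Biostrings::end(r)     # 1-based reverse site ends
  rs <- Biostrings::start(r)
  hits <- list()
  for (s in fs) {
    ok <- which(rs >= s + nchar(pair$forward) & (re - s + 1L) <= max_len)
    for (j in ok) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = s - 1L, end = re[j], strand = "+",
        length = re[j] - (s - 1L), stringsAsFactors = FALSE
      )
    }
  }
  if (length(hits) == 0L) {
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               length = integer(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, hits)
  }
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Empirical amplicon melting temperature
#'
#' The standard empirical product-Tm formula
#' `81.5 + 16.6 log10([Na+]) + 0.41 (%GC) - 675 / N` for an amplicon of `N`
#' bp at a monovalent-cation concentration in molar units.
#'
#' @param length_bp Product length in bp, >= 40.
#' @param gc GC fraction in `[0, 1]`.
#' @param cation Monovalent cation concentration (M), > 0; default 0.2 M
#'   equivalent for a typical qPCR master mix.
#' @return Predicted Tm in C.
#' @export
product_tm <- function(length_bp, gc, cation = 0.2) {
  if (any(length_bp < 40)) {
    abort("product_tm requires length >= 40 bp", "meltsex_value_error")
  }
  if (any(gc < 0 | gc > 1)) {
    abort("gc must be in [0, 1]", "meltsex_value_error")
  }
  if (any(cation <= 0)) {
    abort("cation concentration must be > 0", "meltsex_value_error")
  }
  81.5 + 16.6 * log10(cation) + 41 * gc - 675 / length_bp
}
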