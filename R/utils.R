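# Internal helpers shared across modules.

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "meltsex_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Derive a reproducible per-well seed from a master seed
#'
#' Stable string hash of `(master, id)` into `[1, 2^31 - 2]`, so per-well
#' random draws are reproducible under any reordering of wells on a plate.
#'
#' @param master Integer master seed.
#' @param id Character identifier (typically a well id).
#' @return An integer seed.
#' @export
derive_seed <- function(master, id) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- abs(as.numeric(master)) %% 2147483647
  for (ch in utf8ToInt(as.character(id))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(max(h, 1))
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's RNG
# stream. A NULL seed evaluates `code` as-is.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = env)
      } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Strict numeric parser: refuses NA/blank/garbage rather than coercing.
parse_numeric <- function(x, column, context = "input") {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    abort(
      sprintf(
        "non-numeric value '%s' in column '%s' (%s, row %d)",
        x[bad[1L]], column, context, bad[1L]
      ),
      "meltsex_format_error"
    )
  }
  out
}

parse_logical <- function(x, column, context = "input") {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(is.na(out) & !(x %in% c("", "na")))
  if (length(bad) > 0L) {
    abort(
      sprintf(
        "non-logical value '%s' in column '%s' (%s, row %d)",
        x[bad[1L]], column, context, bad[1L]
      ),
      "meltsex_format_error"
    )
  }
  as.logical(out)
}

is_uniform_grid <- function(x, tol = 1e-6) {
  if (length(x) < 2L) return(FALSE)
  d <- diff(x)
  all(d > 0) && (max(d) - min(d)) <= tol
}
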