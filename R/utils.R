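# Internal helpers shared across modules.

# Metadata columns of a sample table; every other column is a measured variable.
.META_COLS <- c(
  "sample_id", "subject_id", "cohort",
  "collection_date", "hospitalization_date", "covid_report_date",
  "age", "sex", "severity", "vaccinated",
  "true_recovery_day", "day", "acute"
)

#' Variable (measurement) columns of a sample table
#'
#' A sample table is a plain `data.frame` with one row per sample, a fixed
#' set of metadata columns (`sample_id`, `subject_id`, `cohort`, dates, `age`,
#' `sex`, `severity`, `vaccinated`, and optionally `day`, `acute`,
#' `true_recovery_day`) and one numeric column per quantified variable.
#'
#' @param samples sample table (`data.frame`)
#' @return character vector of variable column names
#' @export
sample_variables <- function(samples) {
  stopifnot(is.data.frame(samples))
  setdiff(names(samples), .META_COLS)
}

#' Numeric matrix of measured values from a sample table
#'
#' @param samples sample table
#' @param variables optional subset of variable names
#' @return numeric matrix, rows named by `sample_id`
#' @export
sample_matrix <- function(samples, variables = NULL) {
  vars <- variables %||% sample_variables(samples)
  missing <- setdiff(vars, names(samples))
  if (length(missing) > 0L) {
    stop_config("variables", paste0(
      "variables absent from table: ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(samples[, vars, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- samples$sample_id
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed configuration error so callers can distinguish bad settings from
# numerical failures.
stop_config <- function(field, message) {
  stop(structure(
    class = c("phenorevert_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration [%s]: %s", field, message),
         call = sys.call(-1))
  ))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# When seed is NULL the expression runs against the current stream.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_config("seed", "seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic 32-bit FNV-1a hash of a character scalar, for provenance
# blocks (avoids a digest dependency).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; keeps h a double-safe int
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime 16777619, split into 16-bit
    # halves so every intermediate stays exactly representable in a double
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Derive a child seed from a base seed and a label, staying below 2^31.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  offset <- strtoi(substr(fnv1a32(label), 1, 6), base = 16L)
  (as.integer(seed) + offset) %% 2147483647L
}
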