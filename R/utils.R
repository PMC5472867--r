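#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import Matrix
#' @importFrom methods as
NULL

# Read a text table file, dropping blank lines and '#' comments but keeping
# the original line numbers so parse errors can point at the offending line.
read_clean_lines <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(
      paste0("file not found: ", path),
      class = "rwrhnet_file_error"
    )
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  tibble(line = which(keep), text = lines[keep])
}

split_fields <- function(text) strsplit(trimws(text), "[ \t]+")

parse_error <- function(path, line, msg) {
  abort(
    sprintf("%s: line %d: %s", path, line, msg),
    class = "rwrhnet_parse_error"
  )
}

validate_error <- function(msg) abort(msg, class = "rwrhnet_validation_error")

param_error <- function(msg) abort(msg, class = "rwrhnet_parameter_error")

# numeric conversion with a line-numbered error
as_weight <- function(x, path, line) {
  w <- suppressWarnings(as.numeric(x))
  if (is.na(w)) parse_error(path, line, paste0("non-numeric weight '", x, "'"))
  if (w < 0) {
    validate_error(sprintf("%s: line %d: negative weight %s", path, line, x))
  }
  w
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

stopifnot_scalar_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    param_error(sprintf(
      "`%s` must be a single number in %s, got %s",
      name, if (open) "(0, 1)" else "[0, 1]", format(x)
    ))
  }
  invisible(x)
}
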