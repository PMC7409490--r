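# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the session RNG, evaluates `expr`, and restores the previous
#' `.Random.seed`, so simulation functions are deterministic without
#' clobbering the caller's stream.
#' @noRd
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @noRd
assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

#' Open a possibly gzip-compressed path for reading text
#' @noRd
openInput <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' @noRd
openOutput <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Stop with a file/line-qualified parse error
#' @noRd
parseError <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}
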