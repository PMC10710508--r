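# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are pure
#' functions of (parameters, seed).
#' @noRd
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("'%s' must be a single non-missing number", name)
  }
}

# split semicolon-joined functional tags into a character vector
splitLabels <- function(labels) {
  strsplit(as.character(labels), ";", fixed = TRUE)
}

joinLabels <- function(label_list) {
  vapply(label_list, paste, character(1), collapse = ";")
}

# CAZyme family token, e.g. "GH16_3" -> class "GH"; NA for non-CAZyme tags
cazymeClass <- function(tag) {
  m <- regmatches(tag, regexpr("^(GH|PL|CE|CBM|GT|AA)(?=[0-9])", tag, perl = TRUE))
  out <- rep(NA_character_, length(tag))
  hit <- grepl("^(GH|PL|CE|CBM|GT|AA)[0-9]", tag)
  out[hit] <- sub("^((GH|PL|CE|CBM|GT|AA))[0-9].*$", "\\1", tag[hit])
  out
}

isCazymeTag <- function(tag) grepl("^(GH|PL|CE|CBM|GT|AA)[0-9]", tag)
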