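# Internal helpers: typed conditions and seeded-RNG scoping.

cld_error <- function(class, message, ..., call = sys.call(-1)) {
  stop(errorCondition(message, ..., class = c(class, "cld_error"),
                      call = call))
}

cld_warning <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "cld_warning")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions with a `seed` argument never perturb the
#' user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a base seed, staying inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1009 + 12345) %% 2147483587L)
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != floor(x) || x < min)
    cld_error("cld_argument_error",
              sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

# Normalize a variable name for cross-CLD matching: lowercase, strip
# punctuation, collapse runs of whitespace.
normalize_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:punct:]]", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}
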