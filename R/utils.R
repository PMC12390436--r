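#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a fixed RNG seed, restoring global state
#'
#' All randomness in the package flows through this helper so that every
#' generator output is a pure function of its seed and arguments, and no
#' function perturbs the caller's RNG stream.
#'
#' @param seed integer scalar.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## derive a stream-specific child seed from a parent seed; keeps independent
## operations on independent streams without global state
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- fnv1a32(key)
  as.integer(h %% 2147483647)
}

## 32-bit FNV-1a hash of a character string, returned as double in [0, 2^32).
## Arithmetic kept exact in doubles: the FNV multiply 16777619 = 403 + 2^24 is
## split so no intermediate exceeds 2^53.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x01")))
  h <- 2166136261
  for (b in bytes) {
    hs <- if (h >= 2^31) h - 2^32 else h
    hs <- bitwXor(as.integer(hs), as.integer(b))
    h <- if (hs < 0) hs + 2^32 else hs
    h <- (h * 403 + (h %% 256) * 16777216) %% 2^32
  }
  h
}

## short hex digest used to stamp artifacts with the config that produced them
config_hash <- function(cfg) {
  u <- unlist(cfg)
  s <- paste(names(u), unname(u), sep = "=", collapse = ";")
  h <- fnv1a32(s)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_config <- function(...) stop(structure(class = c("reswta_config_error", "error", "condition"),
                                            list(message = paste0(...), call = sys.call(-1))))
stop_validation <- function(...) stop(structure(class = c("reswta_validation_error", "error", "condition"),
                                                list(message = paste0(...), call = sys.call(-1))))

assert_that <- function(ok, msg, kind = c("validation", "config")) {
  if (!isTRUE(ok)) {
    if (match.arg(kind) == "config") stop_config(msg) else stop_validation(msg)
  }
  invisible(TRUE)
}

## structured log line: timestamp level stage message
log_line <- function(stage, msg, level = "INFO", verbose = getOption("reswta.verbose", TRUE)) {
  if (isTRUE(verbose))
    message(sprintf("%s %s %s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, stage, msg))
  invisible(NULL)
}
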