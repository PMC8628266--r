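# Internal helpers: argument checking and deterministic seed streams.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(structure(class = c("ritkit_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("ritkit_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_parse <- function(...) {
  stop(structure(class = c("ritkit_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(name, " must be a single finite number")
  if (strict && x <= lower)
    stop_domain(name, " must be > ", lower, " (got ", x, ")")
  if (!strict && x < lower)
    stop_domain(name, " must be >= ", lower, " (got ", x, ")")
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All stochastic components draw from per-stream generators whose seeds are
#' a deterministic hash of the master seed and a label (for example
#' `"saline/animal3/tumor"`). Adding organs or animals therefore never
#' perturbs the draws of existing streams. The result is always in
#' `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), function(x) paste(x, collapse = "_"),
                         character(1)), collapse = "/")
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(labels)) {
    # 31-bit multiplicative string hash (Park-Miller modulus)
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

HOUR_S <- 3600
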