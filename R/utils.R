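# internal helpers: error classes, seeded substreams, misc

stop_resstack <- function(class, msg, ...) {
  stop(structure(class = c(class, "resstack_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Deterministic 31-bit string hash
#'
#' Polynomial rolling hash (base 31, modulus 2^31 - 1) used to derive
#' independent RNG substreams from a global seed plus string tags, so that
#' e.g. adding a model to a panel never perturbs another model's draws.
#'
#' @param ... scalars pasted together (with "/") to form the hashed key.
#' @return integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @keywords internal
hash_seed <- function(...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647
  h <- 7
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h %% (m - 2L) + 1L)
}

# run expr under a local RNG stream without disturbing the caller's RNG
with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == floor(x)
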