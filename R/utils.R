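#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# independent RNG substreams per participant/block so that the data generated
# for one participant never depends on how many other participants precede it.
str_hash31 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  m <- 2147483647  # 2^31 - 1
  for (ch in utf8ToInt(x)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

#' Derive a reproducible RNG substream seed
#'
#' Combines a root seed with a string label (e.g. "p007/self/block2") into a
#' 31-bit seed. Substreams for different labels are effectively independent,
#' and a participant's stream does not depend on cohort insertion order.
#'
#' @param root_seed integer root seed for the session.
#' @param label character scalar naming the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(root_seed, label) {
  stopifnot(length(root_seed) == 1L, is.finite(root_seed))
  m <- 2147483647
  as.integer((as.numeric(root_seed) %% m + str_hash31(label)) %% m)
}

# Run an expression under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
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
  })
  set.seed(seed)
  expr
}

stop_config <- function(...) stop(errorCondition(paste0(...),
  class = c("selfpriors_config_error", "selfpriors_error")))
stop_input <- function(...) stop(errorCondition(paste0(...),
  class = c("selfpriors_input_error", "selfpriors_error")))
stop_stat <- function(...) stop(errorCondition(paste0(...),
  class = c("selfpriors_stat_error", "selfpriors_error")))
stop_fit <- function(msg, diagnostics = NULL) stop(errorCondition(msg,
  diagnostics = diagnostics,
  class = c("selfpriors_fit_error", "selfpriors_error")))

`%||%` <- function(a, b) if (is.null(a)) b else a
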