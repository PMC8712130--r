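#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select group_by summarise ungroup arrange
#'   left_join bind_rows n across all_of
#' @importFrom tibble tibble as_tibble
NULL

# Deterministic 31-bit seed derived from a master seed plus string/number tags.
# All randomness in the package flows through seeds produced here, so a whole
# cohort is reproducible from one integer.
mix_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647
  h <- as.double(seed %% m)
  for (part in unlist(list(...))) {
    for (ch in utf8ToInt(as.character(part))) {
      h <- (h * 31 + ch) %% m
    }
  }
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
# Lightweight equivalent of withr::with_seed (that helper re-queries RNGkind
# on every call, which is too slow for per-block latent draws).
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- rlang::`%||%`
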