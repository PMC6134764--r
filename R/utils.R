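#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_chr map2 imap pmap walk
#' @importFrom stats predict quantile rnorm runif qnorm pnorm sd var setNames
#' @importFrom utils head tail
NULL

# Deterministic sub-seed derivation: hash an arbitrary tag vector (strings,
# integers) into [1, 2^31 - 2] so independent pipeline stages draw from
# reproducible, non-overlapping streams. Polynomial rolling hash mod a
# Mersenne prime; stable across platforms (pure integer arithmetic on
# doubles well below 2^53).
derive_seed <- function(seed, ...) {
  tags <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(seed %% 2147483647)
  for (tag in tags) {
    for (code in utf8ToInt(tag)) {
      h <- (h * 31 + code) %% 2147483647
    }
    h <- (h * 131 + 7) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

assert_that <- function(ok, msg, class = "cytofp_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
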