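#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate approx coef cor lm median pf pnorm pt qbeta
#'   qlnorm qnorm quantile rbinom rlnorm rnorm runif sd psignrank t.test var
#' @importFrom utils head tail write.csv read.csv
#' @importFrom rlang .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed uses (and advances) the current stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a vector of independent sub-seeds from a master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max, n))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("threatsdt_config_error", "error")))
}

stop_contract <- function(...) {
  stop(errorCondition(paste0(...), class = c("threatsdt_contract_error", "error")))
}

# Cheap data.frame constructor for hot loops (skips tibble validation).
quick_df <- function(lst) {
  n <- length(lst[[1L]])
  structure(lst, class = "data.frame", row.names = .set_row_names(n))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1)) {
    stop_config(name, " must lie in [0, 1]")
  }
  invisible(x)
}
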