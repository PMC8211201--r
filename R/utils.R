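# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. seed = NULL runs as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Combines a master seed with any number of integer coordinates (for
#' example a grid cell and replicate index) into a deterministic child
#' seed in `[0, 2^31 - 2]`, so that every unit of work in a large
#' experiment has its own reproducible random stream.
#'
#' @param master Integer master seed.
#' @param ... Integer coordinates distinguishing the work unit.
#' @return A single integer seed.
#' @examples
#' derive_seed(42, 10, 5, 1)
#' @export
derive_seed <- function(master, ...) {
  parts <- c(...)
  h <- as.double(master) %% 2147483647
  for (p in parts) {
    h <- (h * 48271 + as.double(p) + 1) %% 2147483647
  }
  as.integer(h)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}
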