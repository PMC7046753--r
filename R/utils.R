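## internal helpers shared across modules

# run `expr` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' Derive independent child seeds from a master seed
#'
#' Reproducibly expands one master seed into `n` distinct seeds, used to run
#' independent simulation replicates. All seeds fit in a 32-bit integer.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
replicate_seeds <- function(seed, n) {
  stopifnot(n >= 1)
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_tf <- function(...) stop(..., call. = FALSE)

# smallest p-value carried into log scores; keeps scores finite
.P_FLOOR <- 1e-300

signed_log_score <- function(p, direction) {
  p <- max(p, .P_FLOOR)
  if (identical(direction, "enriched")) -log10(p) else log10(p)
}
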