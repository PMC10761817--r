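#' @import data.table
#' @importFrom stats median pbeta pnorm p.adjust rbinom rgamma rmultinom runif
#' @importFrom utils read.csv write.csv head
NULL

# reserved pseudo-gene label for non-targeting control guides
CONTROL_GENE <- "NTC"

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so seeded package operations do not perturb the session stream.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage-specific seed from the run seed
#'
#' One user-facing seed drives every stochastic stage; each stage gets its own
#' stream through a stable arithmetic hash of the stage name, so adding a
#' stage never shifts the draws of another.
#' @param seed integer master seed.
#' @param stage character stage tag.
#' @return integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# vectorized Hamming distance between equal-width sequence vectors
hamming_vec <- function(a, b, width = 20L) {
  mm <- integer(length(a))
  for (k in seq_len(width)) {
    mm <- mm + (substr(a, k, k) != substr(b, k, k))
  }
  mm
}

random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
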