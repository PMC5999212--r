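#' @importFrom rlang .data
#' @importFrom stats rbinom rnbinom rnorm runif var sd cor quantile coef
#' @importFrom stats lm glm lm.fit model.matrix prcomp resid qnorm pnorm
#' @importFrom stats complete.cases setNames p.adjust gaussian poisson
#' @importFrom utils head tail
NULL

# Identifier columns of a wide genotype table; everything else is a locus.
GENO_ID_COLS <- c("individual", "line", "generation", "population", "sex")

#' Locus columns of a wide genotype table
#'
#' A genotype table is a tibble with one row per individual, the identifier
#' columns `individual`, `line`, `generation`, `population`, `sex` (any subset
#' present is honoured), and one integer dosage column in `{0, 1, 2, NA}` per
#' locus.
#'
#' @param gm A wide genotype tibble.
#' @return Character vector of locus column names.
#' @export
geno_loci <- function(gm) {
  setdiff(names(gm), GENO_ID_COLS)
}

#' Extract the dosage matrix from a genotype table
#'
#' @param gm A wide genotype tibble.
#' @return Integer matrix (individuals x loci) with rownames from
#'   `gm$individual` when present.
#' @export
geno_matrix <- function(gm) {
  loci <- geno_loci(gm)
  m <- as.matrix(gm[loci])
  storage.mode(m) <- "integer"
  if ("individual" %in% names(gm)) rownames(m) <- gm$individual
  m
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream.  All stochastic operations in the package route their draws through
# this helper so that a seed in a config pins the whole output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a sub-seed from a base seed and a small stream offset, kept inside
# the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) stop(..., call. = FALSE)
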