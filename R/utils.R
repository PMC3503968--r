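# Internal helpers shared across modules.

#' @importFrom stats var sd cor rbinom rpois rbeta runif pchisq pf phyper
#'   ptukey qtukey qnorm dbeta integrate quantile
NULL

## round-half-up at d decimals; base round() is round-half-even, which does
## not match the rendering convention of the packaged count tables.
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards so seeded utilities do not perturb simulations
## that surround them.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## shared-category bookkeeping: all non-empty subsets of the polyploid taxa,
## largest first (all-taxa, then pairs, then singletons), combn order within a
## size.  For three taxa (A,B,C) this is the layout of the published tables:
## A_B_C, A_B, A_C, B_C, A, B, C.
## fixture column names for the three-taxon category layout
.catCols <- c("cat_NUD_REP_ISL", "cat_NUD_REP", "cat_NUD_ISL", "cat_REP_ISL",
              "cat_NUD", "cat_REP", "cat_ISL")

sharingCategories <- function(polyploids) {
  k <- length(polyploids)
  out <- list()
  for (s in seq(k, 1)) {
    idx <- utils::combn(k, s)
    for (j in seq_len(ncol(idx))) out[[length(out) + 1L]] <- idx[, j]
  }
  names(out) <- vapply(out, function(i) paste(polyploids[i], collapse = "_"),
                       character(1))
  out
}
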