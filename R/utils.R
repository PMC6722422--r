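#' @keywords internal
"_PACKAGE"

#' @importFrom stats optimize pnorm pchisq p.adjust rnbinom rpois rnorm runif
#'   rbinom rmultinom rlnorm median sd var lm logLik model.matrix plogis qlogis
#'   fisher.test glm binomial cor cor.test coef dnbinom setNames complete.cases
#'   aggregate quantile
#' @importFrom utils read.table write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate expr with a fixed RNG state, restoring the caller's stream after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

stop_gutreg <- function(...) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 0 ||
  (is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
     all(abs(x - round(x)) < 1e-8))
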