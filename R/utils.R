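## internal helpers: validation errors that name rows, seed derivation

pv_stop <- function(msg, row = NULL) {
  if (!is.null(row)) msg <- sprintf("%s [row %s]", msg, paste(row, collapse = ", "))
  stop(errorCondition(msg, class = c("pavca_validation_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage seed from a master seed
#'
#' Each simulation stage (trait draw, each task generator) consumes its own
#' RNG stream so that adding or dropping a stage never perturbs the others.
#' Seeds are folded into the 32-bit signed integer range R requires.
#'
#' @param master_seed integer master seed for the cohort.
#' @param stage character stage label, e.g. `"pavca"`.
#' @return an integer seed.
#' @export
stage_seed <- function(master_seed, stage) {
  offsets <- c(traits = 1L, pavca = 2L, crf = 3L, ccp = 4L, ccc = 5L,
               meta = 6L, misc = 7L)
  off <- offsets[[match.arg(stage, names(offsets))]]
  base <- as.numeric(master_seed) %% 1000003
  as.integer((base * 2039 + off * 7919) %% 2147483647)
}

## mean of an exponential truncated to [0, upper]
trunc_exp_mean <- function(rate, upper) {
  1 / rate - upper * exp(-rate * upper) / (1 - exp(-rate * upper))
}

## inverse-CDF draw from an exponential truncated to [0, upper]
rtrunc_exp <- function(n, rate, upper) {
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-rate * upper))) / rate
}
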