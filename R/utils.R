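#' @importFrom stats pchisq pf pnorm pt qlogis plogis rbinom rnorm runif sd
#'   aov coef cor lm.fit median model.matrix p.adjust predict quantile
#'   complete.cases dwilcox setNames
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage child seed from a global seed
#'
#' A fixed affine map modulo a Mersenne prime keeps child seeds inside the
#' 32-bit integer range while decorrelating stages of the pipeline.
#'
#' @param seed integer global seed.
#' @param stage integer stage index (>= 0).
#' @return an integer seed.
#' @keywords internal
child_seed <- function(seed, stage) {
  s <- as.numeric(seed) %% 2147483647
  as.integer(((s * 48271 + as.numeric(stage) * 1299721) %% 2147483629) + 1)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

stop_collected <- function(errors, prefix = "invalid configuration") {
  stop(paste0(prefix, ":\n", paste0("  - ", errors, collapse = "\n")),
       call. = FALSE)
}
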