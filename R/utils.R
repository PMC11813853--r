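#' @importFrom methods is as new
#' @importFrom stats median optimize pnorm p.adjust rnbinom rpois rgamma
#'   rlnorm runif rbinom wilcox.test glm coef dist hclust as.dist
#'   complete.cases setNames sd var quantile
#' @importFrom utils read.delim read.csv write.csv write.table packageVersion
NULL

#' Emit a timestamped log line to stderr
#'
#' Minimal logging used across the pipeline; messages go to stderr so CSV
#' output on stdout is never polluted.
#'
#' @param ... Pieces pasted into the message.
#' @param level One of "INFO", "WARN".
#' @keywords internal
til_log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Run code with a temporary RNG state
#'
#' Seeds the RNG locally and restores the caller's `.Random.seed` on exit,
#' so seeded sampling inside the package never perturbs user-level draws.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
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

#' Derive a reproducible sub-seed from a master seed
#'
#' One shared seed is split into per-purpose substreams so that adding a
#' pipeline stage never perturbs the draws of earlier stages. The derivation
#' is a fixed affine hash kept below 2^31.
#'
#' @param seed Master integer seed.
#' @param stream Small integer identifying the substream.
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate that a value is a probability
#' @keywords internal
check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
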