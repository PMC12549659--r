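#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd quantile runif rnorm predict t.test aggregate
#'   complete.cases median setNames runmed
#' @importFrom utils read.table write.table head tail
NULL

# Classed conditions so callers/tests can discriminate failure modes.
stop_crisp <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "crisp_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_crisp <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "crisp_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Derive a per-stage seed from one master seed
#'
#' One pipeline seed fans out to deterministic sub-seeds for the
#' simulation, fold assignment, RFE, SMOTE, and model-fitting stages so a
#' full run is reproducible from a single integer.
#'
#' @param seed master integer seed.
#' @param stage integer stage offset (each consumer uses a distinct one).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 10007 + 97 * as.double(stage)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
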