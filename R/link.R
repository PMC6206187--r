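#' Logit and inverse-logit links
#'
#' All submodels (initial occupancy and detection) are linear on the logit
#' scale. `inv_logit()` saturates gracefully for large `|x|` (it is
#' `stats::plogis()` underneath, which is computed in a numerically stable
#' way), returning values in the open interval (0, 1) for finite input.
#'
#' @param x Real number(s) on the logit scale.
#' @param p Probability(ies) in (0, 1).
#' @return `inv_logit()` returns probabilities; `logit()` returns reals.
#' @examples
#' inv_logit(0)            # 0.5
#' logit(inv_logit(-1.3))  # -1.3
#' @export
inv_logit <- function(x) plogis(x)

#' @rdname inv_logit
#' @export
logit <- function(p) qlogis(p)

# log(sum(exp(x))) without overflow; -Inf inputs are handled exactly
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Bernoulli log pmf that maps (y = 0, p = 0) -> 0 and (y = 1, p = 0) -> -Inf
log_bern <- function(y, p) dbinom(y, 1L, p, log = TRUE)
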