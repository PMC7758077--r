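#' Dilogarithm (Spence's function) on [0, 1]
#'
#' Computes \eqn{Li_2(z) = \sum_{j \ge 1} z^j / j^2} for arguments in the
#' unit interval, which is the only domain needed by the IBS variance
#' formula \eqn{Li_2(1 - p)}.  Arguments in \eqn{[0, 1/2]} use the defining
#' series directly (geometric convergence, truncated well below machine
#' precision); arguments in \eqn{(1/2, 1]} use the Euler reflection
#' \eqn{Li_2(z) = \pi^2/6 - \log(z)\log(1-z) - Li_2(1-z)} so the series is
#' always evaluated on the fast-converging half.
#'
#' @param z numeric vector in `[0, 1]`.
#' @return `Li2(z)`, same length as `z`.
#' @examples
#' dilog(0)            # 0
#' dilog(1)            # pi^2 / 6
#' dilog(0.5)          # pi^2/12 - log(2)^2/2
#' @export
dilog <- function(z) {
  if (!is.numeric(z) || anyNA(z) || any(z < 0 | z > 1)) {
    stop("`z` must be numeric in [0, 1]", call. = FALSE)
  }
  out <- numeric(length(z))
  lo <- z <= 0.5
  if (any(lo)) out[lo] <- dilog_series(z[lo])
  if (any(!lo)) {
    zh <- z[!lo]
    # log(z)*log1p(-z) -> 0 as z -> 1; guard the 0 * -Inf case at z = 1
    cross <- ifelse(zh == 1, 0, log(zh) * log1p(-zh))
    out[!lo] <- pi^2 / 6 - cross - dilog_series(1 - zh)
  }
  out
}

# defining series, valid (and fast) for z in [0, 1/2]:
# 0.5^60 / 60^2 < 3e-22, far below double precision
dilog_series <- function(z) {
  j <- seq_len(60)
  vapply(z, function(zi) sum(zi^j / j^2), numeric(1))
}
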