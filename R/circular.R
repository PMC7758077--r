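# Circular helpers: von Mises sampling and wrapping.  Angles in radians
# unless noted; the public model interface works in degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# wrap to (-180, 180] degrees
wrap_180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler.  For `kappa` below 1e-8 the
#' distribution is treated as uniform on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration parameter (>= 0).
#' @return numeric vector of angles in `(-pi, pi]` shifted by `mu`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) {
    return(wrap_pi(runif(n, -pi, pi) + mu))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    # chunked rejection; acceptance probability is ~0.66 or better
    m <- ceiling((n - got) / 0.6) + 8L
    u1 <- runif(m)
    u2 <- runif(m)
    u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    vals <- sign(u3[acc] - 0.5) * acos(pmin(pmax(f[acc], -1), 1))
    take <- min(length(vals), n - got)
    if (take > 0L) out[got + seq_len(take)] <- vals[seq_len(take)]
    got <- got + take
  }
  wrap_pi(out + mu)
}

#' Density of the difference of two independent von Mises measurements
#'
#' If `X` and `Y` are independent von Mises with common concentration
#' `kappa` (any shared mean), their circular difference `X - Y` has density
#' \deqn{f(\delta) = I_0(2\kappa\cos(\delta/2)) / (2\pi I_0(\kappa)^2),}
#' which is 2\eqn{\pi}-periodic (the Bessel function \eqn{I_0} is even)
#' and reduces to the uniform density \eqn{1/2\pi} at `kappa = 0`.
#' Evaluated with exponentially scaled Bessel functions so it is
#' overflow-safe for large `kappa`.
#'
#' @param delta angle(s) in radians.
#' @param kappa common concentration parameter (>= 0).
#' @return density values, same length as `delta`.
#' @export
vm_difference_density <- function(delta, kappa) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa >= 0)
  a <- 2 * kappa * cos(delta / 2)
  # log I0(|a|) = log(I0e(|a|)) + |a| with I0e the scaled Bessel function
  log_i0_a <- log(besselI(abs(a), 0, expon.scaled = TRUE)) + abs(a)
  log_i0_k <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  exp(log_i0_a - log(2 * pi) - 2 * log_i0_k)
}
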