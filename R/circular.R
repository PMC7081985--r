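#' Vector strength (resultant length) of a set of phase angles
#'
#' VS is the modulus of the mean unit phasor, `|mean(exp(i * theta))|`,
#' ranging from 0 (uniform phases) to 1 (all phases identical).
#'
#' @param angles numeric vector of angles in radians.
#' @return scalar in \[0, 1\].
#' @export
vector_strength <- function(angles) {
  if (length(angles) == 0L) stop("vector_strength: empty angle set")
  stopifnot(all(is.finite(angles)))
  Mod(mean(exp(1i * angles)))
}

#' Circular mean of a set of phase angles
#'
#' Argument of the mean unit phasor, in `(-pi, pi]`.
#'
#' @inheritParams vector_strength
#' @return scalar angle in radians.
#' @export
circular_mean <- function(angles) {
  if (length(angles) == 0L) stop("circular_mean: empty angle set")
  stopifnot(all(is.finite(angles)))
  Arg(mean(exp(1i * angles)))
}

# smallest absolute angular difference a - b, wrapped to (-pi, pi]
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Draw angles from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration parameter, `>= 0`.
#' @return numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0, is.finite(mu))
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- Arg(exp(1i * theta)) # wrap to (-pi, pi]
      i <- i + 1L
    }
  }
  out
}

# I1(kappa)/I0(kappa): asymptotic vector strength of a von Mises sample
vonmises_vs <- function(kappa) {
  if (kappa == 0) return(0)
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}
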