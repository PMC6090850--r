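# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_input(name, " must be a single value in [0, 1], got ", format(x))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_input(name, " must be an integer >= ", min)
  invisible(as.integer(x))
}

# Geometric mean of strictly positive values.
geomean <- function(x) exp(mean(log(x)))

degrees <- function(rad) rad * 180 / pi
radians <- function(deg) deg * pi / 180

# von Mises sampler (Best-Fisher rejection scheme), in radians.
# kappa = 0 degenerates to the uniform distribution on the circle.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.6) + 8L
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, (mu + sign(u3 - 0.5) * acos(pmax(pmin(f, 1), -1)))[ok])
  }
  out[seq_len(n)]
}
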