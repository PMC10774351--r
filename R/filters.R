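# Butterworth design in zero-pole-gain form, realized as cascaded biquads
# (second-order sections). Transfer-function coefficients of high-order
# designs with cutoffs near DC are numerically ill-conditioned; keeping the
# factored form preserves pole accuracy at a 1 Hz high-pass on kHz-rate data.

# Analog Butterworth prototype + frequency transform, returned as z/p/gain.
butterAnalogZpk <- function(n, w, type) {
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # left half-plane, cutoff 1 rad/s
  W <- tan(pi * w / 2)                           # prewarp (bilinear with fs = 2)
  if (type == "low") {
    list(z = complex(0), p = p * W[1], g = W[1]^n)
  } else if (type == "high") {
    list(z = rep(0 + 0i, n), p = W[1] / p, g = 1)
  } else if (type == "stop") {
    bw <- W[2] - W[1]
    w0 <- sqrt(W[1] * W[2])
    newp <- complex(0)
    for (pp in p) {               # s -> bw*s / (s^2 + w0^2): order doubles
      b2 <- bw / pp
      disc <- sqrt(b2^2 / 4 - w0^2 + 0i)
      newp <- c(newp, b2 / 2 + disc, b2 / 2 - disc)
    }
    list(z = rep(c(1i * w0, -1i * w0), n), p = newp, g = 1)
  } else stop("unknown filter type: ", type)
}

bilinearZpk <- function(z, p, g) {
  zd <- (1 + z) / (1 - z)
  pd <- (1 + p) / (1 - p)
  gd <- g * Re(prod(1 - z) / prod(1 - p))
  # bilinear maps the point at infinity to z = -1; pad missing zeros there
  list(z = c(zd, rep(-1 + 0i, length(p) - length(z))), p = pd, g = gd)
}

# Pair conjugate roots into quadratic factors.
pairConjugate <- function(r) {
  r <- r[order(Re(r), abs(Im(r)))]
  used <- rep(FALSE, length(r))
  out <- list()
  for (i in seq_along(r)) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(r[i])) > 1e-9) {
      j <- which(!used & abs(r - Conj(r[i])) < 1e-6)[1]
      if (is.na(j)) stop("unpaired complex root in filter design")
      used[j] <- TRUE
      out[[length(out) + 1]] <- c(r[i], r[j])
    } else {
      j <- which(!used & abs(Im(r)) <= 1e-9)[1]
      if (is.na(j)) {
        out[[length(out) + 1]] <- c(r[i], NA)
      } else {
        used[j] <- TRUE
        out[[length(out) + 1]] <- c(r[i], r[j])
      }
    }
  }
  out
}

zpk2sos <- function(z, p, g) {
  zp <- pairConjugate(z)
  pp <- pairConjugate(p)
  stopifnot(length(zp) == length(pp))
  sos <- matrix(0, length(pp), 6)
  for (i in seq_along(pp)) {
    pq <- pp[[i]]
    zq <- zp[[i]]
    a <- if (is.na(pq[2])) Re(c(1, -pq[1], 0)) else Re(c(1, -(pq[1] + pq[2]), pq[1] * pq[2]))
    b <- if (is.na(zq[2])) Re(c(1, -zq[1], 0)) else Re(c(1, -(zq[1] + zq[2]), zq[1] * zq[2]))
    sos[i, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * g
  sos
}

#' Design a digital Butterworth filter as second-order sections
#'
#' @param n filter order (the band-stop transform doubles it).
#' @param w normalized cutoff(s) in (0, 1), as a fraction of the Nyquist
#'   frequency; length 2 for \code{type = "stop"}.
#' @param type \code{"low"}, \code{"high"} or \code{"stop"}.
#' @return a \code{k x 6} matrix of biquad coefficients
#'   \code{(b0, b1, b2, a0, a1, a2)} with \code{a0 = 1}.
#' @examples
#' sos <- butterSos(6, 100 / 512, "low")
#' @export
butterSos <- function(n, w, type = c("low", "high", "stop")) {
  type <- match.arg(type)
  if (any(w <= 0) || any(w >= 1)) stop("normalized cutoffs must lie in (0, 1)")
  d <- butterAnalogZpk(n, w, type)
  dd <- bilinearZpk(d$z, d$p, d$g)
  zpk2sos(dd$z, dd$p, dd$g)
}

#' Frequency response of a second-order-section cascade
#'
#' @param sos biquad matrix from [butterSos()].
#' @param w angular frequencies (radians per sample).
#' @return complex response at each \code{w}.
#' @export
sosFreqResp <- function(sos, w) {
  H <- rep(1 + 0i, length(w))
  ej <- exp(-1i * w)
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]
    a <- sos[i, 4:6]
    H <- H * (b[1] + b[2] * ej + b[3] * ej^2) / (a[1] + a[2] * ej + a[3] * ej^2)
  }
  H
}

# One-direction cascade over a time x channel matrix; the C kernel runs
# direct form I per section with pre-start inputs held at the first sample
# and output state at the section's DC-steady response, so constant inputs
# pass through with exactly the DC gain (no startup transient).
sosFilterOnce <- function(sos, x) .sosFilterOnceC(x, sos)

#' Zero-phase (forward-backward) filtering through second-order sections
#'
#' Applies the cascade forward and backward with odd-reflection padding and
#' DC-steady-state initial conditions, so the net response is zero-phase with
#' squared magnitude.
#'
#' @param sos biquad matrix from [butterSos()].
#' @param x numeric signal vector, or a time x channel matrix (channels in
#'   columns, filtered independently in one vectorized pass).
#' @param pad padding length in samples (default: 3 x number of sections x 20,
#'   capped at the signal length minus 1).
#' @return filtered signal, same shape as \code{x}.
#' @export
sosFiltFilt <- function(sos, x, pad = NULL) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  minLen <- 3L * (2L * nrow(sos)) + 1L
  if (n < minLen)
    stop("input too short for zero-phase filtering: need at least ",
         minLen, " samples, got ", n)
  if (is.null(pad)) pad <- min(n - 1L, 3L * nrow(sos) * 20L)
  first <- rep(x[1, ], each = pad)
  last <- rep(x[n, ], each = pad)
  xp <- rbind(2 * first - x[(pad + 1):2, , drop = FALSE],
              x,
              2 * last - x[(n - 1):(n - pad), , drop = FALSE])
  y <- sosFilterOnce(sos, xp)
  y <- sosFilterOnce(sos, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE][(pad + 1):(pad + n), , drop = FALSE]
  if (vec) as.numeric(y) else y
}
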