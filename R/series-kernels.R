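# Dimensionless response kernels for 1-D confined-compression biphasic
# theory, single-sided drainage. All functions take x = t / tau with
# tau = h^2 / (H_A k).
#
# Each kernel has two exactly equivalent representations linked by the
# Jacobi theta transformation: a spectral (eigenfunction) series that
# converges exponentially for x away from 0, and an image (erfc) series that
# converges exponentially for small x. The switch point X_SWITCH is far
# inside the region where both converge to machine precision, so the choice
# never affects results beyond round-off.

X_SWITCH <- 0.05

# scaled incomplete integral: I(a, x) = int_0^x s^{-1/2} exp(-a/s) ds
img_I <- function(a, x) {
  b2 <- a / x
  2 * sqrt(x) * exp(-b2) - 2 * sqrt(pi * a) * erfc_safe(sqrt(b2))
}

# J(a, x) = int_0^x I(a, s) ds
img_J <- function(a, x) {
  b2 <- a / x
  e <- exp(-b2)
  (4 / 3) * x^1.5 * e + (4 / 3) * a * sqrt(x) * e -
    sqrt(pi) * erfc_safe(sqrt(b2)) * ((4 / 3) * a^1.5 + 2 * sqrt(a) * x)
}

erfc_safe <- function(z) 2 * stats::pnorm(z * sqrt(2), lower.tail = FALSE)

# Unit-step creep response, u(x) in [0, 1]: mean strain / (sigma0 / H_A).
# Spectral: 1 - 2 sum exp(-M_n^2 x) / M_n^2, M_n = (n + 1/2) pi.
# Image: 2 sqrt(x/pi) + (2/sqrt(pi)) sum (-1)^m I(m^2, x).
kernel_creep_step <- function(x, ctl) {
  out <- numeric(length(x))
  small <- x > 0 & x < X_SWITCH
  large <- x >= X_SWITCH
  if (any(small)) {
    xs <- x[small]
    s <- 2 * sqrt(xs / pi)
    for (m in 1:8) s <- s + (2 / sqrt(pi)) * (-1)^m * img_I(m^2, xs)
    out[small] <- s
  }
  if (any(large)) {
    xl <- x[large]
    M2 <- ((seq_len(ctl$n_max) - 0.5) * pi)^2
    terms <- 2 * exp(-outer(xl, M2)) / rep(M2, each = length(xl))
    if (any(abs(terms[, ncol(terms)]) > ctl$tol))
      stop(sprintf("series not converged within n_max = %d terms", ctl$n_max))
    out[large] <- 1 - rowSums(terms)
  }
  pmin(pmax(out, 0), 1)
}

# Integrated creep response phi(x) = int_0^x u(s) ds.
# Spectral: x - 1/3 + sum (2 / M_n^4) exp(-M_n^2 x).
# Image: (1/sqrt(pi)) [ (4/3) x^{3/2} + 2 sum (-1)^m J(m^2, x) ].
kernel_creep_int <- function(x, ctl) {
  out <- numeric(length(x))
  small <- x > 0 & x < X_SWITCH
  large <- x >= X_SWITCH
  if (any(small)) {
    xs <- x[small]
    s <- (4 / 3) * xs^1.5
    for (m in 1:8) s <- s + 2 * (-1)^m * img_J(m^2, xs)
    out[small] <- s / sqrt(pi)
  }
  if (any(large)) {
    xl <- x[large]
    M2 <- ((seq_len(ctl$n_max) - 0.5) * pi)^2
    terms <- exp(-outer(xl, M2)) * rep(2 / M2^2, each = length(xl))
    if (any(abs(terms[, ncol(terms)]) > ctl$tol))
      stop(sprintf("series not converged within n_max = %d terms", ctl$n_max))
    out[large] <- xl - 1 / 3 + rowSums(terms)
  }
  pmax(out, 0)
}

# Integrated relaxation response f(x) = int_0^x g(s) ds where g is the
# unit-step stress-relaxation response / H_A (singular at 0+).
# Spectral: x + 1/3 - sum (2 / (n^2 pi^2)) exp(-n^2 pi^2 x).
# Image: 2 sqrt(x/pi) + (2/sqrt(pi)) sum I(m^2, x).
kernel_relax_int <- function(x, ctl) {
  out <- numeric(length(x))
  small <- x > 0 & x < X_SWITCH
  large <- x >= X_SWITCH
  if (any(small)) {
    xs <- x[small]
    s <- 2 * sqrt(xs)
    for (m in 1:8) s <- s + 2 * img_I(m^2, xs)
    out[small] <- s / sqrt(pi)
  }
  if (any(large)) {
    xl <- x[large]
    lam <- (seq_len(ctl$n_max) * pi)^2
    terms <- exp(-outer(xl, lam)) * rep(2 / lam, each = length(xl))
    if (any(abs(terms[, ncol(terms)]) > ctl$tol))
      stop(sprintf("series not converged within n_max = %d terms", ctl$n_max))
    out[large] <- xl + 1 / 3 - rowSums(terms)
  }
  pmax(out, 0)
}
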