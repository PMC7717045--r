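# Minimal dense polynomial helpers (ascending coefficients).  The model
# families are fixed low-degree polynomials, so derivatives and products are
# exact coefficient arithmetic -- no symbolic algebra needed.

poly_eval <- function(coef, u) {
  out <- rep(coef[length(coef)], length(u))
  if (length(coef) > 1L) {
    for (k in seq(length(coef) - 1L, 1L)) out <- out * u + coef[k]
  }
  out
}

poly_deriv <- function(coef) {
  n <- length(coef)
  if (n == 1L) return(0)
  coef[-1L] * seq_len(n - 1L)
}

poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Real roots in [lo, hi]: closed form for degree <= 2, companion-matrix
# (base polyroot) otherwise.
poly_real_roots <- function(coef, lo = 0, hi = 1, tol = 1e-9) {
  while (length(coef) > 1L && abs(coef[length(coef)]) < 1e-300) {
    coef <- coef[-length(coef)]
  }
  deg <- length(coef) - 1L
  if (deg <= 0L) return(numeric(0))
  if (deg == 1L) {
    r <- -coef[1L] / coef[2L]
  } else if (deg == 2L) {
    disc <- coef[2L]^2 - 4 * coef[3L] * coef[1L]
    if (disc < 0) return(numeric(0))
    # numerically stable quadratic roots
    q <- -(coef[2L] + sign(coef[2L] + (coef[2L] == 0)) * sqrt(disc)) / 2
    r <- c(q / coef[3L], if (abs(q) > 0) coef[1L] / q else -coef[2L] / (2 * coef[3L]))
  } else {
    z <- polyroot(coef)
    r <- Re(z[abs(Im(z)) < tol])
  }
  sort(unique(r[r >= lo - tol & r <= hi + tol]))
}
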