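# Independent oracles, kept deliberately separate from the package's own
# implementations.

# --- monopole near a rigid sphere: analytic spherical-harmonic series ------
# Far-field directivity (coefficient of exp(ikr)/r) of a unit monopole at
# x0 outside a rigid sphere of radius a centred at the origin, with
# G = exp(ikR)/(4 pi R) and time convention exp(-i w t).
sph_j <- function(m, x) sqrt(pi / (2 * x)) * besselJ(x, m + 0.5)
sph_y <- function(m, x) sqrt(pi / (2 * x)) * besselY(x, m + 0.5)
sph_h <- function(m, x) complex(real = sph_j(m, x), imaginary = sph_y(m, x))
dsph <- function(fn, m, x) {
  if (m == 0) -fn(1, x) else fn(m - 1, x) - (m + 1) / x * fn(m, x)
}

oracle_sphere_far <- function(units, x0, a, k, mmax = 30) {
  r0 <- sqrt(sum(x0^2))
  ct <- pmin(1, pmax(-1, drop(units %*% (x0 / r0))))
  Fv <- exp(-1i * k * drop(units %*% x0)) / (4 * pi)
  Pprev2 <- NULL
  Pprev <- NULL
  for (m in 0:mmax) {
    Pm <- if (m == 0) {
      rep(1, length(ct))
    } else if (m == 1) {
      ct
    } else {
      ((2 * m - 1) * ct * Pprev - (m - 1) * Pprev2) / m
    }
    A_m <- -(1i * k / (4 * pi)) * (2 * m + 1) * sph_h(m, k * r0) *
      dsph(sph_j, m, k * a) / dsph(sph_h, m, k * a)
    Fv <- Fv + (1 / k) * (-1i)^(m + 1) * A_m * Pm
    Pprev2 <- Pprev
    Pprev <- Pm
  }
  Fv
}

# --- Mann-Whitney U by exhaustive enumeration ------------------------------
# Independent route: U defined by pairwise comparisons (#{x_i > y_j} plus
# half-ties); the null distribution enumerated over all assignments of the
# pooled values to group 1.
oracle_u_stat <- function(x, y) {
  sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
}

oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  u_obs <- oracle_u_stat(x, y)
  mu <- n1 * length(y) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) {
    oracle_u_stat(pooled[idx], pooled[-idx])
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
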