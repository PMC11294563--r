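# Independent brute-force oracles, kept free of package internals.

# Monomer concentration by bisection on mass action 2 c1^2 / K + c1 = c.
oracle_monomer <- function(c, K, tol = 1e-14) {
  if (c == 0) return(0)
  lo <- 0
  hi <- c
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (2 * mid^2 / K + mid - c > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * c) break
  }
  (lo + hi) / 2
}

# Two-compartment equilibrium by grid + bisection directly on the chemical
# potential equality (raw mu difference, no monomer shortcut) and the
# conservation law.
oracle_equilibrium <- function(kd_dim, kd_mem, c_tot, a = 5e-9,
                               psi = 0.174e6) {
  mu <- function(c) {
    log(c) - 0.5 * log(1 + 4 * c / kd_dim + sqrt(1 + 8 * c / kd_dim))
  }
  c_m_of <- function(c_c) {
    # solve mu(c_c) = log(kd_mem) + mu(c_m) by bisection on log10 c_m
    target <- mu(c_c) - log(kd_mem)
    lo <- log10(c_c) - 2
    hi <- log10(c_c) + 12
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (mu(10^mid) > target) hi <- mid else lo <- mid
    }
    10^((lo + hi) / 2)
  }
  resid <- function(lg) {
    c_c <- 10^lg
    c_c + a * psi * c_m_of(c_c) - c_tot
  }
  lo <- log10(c_tot) - 12
  hi <- log10(c_tot)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) hi <- mid else lo <- mid
  }
  c_c <- 10^((lo + hi) / 2)
  list(c_c = c_c, c_m = c_m_of(c_c))
}

# Convert an AU rundown generated by gen_rundown back to molar using the
# known generator scale.
as_molar <- function(gen) {
  d <- gen$observed
  d$cyt <- d$cyt / gen$config$au_scale[["cyt"]]
  d$mem <- d$mem / gen$config$au_scale[["mem"]]
  d$units <- "molar"
  d
}
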