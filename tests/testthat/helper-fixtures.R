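# Shared fixtures: small states, grids and a hand-coded SMS oracle that is
# written straight from the process formulas, independent of the package's
# flux bookkeeping.

default_params <- bio_params()

make_state <- function(N = 2, P = 1, Z = 0.5, D = 0.2, theta0 = 0.02,
                       params = default_params) {
  eco_state(N = N, P = P, Z = Z, D = D, theta0 = theta0, params = params)
}

# Term-by-term SMS oracle: every process evaluated directly from its formula.
oracle_sms <- function(st, env, p) {
  cn <- p$c2n * 12.011
  theta <- if (st$P > 0) st$Chl / (st$P * cn) else 0
  mu_NT <- p$mu0 * p$a_T^env$T * st$N / (p$K_N + st$N)
  x <- p$alpha * env$PAR * theta
  mu <- if (mu_NT > 0 && x > 0) mu_NT * (1 - exp(-x / mu_NT)) else 0
  if (st$P == 0) mu <- 0
  U <- mu * st$P
  G <- p$g_max * st$P / (p$K_P + st$P) * st$Z
  rho <- if (x > 0) min(p$theta_max, p$theta_max * mu / x) else p$theta_max
  list(N = -U + p$e_Z * st$Z + p$r_D * st$D,
       P = U - G - p$m_P * st$P,
       Z = p$beta * G - p$m_Z * st$Z - p$e_Z * st$Z,
       D = (1 - p$beta) * G + p$m_P * st$P + p$m_Z * st$Z - p$r_D * st$D,
       Chl = rho * U * cn - theta * cn * (G + p$m_P * st$P))
}

random_state <- function(params = default_params) {
  th <- runif(1, 1e-4, params$theta_max)
  eco_state(N = runif(1, 0, 10), P = runif(1, 0, 5), Z = runif(1, 0, 3),
            D = runif(1, 0, 2), theta0 = th, params = params)
}

ln_slope <- function(t, y) {
  keep <- y > 0
  unname(coef(lm(log(y[keep]) ~ t[keep]))[2])
}

center_of_mass <- function(conc, grid) sum(conc * grid$z_centers * grid$dz) /
  sum(conc * grid$dz)
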