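test_that("nutrient limitation is Michaelis-Menten with the right anchors", {
  expect_identical(nutrient_limitation(0, 1.5), 0)
  expect_identical(nutrient_limitation(1.5, 1.5), 0.5)
  expect_identical(nutrient_limitation(4.5, 1.5), 0.75)
  expect_error(nutrient_limitation(-1, 1.5), "negative")
  expect_error(nutrient_limitation(1, 0), "K_N")
  N <- seq(0, 50, by = 0.5)
  expect_true(all(diff(nutrient_limitation(N, 1.5)) > 0))
  expect_true(all(nutrient_limitation(N, 1.5) < 1))
})

test_that("maximum growth follows the Eppley temperature curve", {
  p <- bio_params()
  expect_identical(max_growth(0, p), p$mu0)
  expect_equal(max_growth(10, p), 0.59 * 1.066^10)
  p1 <- bio_params(a_T = 1)
  expect_identical(max_growth(25, p1), max_growth(-5, p1))
  expect_true(all(diff(max_growth(seq(-2, 30, 2), p)) > 0))
})

test_that("realised growth has the Geider limits", {
  p <- bio_params()
  st <- make_state(N = 4.5, P = 1)
  expect_identical(phyto_growth(st, list(T = 15, PAR = 0), p), 0)
  st0 <- make_state(N = 0, P = 1)
  expect_identical(phyto_growth(st0, list(T = 15, PAR = 100), p), 0)
  # saturating light: mu -> mu_NT
  mu_NT <- max_growth(15, p) * nutrient_limitation(4.5, p$K_N)
  mu_sat <- phyto_growth(st, list(T = 15, PAR = 1e6), p)
  expect_equal(mu_sat, mu_NT, tolerance = 1e-6)
  # light-limited linear regime: mu -> alpha * PAR * theta
  th <- theta_diag(st, p)
  mu_lin <- phyto_growth(st, list(T = 15, PAR = 1e-4), p)
  expect_equal(mu_lin, p$alpha * 1e-4 * th, tolerance = 1e-4)
  expect_error(phyto_growth(st, list(T = 15, PAR = -1), p), "PAR")
})

test_that("growth is monotone in N, PAR and T and bounded by mu_NT", {
  p <- bio_params()
  for (v in list(
    vapply(c(0, 0.5, 2, 8), function(N)
      phyto_growth(make_state(N = N), list(T = 15, PAR = 50), p), numeric(1)),
    vapply(c(0, 10, 50, 300), function(PAR)
      phyto_growth(make_state(), list(T = 15, PAR = PAR), p), numeric(1)),
    vapply(c(5, 10, 15, 25), function(T_C)
      phyto_growth(make_state(), list(T = T_C, PAR = 50), p), numeric(1))))
    expect_true(all(diff(v) >= 0))
  st <- make_state(N = 3)
  mu <- phyto_growth(st, list(T = 18, PAR = 200), p)
  expect_lte(mu, max_growth(18, p) * nutrient_limitation(3, p$K_N))
})

test_that("chlorophyll synthesis ratio hits its limits and the direct formula", {
  p <- bio_params()
  expect_identical(chl_synthesis_ratio(0.5, 0.02, 0, p), p$theta_max)
  expect_identical(chl_synthesis_ratio(0, 0.02, 100, p), 0)
  # saturating light, theta = 0.02, PAR = 300: direct evaluation
  st <- make_state(N = 4.5, P = 1, theta0 = 0.02)
  mu <- phyto_growth(st, list(T = 15, PAR = 300), p)
  rho <- chl_synthesis_ratio(mu, 0.02, 300, p)
  expect_equal(rho, min(p$theta_max, p$theta_max * mu / (p$alpha * 300 * 0.02)))
  expect_lt(rho, p$theta_max / 3)
  # never exceeds theta_max for any combination
  for (PAR in c(1e-6, 1, 100)) for (mu in c(0, 0.3, 2))
    expect_lte(chl_synthesis_ratio(mu, 0.015, PAR, p), p$theta_max)
})

test_that("grazing is Holling II with supremum g_max", {
  expect_identical(grazing(0), 0)
  expect_identical(grazing(1), 0.45)
  expect_equal(grazing(1e6), 0.9, tolerance = 1e-5)
  expect_error(grazing(-0.1), "negative")
  P <- seq(0, 30, 0.5)
  expect_true(all(diff(grazing(P)) > 0))
  expect_true(all(grazing(P) < 0.9))
})

test_that("SMS tendencies match a term-by-term independent oracle", {
  p <- bio_params()
  env <- list(T = 15, PAR = 50)
  st <- make_state(N = 2, P = 1, Z = 0.5, D = 0.2)
  got <- sms(st, env, p)
  want <- oracle_sms(st, env, p)
  for (k in names(want)) expect_equal(got[[k]], want[[k]], info = k)

  zero <- eco_state(0, 0, 0, 0, Chl = 0)
  expect_true(all(abs(unlist(sms(zero, env, p))) == 0))

  dark <- eco_state(N = 0, P = 1, Z = 0, D = 0)
  expect_equal(sms(dark, list(T = 15, PAR = 0), p)$P, -0.03)
})

test_that("nitrogen tendencies always sum to zero", {
  set.seed(42)
  p <- bio_params()
  for (i in 1:50) {
    st <- random_state(p)
    env <- list(T = runif(1, 5, 25), PAR = runif(1, 0, 400))
    ten <- sms(st, env, p)
    tot <- ten$N + ten$P + ten$Z + ten$D
    expect_lt(abs(tot), 1e-13 * max(1, abs(ten$N)))
  }
})

test_that("the positivity-preserving step conserves nitrogen and stays nonnegative", {
  set.seed(7)
  p <- bio_params()
  for (i in 1:30) {
    st <- random_state(p)
    env <- list(T = runif(1, 5, 25), PAR = runif(1, 0, 400))
    dt <- runif(1, 1 / 288, 0.5)   # up to half a day
    s2 <- sms_step(st, env, p, dt)
    expect_true(all(unlist(unclass(s2)) >= 0))
    tot1 <- st$N + st$P + st$Z + st$D
    tot2 <- s2$N + s2$P + s2$Z + s2$D
    expect_equal(tot2, tot1, tolerance = 1e-13)
    th <- theta_diag(s2, p)
    if (!is.na(th) && s2$P > 1e-12)
      expect_lte(th, p$theta_max * (1 + 1e-9))
  }
})

test_that("box trajectory agrees with an independent stiff ODE solve", {
  skip_if_not_installed("deSolve")
  p <- bio_params()
  env <- list(T = 15, PAR = 50)
  s0 <- eco_state(N = 2, P = 0.5, Z = 0.2, D = 0.1)
  deriv <- function(t, y, parms) {
    st <- structure(as.list(y), class = "eco_state")
    list(unlist(sms(st, env, p)))
  }
  ref <- deSolve::ode(y = c(N = s0$N, P = s0$P, Z = s0$Z, D = s0$D,
                            Chl = s0$Chl),
                      times = c(0, 10), func = deriv, parms = NULL,
                      rtol = 1e-8, atol = 1e-10)
  box <- run_box(s0, PAR = 50, T_C = 15, p, t_end_days = 10)
  last <- box[nrow(box), ]
  for (k in c("N", "P", "Z", "D", "Chl"))
    expect_equal(last[[k]], unname(ref[2, k]), tolerance = 0.02, info = k)
})

test_that("closed-box long integration stays bounded with constant total nitrogen", {
  s0 <- eco_state(N = 3, P = 0.5, Z = 0.2, D = 0.1)
  b <- run_box(s0, PAR = 80, T_C = 15, t_end_days = 1000, dt = 3600,
               output_every_days = 10)
  tot <- b$N + b$P + b$Z + b$D
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-10)
  expect_true(all(is.finite(as.matrix(b))))
  expect_true(all(b$theta[!is.na(b$theta)] <= 0.03 + 1e-6))
  expect_true(all(b$theta[!is.na(b$theta)] > 0))
})
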