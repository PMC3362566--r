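test_that("model bias is the mean model-minus-observation difference", {
  expect_identical(model_bias(skill_series(1:4, c(2, 3, 4, 5), c(2, 3, 4, 5))), 0)
  expect_equal(model_bias(skill_series(1:3, c(1, 2, 3) + 1.5, c(1, 2, 3))), 1.5)
  expect_equal(model_bias(skill_series(1:3, c(1, 2, 4), c(0, 2, 1))), 4 / 3)
  # pairwise deletion of missing observations
  expect_equal(model_bias(skill_series(1:3, c(1, 2, 4), c(0, NA, 1))), 2)
  expect_error(model_bias(skill_series(1:2, c(NA, NA), c(1, 2))), "no valid")
  expect_error(model_bias(1:3), "skill_series")
})

test_that("model bias is linear in a constant model offset", {
  set.seed(21)
  M <- rnorm(50); D <- rnorm(50); D[sample(50, 5)] <- NA
  b0 <- model_bias(skill_series(1:50, M, D))
  for (const in c(-2, 0.5, 10))
    expect_equal(model_bias(skill_series(1:50, M + const, D)), b0 + const)
})

test_that("bias map recovers constructed offsets and matches the scalar loop", {
  lon <- seq(-10, -8, 0.5); lat <- seq(40, 42, 0.5)
  nt <- 6
  set.seed(31)
  obs <- array(rnorm(length(lon) * length(lat) * nt),
               c(length(lon), length(lat), nt))
  offset <- outer(seq_along(lon), seq_along(lat), function(i, j) 0.1 * i - 0.2 * j)
  mod <- obs + array(rep(offset, nt), dim(obs))
  bm <- bias_map(gridded_field(lon, lat, mod), gridded_field(lon, lat, obs))
  expect_equal(bm$values, offset, tolerance = 1e-12)

  # identical stacks -> zero map
  z <- bias_map(gridded_field(lon, lat, obs), gridded_field(lon, lat, obs))
  expect_true(all(z$values == 0))

  # random stacks with gaps: per-point agreement with the scalar statistic
  obs2 <- obs; obs2[sample(length(obs2), 40)] <- NA
  mod2 <- mod; mod2[sample(length(mod2), 15)] <- NA
  bm2 <- bias_map(gridded_field(lon, lat, mod2), gridded_field(lon, lat, obs2))
  for (i in seq_along(lon)) for (j in seq_along(lat)) {
    good <- is.finite(mod2[i, j, ]) & is.finite(obs2[i, j, ])
    if (any(good)) {
      expect_equal(bm2$values[i, j],
                   model_bias(skill_series(1:nt, mod2[i, j, ], obs2[i, j, ])))
    } else {
      expect_true(is.na(bm2$values[i, j]))
    }
  }
  expect_error(bias_map(gridded_field(lon + 1, lat, mod),
                        gridded_field(lon, lat, obs)), "grids differ")
})

test_that("the low-pass filter has the stated pass and stop behaviour", {
  dt_h <- 1
  t <- seq(0, 30 * 24, by = dt_h)          # 30 days, hourly
  interior <- t > 5 * 24 & t < 25 * 24
  # DC gain 1
  expect_equal(lowpass(rep(3.2, length(t)), dt_h), rep(3.2, length(t)),
               tolerance = 1e-9)
  # 12-h tide suppressed to under 10%
  tide <- sin(2 * pi * t / 12)
  expect_lt(max(abs(lowpass(tide, dt_h)[interior])), 0.1)
  # 5-day signal preserved within 1% in superposition
  slow <- sin(2 * pi * t / (5 * 24))
  f <- lowpass(slow + tide, dt_h)
  expect_lt(max(abs(f[interior] - slow[interior])), 0.01)
  # idempotence on an already-smooth series
  expect_equal(lowpass(f, dt_h)[interior], f[interior], tolerance = 0.01)
})

test_that("the filter handles gaps and rejects impossible requests", {
  dt_h <- 1
  t <- seq(0, 20 * 24, by = dt_h)
  x <- sin(2 * pi * t / (4 * 24))
  x2 <- x; x2[100:102] <- NA               # short gap: bridged
  f <- lowpass(x2, dt_h)
  expect_true(all(is.finite(f)))
  x3 <- x; x3[200:260] <- NA               # long gap: segments split
  f3 <- lowpass(x3, dt_h)
  expect_true(all(is.na(f3[200:260])))
  expect_true(all(is.finite(f3[-(200:260)])))
  expect_error(lowpass(x[1:30], dt_h), "shorter")
  expect_error(lowpass(x, dt_hours = 30, cutoff_hours = 40), "cutoff")
})

test_that("disc averaging selects by great-circle distance", {
  lon <- seq(-9.5, -8.5, 0.05); lat <- seq(41.5, 42.5, 0.05)
  uni <- gridded_field(lon, lat, matrix(2.5, length(lon), length(lat)))
  r <- disc_average(uni, -9, 42, radius_km = 7)
  expect_identical(r$mean, 2.5)
  expect_identical(r$sd, 0)
  expect_gt(r$n, 1)

  # radius below the grid spacing centred on a grid point: that point only
  v <- matrix(seq_len(length(lon) * length(lat)), length(lon), length(lat))
  g <- gridded_field(lon, lat, v)
  r1 <- disc_average(g, lon[3], lat[4], radius_km = 1)
  expect_identical(r1$n, 1L)
  expect_identical(r1$sd, 0)
  expect_identical(r1$mean, as.numeric(v[3, 4]))

  # two-point disc: mean (a+b)/2, population sd |a-b|/2
  lon2 <- c(0, 0.05); lat2 <- c(50, 50.2)
  g2 <- gridded_field(lon2, lat2, matrix(c(1, 3, NA, NA), 2, 2))
  r2 <- disc_average(g2, 0.025, 50, radius_km = 7)
  expect_identical(r2$n, 2L)
  expect_equal(r2$mean, 2)
  expect_equal(r2$sd, 1)

  expect_error(disc_average(g, 0, 0, radius_km = 7), "no valid")
})

test_that("disc averaging is unaffected by longitude wrap-around", {
  lat <- seq(-1, 1, 0.2)
  # grid points on both sides of the dateline
  lon <- c(179.2, 179.6, 180, -179.6, -179.2)
  set.seed(41)
  v <- matrix(rnorm(length(lon) * length(lat)), length(lon))
  a <- disc_average(gridded_field(lon, lat, v), 180, 0, radius_km = 50)
  b <- disc_average(gridded_field(lon, lat, v), -180, 0, radius_km = 50)
  expect_equal(a$mean, b$mean)
  expect_equal(a$sd, b$sd)
  expect_identical(a$n, b$n)
})
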