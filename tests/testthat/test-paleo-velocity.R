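# Anomaly, spatial gradient, change velocity, site extraction.

planar_grid <- function(a, b, c0 = 0, nx = 7, ny = 6, cellsize = 1,
                        units = "km", xll = 0, yll = 0, variable = "MAT",
                        epoch = "current") {
  x <- (seq_len(nx) - 0.5) * cellsize + xll
  y <- (seq_len(ny) - 0.5) * cellsize + yll
  vals <- outer(rev(y), x, function(yy, xx) a * xx + b * yy + c0)
  climate_grid(vals, cellsize, xll = xll, yll = yll, units = units,
               variable = variable, epoch = epoch)
}

test_that("multi-model mean averages cell-wise and propagates nodata", {
  g1 <- planar_grid(0.01, 0.02)
  expect_equal(multi_model_mean(list(g1, g1))$values, g1$values)

  a <- climate_grid(matrix(3, 4, 4), 1); b <- climate_grid(matrix(5, 4, 4), 1)
  expect_true(all(multi_model_mean(list(a, b))$values == 4))

  a$values[2, 3] <- NA
  mm <- multi_model_mean(list(a, b))
  expect_true(is.na(mm$values[2, 3]))
  expect_equal(sum(is.na(mm$values)), 1L)

  shifted <- climate_grid(matrix(5, 4, 4), 1, xll = 10)
  expect_error(multi_model_mean(list(a, shifted)), "co-registered")
  expect_error(multi_model_mean(list(a)), "at least two")
})

test_that("anomaly is the signed current-minus-past difference", {
  cur <- climate_grid(matrix(10, 3, 3), 1)
  past <- climate_grid(matrix(4, 3, 3), 1)
  expect_true(all(grid_anomaly(cur, past)$values == 6))
  expect_true(all(grid_anomaly(cur, cur)$values == 0))
  # antisymmetry
  g1 <- planar_grid(0.01, -0.03, 5)
  g2 <- planar_grid(-0.02, 0.01, 2)
  expect_equal(grid_anomaly(g1, g2)$values, -grid_anomaly(g2, g1)$values)
})

test_that("spatial gradient matches the analytic planar slope", {
  g <- planar_grid(0.003, 0.004, 10, nx = 9, ny = 8)
  gr <- spatial_gradient(g)$values
  inner <- gr[2:7, 2:8]
  expect_true(all(abs(inner - 0.005) / 0.005 < 1e-10))
  # edges are nodata (no one-sided differences)
  expect_true(all(is.na(gr[c(1, 8), ])) && all(is.na(gr[, c(1, 9)])))

  const <- climate_grid(matrix(7, 5, 5), 1)
  gc <- spatial_gradient(const)$values
  expect_true(all(gc[2:4, 2:4] == 0))

  oneD <- planar_grid(-0.02, 0)
  g1d <- spatial_gradient(oneD)$values
  expect_true(all(abs(g1d[2:5, 2:6] - 0.02) < 1e-12))

  withna <- planar_grid(0.01, 0.01)
  withna$values[3, 3] <- NA
  gn <- spatial_gradient(withna)$values
  # the four rook neighbours of the nodata cell lose their gradient
  expect_true(all(is.na(gn[cbind(c(2, 4, 3, 3), c(3, 3, 2, 4))])))
})

test_that("degree grids convert gradients to per-km with cos(latitude)", {
  # field linear in longitude only: 2 units per degree at latitude ~40N
  g <- planar_grid(2, 0, 0, nx = 5, ny = 5, cellsize = 0.5, units = "degrees",
                   yll = 40)
  gr <- spatial_gradient(g)$values
  lat_row3 <- 40 + (5 - 3 + 0.5) * 0.5
  expected <- 2 / (111.32 * cos(lat_row3 * pi / 180))
  expect_equal(gr[3, 3], expected, tolerance = 1e-10)
})

test_that("change velocity divides anomaly by floored gradient", {
  an <- climate_grid(matrix(4.2, 3, 3), 1)
  gr <- climate_grid(matrix(0.0021, 3, 3), 1)
  expect_equal(change_velocity(an, gr)$values[2, 2], 2000, tolerance = 1e-10)

  zero <- climate_grid(matrix(0, 3, 3), 1)
  expect_true(all(change_velocity(zero, gr)$values == 0))

  flat <- climate_grid(matrix(0, 3, 3), 1)
  v <- change_velocity(an, flat, floor = 0.001)
  expect_true(all(v$values == 4.2 / 0.001))
  expect_error(change_velocity(an, gr, floor = 0), "floor")

  # scale consistency above the floor
  an2 <- climate_grid(matrix(8.4, 3, 3), 1)
  expect_equal(change_velocity(an2, gr)$values, 2 * change_velocity(an, gr)$values)
})

test_that("derive_historical extracts log-velocities and anomalies at sites", {
  gr_t <- sim_paleo_grids(10, 10, 1, list(type = "planar", a = 0.003,
                                          b = 0.004, c = 10, lgm_offset = -4.2))
  gr_p <- sim_paleo_grids(10, 10, 1, list(type = "planar", a = 0.05, b = 0,
                                          c = 800, lgm_offset = -120),
                          variable = "MAP")
  sites <- data.frame(site = c("A", "B"), x = c(4.5, 6.5), y = c(5.5, 3.5))
  hv <- derive_historical(gr_t$current, gr_t$lgm, gr_p$current, gr_p$lgm, sites)
  expect_equal(hv$TA, c(4.2, 4.2))
  expect_equal(hv$PA, c(120, 120))
  expect_equal(hv$raw_TCV, rep(4.2 / 0.005, 2), tolerance = 1e-10)
  expect_equal(hv$TCV, log10(hv$raw_TCV))
  expect_equal(hv$raw_PCV, rep(120 / 0.05, 2), tolerance = 1e-10)
  # log identity: raw velocity 1 -> 0
  expect_equal(log(1, base = 10), 0)
  expect_equal(derive_historical(gr_t$current, gr_t$lgm, gr_p$current,
                                 gr_p$lgm, sites, log_base = 10)$TCV,
               log10(4.2 / 0.005) * c(1, 1), tolerance = 1e-10)

  outside <- data.frame(site = "far", x = 99, y = 5)
  expect_error(derive_historical(gr_t$current, gr_t$lgm, gr_p$current,
                                 gr_p$lgm, outside), "far")
  edge <- data.frame(site = "edge", x = 0.5, y = 0.5)
  expect_error(derive_historical(gr_t$current, gr_t$lgm, gr_p$current,
                                 gr_p$lgm, edge), "nodata")
})

test_that("extraction is invariant to a common origin shift", {
  mk <- function(xll, yll) {
    list(t = planar_grid(0.01, 0.02, 5, nx = 8, ny = 8, xll = xll, yll = yll),
         tl = planar_grid(0.01, 0.02, 1, nx = 8, ny = 8, xll = xll, yll = yll,
                          epoch = "LGM"),
         p = planar_grid(0.05, 0, 700, nx = 8, ny = 8, xll = xll, yll = yll,
                         variable = "MAP"),
         pl = planar_grid(0.05, 0, 650, nx = 8, ny = 8, xll = xll, yll = yll,
                          variable = "MAP", epoch = "LGM"))
  }
  s0 <- data.frame(site = "A", x = 3.5, y = 4.5)
  g0 <- mk(0, 0); g1 <- mk(100, -50)
  s1 <- transform(s0, x = x + 100, y = y - 50)
  h0 <- derive_historical(g0$t, g0$tl, g0$p, g0$pl, s0)
  h1 <- derive_historical(g1$t, g1$tl, g1$p, g1$pl, s1)
  expect_equal(h0[, -1], h1[, -1], tolerance = 1e-10)
})

test_that("ESRI ASCII grids round-trip through write and read", {
  g <- sim_paleo_grids(6, 5, 2.5, list(type = "noisy-planar", noise_sd = 1),
                       seed = 3)$current
  g$values[2, 4] <- NA
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(g, path)
  g2 <- read_ascii_grid(path, units = "km", variable = "MAT",
                        epoch = "current")
  expect_equal(g2$values, g$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g2$cellsize, 2.5)
  expect_equal(c(g2$xll, g2$yll), c(g$xll, g$yll))
})
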