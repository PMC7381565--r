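# Inclusion-exclusion partitioning, permutation inference, Moran's I.

test_that("inclusion-exclusion reproduces the hand-worked partition", {
  R <- c(C = 0.30, S = 0.20, H = 0.25, CS = 0.35, CH = 0.33, SH = 0.30,
         CSH = 0.40)
  fr <- partition_fractions(R)
  expect_equal(unname(fr), c(0.10, 0.07, 0.05, -0.02, 0.05, -0.02, 0.17),
               tolerance = 1e-12)
  expect_equal(sum(fr), 0.40, tolerance = 1e-12)

  flat <- partition_fractions(c(C = 0.3, S = 0.3, H = 0.3, CS = 0.3,
                                CH = 0.3, SH = 0.3, CSH = 0.3))
  expect_true(all(abs(flat[1:6]) < 1e-12))
})

test_that("the seven fractions always sum to the full-model value", {
  for (seed in 1:20) {
    R <- with_seed_test(seed, {
      v <- runif(7, -0.3, 0.8)
      names(v) <- c("C", "S", "H", "CS", "CH", "SH", "CSH")
      v
    })
    expect_equal(sum(partition_fractions(R)), unname(R["CSH"]),
                 tolerance = 1e-12)
  }
})

test_that("a fitted partition conserves the full-model mean adjusted R2", {
  ds <- sim_dataset(sim_config(seed = 21))
  y <- shannon(ds$community)
  vp <- en_varpart(y, ds$env, repeats = 2, alpha_grid = c(0.3, 0.9),
                   n_perm = 0, seed = 4)
  expect_lt(abs(sum(vp$fractions) - vp$combo_r2adj[["CSH"]]), 1e-10)
  expect_equal(unname(vp$totals),
               unname(vp$combo_r2adj[c("C", "S", "H")]))
  # determinism under the seed
  vp2 <- en_varpart(y, ds$env, repeats = 2, alpha_grid = c(0.3, 0.9),
                    n_perm = 0, seed = 4)
  expect_identical(vp$fractions, vp2$fractions)
})

test_that("an inert historical set gets a negligible pure fraction", {
  cfg <- sim_config(n_sites = 500, effect_sizes = c(climatic = -1, soil = -0.5),
                    cross_set_correlation = 0, seed = 1)
  ds <- sim_dataset(cfg)
  vp <- en_varpart(shannon(ds$community), ds$env, repeats = 1,
                   alpha_grid = 0.5, n_perm = 0, seed = 1)
  expect_lt(abs(vp$fractions[["pure_historical"]]), 0.05)
  expect_gt(vp$fractions[["pure_climatic"]], vp$fractions[["pure_historical"]])
})

test_that("permutation p-values follow (1 + exceedances) / (1 + n_perm)", {
  cfg <- sim_config(n_sites = 40, effect_sizes = c(climatic = -2),
                    cross_set_correlation = 0, noise_sd = 0.3, seed = 2)
  ds <- sim_dataset(cfg)
  vp <- en_varpart(ds$driver, ds$env, repeats = 1, alpha_grid = 0.5,
                   n_perm = 99, repeats_null = 1, seed = 3,
                   perm_fractions = "total_climatic")
  # the signal is overwhelming: no null value reaches the observed total
  expect_equal(vp$pvalues[["total_climatic"]], 1 / 100, tolerance = 1e-12)
  expect_true(vp$significant[["total_climatic"]])
  expect_error(en_varpart(ds$driver, ds$env, n_perm = 50, seed = 1),
               "n_perm")
})

test_that("partition inputs are validated", {
  env <- random_env(16)
  y <- with_seed_test(1, rnorm(16))
  no_soil <- predictor_table(as.data.frame(env)[, c(1:4, 8:11)],
                             sets = predictor_sets(env)[c(1:4, 8:11)])
  expect_error(en_varpart(y, no_soil), "lacks set")
  expect_error(en_varpart(rep(1, 16), env), "constant response")
  expect_error(en_varpart(y[1:10], env), "differ in length")
  expect_error(en_varpart(with_seed_test(2, rnorm(12)),
                          random_env(12, seed = 2)),
               "n - p - 1")
})

test_that("Moran's I matches hand oracles and the analytic null mean", {
  # 2x2 rook checkerboard: every neighbour pair has opposite sign -> I = -1
  rook_w <- function(nr, nc) {
    n <- nr * nc
    W <- matrix(0, n, n)
    idx <- function(i, j) (i - 1) * nc + j
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
          W[idx(i, j), idx(ii, jj)] <- 1
      }
    }
    W
  }
  checker <- function(nr, nc) {
    outer(seq_len(nr), seq_len(nc), function(i, j) ifelse((i + j) %% 2, 1, -1))
  }
  for (dims in list(c(2, 2), c(4, 4))) {
    z <- as.vector(t(checker(dims[1], dims[2])))
    mi <- morans_i(z, W = rook_w(dims[1], dims[2]), n_perm = 99, seed = 1)
    expect_equal(mi$I, -1, tolerance = 1e-12)
    expect_equal(mi$expected, -1 / (prod(dims) - 1))
  }
  # permutation null centres on -1/(n-1)
  z <- with_seed_test(5, rnorm(16))
  mi <- morans_i(z, W = rook_w(4, 4), n_perm = 999, seed = 2)
  expect_lt(abs(mi$null_mean - (-1 / 15)), 0.02)
})

test_that("Moran's I statistic agrees with an independent implementation", {
  skip_if_not_installed("ape")
  coords <- data.frame(lon = with_seed_test(6, runif(20, 100, 110)),
                       lat = with_seed_test(7, runif(20, 25, 35)))
  z <- with_seed_test(8, rnorm(20))
  dm <- as.matrix(great_circle_dist(coords))
  W <- 1 / dm; diag(W) <- 0; W <- W / rowSums(W)
  mine <- morans_i(z, coords = coords, n_perm = 99, seed = 1)
  theirs <- ape::Moran.I(z, W)
  expect_equal(mine$I, theirs$observed, tolerance = 1e-10)
})

test_that("a smooth latitudinal trend in residuals is detected", {
  coords <- data.frame(lon = with_seed_test(11, runif(50, 98, 122)),
                       lat = seq(22, 40, length.out = 50))
  resid <- scale(coords$lat)[, 1] + with_seed_test(12, rnorm(50, sd = 0.2))
  mi <- morans_i(resid, coords = coords, n_perm = 999, seed = 1)
  expect_lte(mi$p, 0.05)
  expect_error(morans_i(rep(0, 10), coords = coords[1:10, ]), "variance")
})
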