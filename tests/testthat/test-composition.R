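# NMDS, environmental vectors, Mantel tests, distance-based partitioning.

test_that("NMDS embeds an exactly two-dimensional configuration", {
  pts <- with_seed_test(1, matrix(rnorm(40), 20, 2))
  d <- dist(pts)
  ord <- suppressWarnings(nmds_ord(d, k = 2, n_starts = 20, seed = 1))
  expect_lt(ord$stress, 0.01)
  expect_equal(unname(colMeans(ord$scores)), c(0, 0), tolerance = 1e-8)
  # determinism
  ord2 <- suppressWarnings(nmds_ord(d, k = 2, n_starts = 20, seed = 1))
  expect_identical(ord$scores, ord2$scores)
})

test_that("NMDS stress does not increase with added dimensions", {
  m <- with_seed_test(2, matrix(rpois(15 * 12, 3), 15, 12))
  m[rowSums(m) == 0, 1] <- 1
  d <- braycurtis_dist(community_matrix(m))
  s2 <- nmds_ord(d, k = 2, n_starts = 20, seed = 3)$stress
  s3 <- nmds_ord(d, k = 3, n_starts = 20, seed = 3)$stress
  expect_lte(s3, s2 + 1e-6)
  bad <- matrix(runif(16), 4, 4)
  expect_error(nmds_ord(bad), "symmetric")
})

test_that("environmental vectors recover an axis-aligned variable", {
  sc <- with_seed_test(4, matrix(rnorm(60), 30, 2))
  sc <- scale(sc, scale = FALSE)
  ord <- structure(list(scores = sc), class = "nmds_ord")
  env <- predictor_table(
    data.frame(MAT = sc[, 1], SOC = with_seed_test(5, rnorm(30)),
               TA = with_seed_test(6, rnorm(30))),
    sets = c("climatic", "soil", "historical"))
  ef <- env_vector_fit(ord, env, n_perm = 199, seed = 1)
  mat <- ef[ef$variable == "MAT", ]
  expect_gt(mat$r2, 0.999)
  expect_equal(abs(mat$axis1), 1, tolerance = 1e-3)
  expect_lt(abs(mat$axis2), 0.05)
  expect_lt(mat$p, 0.05)
  # unit directions
  norms <- sqrt(ef$axis1^2 + ef$axis2^2)
  expect_equal(norms, rep(1, 3), tolerance = 1e-8)
})

test_that("envfit r2 is invariant to rotation of the scores", {
  sc <- with_seed_test(7, matrix(rnorm(50), 25, 2))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  env <- predictor_table(
    data.frame(MAT = with_seed_test(8, sc[, 1] + 0.5 * rnorm(25)),
               SOC = with_seed_test(9, rnorm(25)),
               TA = with_seed_test(10, rnorm(25))),
    sets = c("climatic", "soil", "historical"))
  r2a <- env_vector_fit(sc, env, n_perm = 99, seed = 1)$r2
  r2b <- env_vector_fit(sc %*% R, env, n_perm = 99, seed = 1)$r2
  expect_equal(r2a, r2b, tolerance = 1e-8)
})

test_that("constant environmental variables are reported inert", {
  sc <- with_seed_test(11, matrix(rnorm(40), 20, 2))
  env <- predictor_table(
    data.frame(MAT = with_seed_test(12, rnorm(20)), SOC = rep(3, 20),
               TA = with_seed_test(13, rnorm(20))),
    sets = c("climatic", "soil", "historical"))
  expect_warning(ef <- env_vector_fit(sc, env, n_perm = 99, seed = 1),
                 "constant")
  soc <- ef[ef$variable == "SOC", ]
  expect_equal(soc$r2, 0)
  expect_equal(soc$p, 1)
})

test_that("Mantel r is a correlation: identity and affine invariance", {
  d1 <- dist(with_seed_test(14, matrix(rnorm(30), 15, 2)))
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$r, 1,
               tolerance = 1e-12)
  expect_equal(mantel_test(d1, 2.5 * d1 + 0.3, n_perm = 99, seed = 1)$r, 1,
               tolerance = 1e-12)
  expect_error(mantel_test(d1, dist(matrix(0, 15, 2))), "variance")
  expect_error(mantel_test(d1, dist(matrix(rnorm(8), 4, 2))[1:3]),
               "size|symmetric")
})

test_that("Mantel permutations relabel sites, matching exhaustive enumeration", {
  n <- 5
  d1 <- dist(with_seed_test(15, matrix(rnorm(n * 2), n, 2)))
  d2 <- dist(with_seed_test(16, matrix(rnorm(n * 2), n, 2)))
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- grid[apply(grid, 1, function(p) length(unique(p)) == n), ]
  r_all <- apply(perms, 1, function(p) {
    cor(as.vector(as.dist(m1[p, p])), as.vector(d2))
  })
  obs <- cor(as.vector(d1), as.vector(d2))
  p_exact <- mean(r_all >= obs - 1e-12)
  mt <- mantel_test(d1, d2, n_perm = 999, seed = 2)
  expect_equal(mt$r, obs, tolerance = 1e-12)
  expect_lt(abs(mt$p - p_exact), 0.08)
})

test_that("predictor distances are rotation-invariant Euclidean distances", {
  env <- random_env(12, seed = 3)
  for (set in c("climatic", "soil", "historical")) {
    X <- set_matrix(env, set)
    expect_equal(as.matrix(predictor_distance(env, set)),
                 as.matrix(dist(scale(X))), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # duplicated site -> zero distance
  vals <- as.data.frame(env)
  vals[2, ] <- vals[1, ]
  env2 <- predictor_table(vals, sets = predictor_sets(env))
  expect_equal(as.matrix(predictor_distance(env2, "climatic"))[1, 2], 0)
})

test_that("a standardized (3,4) site difference gives distance 5", {
  # columns built with empirical sd exactly 1, so scale() only centres
  v1 <- c(0, 3, rep(1.5 + 0.75, 4), rep(1.5 - 0.75, 4))
  v2 <- c(0, 4, rep(2 + sqrt(1 / 8), 4), rep(2 - sqrt(1 / 8), 4))
  expect_equal(sd(v1), 1, tolerance = 1e-12)
  expect_equal(sd(v2), 1, tolerance = 1e-12)
  env <- predictor_table(
    data.frame(MAT = v1, MAP = v2,
               SOC = seq(0, 1, length.out = 10),
               TN = with_seed_test(17, rnorm(10)),
               TA = with_seed_test(18, rnorm(10)),
               PA = with_seed_test(19, rnorm(10))),
    sets = c("climatic", "climatic", "soil", "soil", "historical",
             "historical"))
  d <- as.matrix(predictor_distance(env, "climatic"))
  expect_equal(d[1, 2], 5, tolerance = 1e-10)
})

test_that("distance-based partitioning recovers a pure climatic signal", {
  env <- random_env(40, seed = 5)
  dc <- predictor_distance(env, "climatic")
  response <- 0.05 + 0.9 * dc   # exact linear function of climatic distance
  dbv <- db_varpart(response, env, n_perm = 0)
  expect_lt(abs(dbv$fractions[["pure_soil"]]), 0.02)
  expect_lt(abs(dbv$fractions[["pure_historical"]]), 0.02)
  expect_equal(dbv$fractions[["pure_climatic"]], dbv$combo_r2adj[["CSH"]],
               tolerance = 0.05)
  expect_gt(dbv$combo_r2adj[["C"]], 0.999)
  # conservation
  expect_lt(abs(sum(dbv$fractions) - dbv$combo_r2adj[["CSH"]]), 1e-10)
})

test_that("identical predictor sets leave no pure fractions", {
  base <- with_seed_test(20, data.frame(a = rnorm(16), b = rnorm(16)))
  env <- predictor_table(
    data.frame(MAT = base$a, MAP = base$b, SOC = base$a, TN = base$b,
               TA = base$a, PA = base$b),
    sets = c("climatic", "climatic", "soil", "soil", "historical",
             "historical"))
  d <- with_seed_test(21, {
    dist(matrix(rnorm(32), 16, 2)) + 0.5 * predictor_distance(env, "climatic")
  })
  dbv <- db_varpart(d, env, n_perm = 0)
  expect_lt(max(abs(dbv$fractions[c("pure_climatic", "pure_soil",
                                    "pure_historical")])), 0.01)
})

test_that("single-set distance regression matches a direct least-squares oracle", {
  env <- random_env(14, seed = 6)
  dresp <- with_seed_test(22, dist(matrix(rnorm(28), 14, 2)))
  dbv <- db_varpart(dresp, env, n_perm = 0)
  y <- as.vector(dresp)
  x <- as.vector(predictor_distance(env, "climatic"))
  ols <- summary(lm(y ~ x))
  npair <- length(y)
  oracle <- 1 - (1 - ols$r.squared) * (npair - 1) / (npair - 1 - 1)
  expect_equal(dbv$combo_r2adj[["C"]], oracle, tolerance = 1e-10)
})

test_that("db_varpart permutation machinery flags a strong climatic signal", {
  env <- random_env(16, seed = 7)
  response <- 0.1 + predictor_distance(env, "climatic")
  dbv <- db_varpart(response, env, n_perm = 199, seed = 1)
  expect_lt(dbv$pvalues[["total_climatic"]], 0.05)
  expect_true(dbv$significant[["pure_climatic"]])
  expect_true(all(dbv$pvalues > 0 & dbv$pvalues <= 1))
})

test_that("great-circle distances are plausible and labelled", {
  coords <- data.frame(site = c("a", "b"), lon = c(100, 101), lat = c(30, 30))
  d <- great_circle_dist(coords)
  # one degree of longitude at 30N is about 96.5 km
  expect_equal(as.vector(d), 111.32 * cos(30 * pi / 180), tolerance = 0.01)
  expect_equal(attr(d, "Labels"), c("a", "b"))
})
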