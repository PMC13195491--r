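test_that("FST linearization is exact and rejects the boundary", {
  expect_equal(linearize_fst(0), 0)
  expect_equal(linearize_fst(0.5), 1)
  expect_equal(round(linearize_fst(0.028), 4), 0.0288)
  expect_equal(linearize_fst(-0.01), -0.01 / 1.01)
  expect_error(linearize_fst(1), "infinite")
})

test_that("geographic distances match an independent haversine oracle", {
  frame <- data.frame(sample = c("a", "b", "c"),
                      population = c("p1", "p2", "p3"),
                      group = "A",
                      lon = c(0, 180, 121), lat = c(0, 0, 31))
  fst <- matrix(0.1, 3, 3, dimnames = list(c("p1", "p2", "p3"),
                                           c("p1", "p2", "p3")))
  diag(fst) <- 0
  env <- data.frame(population = c("p1", "p2", "p3"), horizon = "present",
                    bio12 = c(1000, 1500, 1200), bio5 = c(30, 32, 31))
  dm <- distance_matrices(frame, env, fst,
                          env_vars = c("bio5", "bio12"))
  # antipodal points: half the great circle
  expect_equal(dm$geographic_km["p1", "p2"], 6371 * pi, tolerance = 1)
  expect_equal(dm$geographic_km["p1", "p1"], 0)
  # against the formula written out independently
  frame2 <- data.frame(sample = 1:2, population = c("sh", "tk"),
                       group = "A", lon = c(121, 139), lat = c(31, 35))
  fst2 <- matrix(c(0, .1, .1, 0), 2,
                 dimnames = list(c("sh", "tk"), c("sh", "tk")))
  env2 <- data.frame(population = c("sh", "tk"), horizon = "present",
                     bio12 = c(1, 2), bio5 = c(1, 2))
  dm2 <- distance_matrices(frame2, env2, fst2,
                           env_vars = c("bio5", "bio12"))
  expect_equal(dm2$geographic_km["sh", "tk"],
               brute_haversine_km(31, 121, 35, 139), tolerance = 1)
  # genetic distances are the linearized fst
  expect_equal(dm2$genetic["sh", "tk"], 0.1 / 0.9)
})

test_that("Mantel test recovers perfect correlation and is seed-stable", {
  set.seed(81)
  a <- as.matrix(dist(matrix(rnorm(20), 10)))
  r <- mantel_test(a, a, n_perm = 99, seed = 1)
  expect_equal(r$r, 1)
  b <- as.matrix(dist(matrix(rnorm(20), 10)))
  p1 <- mantel_test(a, b, n_perm = 199, seed = 7)$p
  p2 <- mantel_test(a, b, n_perm = 199, seed = 7)$p
  expect_identical(p1, p2)
  expect_error(mantel_test(a, matrix(1, 10, 10), n_perm = 99), "constant")
})

test_that("mantel r is invariant under simultaneous label permutation", {
  set.seed(82)
  a <- as.matrix(dist(matrix(rnorm(24), 12)))
  b <- as.matrix(dist(matrix(rnorm(24), 12)))
  perm <- sample(12)
  r1 <- mantel_test(a, b, n_perm = 49, seed = 1)$r
  r2 <- mantel_test(a[perm, perm], b[perm, perm], n_perm = 49, seed = 1)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("collinearity filter drops exactly the planted offenders", {
  set.seed(83)
  n <- 40
  m <- matrix(rnorm(n * 6), n,
              dimnames = list(NULL, paste0("v", 1:6)))
  # duplicated variable: one of the pair goes
  dup <- cbind(m, v7 = m[, "v1"])
  kept <- collinearity_filter(dup, r_max = 0.8)
  expect_equal(length(kept), 6L)
  expect_equal(sum(c("v1", "v7") %in% kept), 1L)
  # independent variables all retained
  if (max(abs(cor(m))[upper.tri(cor(m))]) < 0.8) {
    expect_equal(collinearity_filter(m, r_max = 0.8), colnames(m))
  }
  # 8-variable fixture with one planted pair at r ~ 0.95
  m8 <- matrix(rnorm(n * 7), n, dimnames = list(NULL, paste0("w", 1:7)))
  m8 <- cbind(m8, w8 = m8[, "w3"] + rnorm(n, 0, 0.3))
  stopifnot(abs(cor(m8[, "w3"], m8[, "w8"])) > 0.9)
  kept8 <- collinearity_filter(m8, r_max = 0.8)
  expect_equal(length(kept8), 7L)
})

test_that("RDA explained variance hits the exact limits", {
  set.seed(84)
  n <- 40
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("x1", "x2")))
  noise <- matrix(rnorm(n * 10), n)
  # response orthogonal to X by explicit residualization
  Xc <- cbind(1, scale(X))
  Yo <- noise - Xc %*% solve(crossprod(Xc), crossprod(Xc, noise))
  expect_lt(rda_r2(Yo, X, n_perm = 0)$r2, 1e-12)
  # response exactly linear in X
  B <- matrix(rnorm(2 * 10), 2)
  Yl <- scale(X) %*% B
  expect_equal(rda_r2(Yl, X, n_perm = 0)$r2, 1, tolerance = 1e-12)
  # empty conditioning block equals no conditioning
  Y <- noise + scale(X) %*% B
  r_no <- rda_r2(Y, X, n_perm = 99, seed = 5)
  r_empty <- rda_r2(Y, X, Z = matrix(numeric(0), n, 0), n_perm = 99,
                    seed = 5)
  expect_identical(r_no, r_empty)
  # rank-deficient predictors are refused with names
  Xbad <- cbind(X, x3 = X[, 1])
  expect_error(rda_r2(Y, Xbad, n_perm = 0), "x3")
})

test_that("RDA agrees with vegan on ordinary and partial models", {
  set.seed(85)
  n <- 30
  Y <- matrix(rnorm(n * 25), n)
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  Z <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("u", "v")))
  ours <- rda_r2(Y, X, n_perm = 0)
  veg <- vegan::RsquareAdj(vegan::rda(Y ~ scale(X)))
  expect_equal(ours$r2, veg$r.squared, tolerance = 1e-10)
  expect_equal(ours$r2_adj, veg$adj.r.squared, tolerance = 1e-10)
  ours_p <- rda_r2(Y, X, Z = Z, n_perm = 0)
  vfit <- vegan::rda(Y ~ scale(X) + Condition(scale(Z)))
  veg_p <- vfit$CCA$tot.chi / vfit$tot.chi
  expect_equal(ours_p$r2, veg_p, tolerance = 1e-10)
})

test_that("planted-signal RDA recovers a known variance fraction", {
  set.seed(86)
  n <- 50
  x <- rnorm(n)
  loadings <- rnorm(200, 0, sqrt(0.1))
  Y <- outer(x, loadings) + matrix(rnorm(n * 200, 0, sqrt(0.9)), n)
  r <- rda_r2(Y, cbind(x = x), n_perm = 99, seed = 2)
  expect_gt(r$r2, 0.05)
  expect_lt(r$r2, 0.2)
  expect_lt(r$p, 0.05)
})

test_that("variance partition reproduces the two-block identities", {
  part <- variance_partition(0.0628, 0.0195, 0.0473)
  expect_equal(part$r2_geo_given_env, 0.0155, tolerance = 1e-10)
  expect_equal(part$r2_env_given_geo, 0.0433, tolerance = 1e-10)
  expect_equal(part$confounded, 0.004, tolerance = 1e-10)
  expect_equal(part$unexplained, 0.9372, tolerance = 1e-10)
})

test_that("pRDA partitioning handles orthogonal and confounded designs", {
  set.seed(87)
  n <- 60
  e <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("e1", "e2")))
  g <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("lon", "lat")))
  Y <- scale(e) %*% matrix(rnorm(2 * 50, 0, 0.3), 2) +
    scale(g) %*% matrix(rnorm(2 * 50, 0, 0.3), 2) +
    matrix(rnorm(n * 50), n)
  part <- prda_partition(Y, e, g, n_perm = 49, seed = 3)
  # identities hold to machine precision
  expect_equal(part$r2_geo_given_env, part$r2_full - part$r2_env,
               tolerance = 1e-12)
  expect_equal(part$confounded,
               part$r2_geo + part$r2_env - part$r2_full,
               tolerance = 1e-12)
  expect_equal(part$unexplained, 1 - part$r2_full, tolerance = 1e-12)
  # random orthogonal predictor blocks: tiny confounded fraction
  expect_lt(abs(part$confounded), 0.05)
  # near-duplicated blocks: conditional fractions collapse, confounded
  # carries (almost) the whole marginal fraction
  g2 <- e + matrix(rnorm(n * 2, 0, 0.02), n)
  colnames(g2) <- c("lon", "lat")
  Y2 <- scale(e) %*% matrix(rnorm(2 * 50, 0, 0.5), 2) +
    matrix(rnorm(n * 50), n)
  part2 <- prda_partition(Y2, e, g2, n_perm = 0)
  expect_lt(part2$r2_env_given_geo, 0.02)
  expect_lt(part2$r2_geo_given_env, 0.02)
  expect_gt(part2$confounded, 0.9 * part2$r2_env)
})
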