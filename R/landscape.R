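#' Linearized genetic distance from FST
#'
#' The classical FST / (1 - FST) transform used before regressing genetic
#' on geographic/environmental distance. Monotone; negative FST estimates
#' pass through unchanged in sign.
#'
#' @param fst numeric vector or matrix of FST values, all < 1.
#' @return Same shape, transformed.
#' @export
linearize_fst <- function(fst) {
  if (any(fst >= 1, na.rm = TRUE)) stop("fst = 1 gives infinite distance")
  fst / (1 - fst)
}

#' Pairwise Hudson FST between populations
#'
#' Ratio-of-sums Hudson estimator over variant sites for every pair of
#' populations (or groups).
#'
#' @param gm a [genotype_matrix()].
#' @param frame matching sample frame.
#' @param by grouping column of `frame` (default `"population"`).
#' @return Symmetric matrix of pairwise FST with zero diagonal.
#' @export
pairwise_fst <- function(gm, frame, by = "population") {
  units <- unique(frame[[by]])
  k <- length(units)
  snps <- gm$is_variant
  wc <- lapply(units, function(u) {
    w <- within_counts(gm, which(frame[[by]] == u))
    list(diff = sum(w$diff[snps]), comp = sum(w$comp[snps]),
         idx = which(frame[[by]] == u))
  })
  names(wc) <- units
  m <- matrix(0, k, k, dimnames = list(units, units))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      bt <- between_counts(gm, wc[[i]]$idx, wc[[j]]$idx)
      hb <- sum(bt$diff[snps]) / sum(bt$comp[snps])
      hw <- (wc[[i]]$diff + wc[[j]]$diff) / (wc[[i]]$comp + wc[[j]]$comp)
      m[i, j] <- m[j, i] <- if (is.finite(hb) && hb > 0) 1 - hw / hb
                            else NA_real_
    }
  }
  m
}

#' Genetic, geographic and environmental distance matrices
#'
#' Geographic distances are great-circle (haversine, Earth radius 6371 km)
#' between population coordinates; environmental distances are Euclidean on
#' variables standardized to zero mean and unit variance across
#' populations; genetic distances are linearized FST.
#'
#' @param frame sample frame (population coordinates are taken from the
#'   first sample of each population).
#' @param env environment table (long-by-horizon); present-day values used.
#' @param fst_mat symmetric pairwise FST matrix (e.g. [pairwise_fst()]).
#' @param env_vars environment variables to use (default: all, normally
#'   the survivors of [collinearity_filter()]).
#' @return List with `genetic`, `geographic_km`, `environmental` matrices
#'   over the populations of `fst_mat`, in its order.
#' @export
distance_matrices <- function(frame, env, fst_mat,
                              env_vars = NULL) {
  pops <- rownames(fst_mat)
  i <- match(pops, frame$population)
  if (anyNA(i)) stop("population(s) missing from frame: ",
                     paste(pops[is.na(i)], collapse = ", "))
  coords <- cbind(frame$lon[i], frame$lat[i])
  geo <- matrix(0, length(pops), length(pops),
                dimnames = list(pops, pops))
  for (a in seq_along(pops)) {
    geo[a, ] <- geosphere::distHaversine(coords[a, ], coords,
                                         r = 6371000) / 1000
  }
  ew <- env_wide(env, "present", env_vars)
  if (!all(pops %in% rownames(ew))) {
    stop("population(s) missing from environment table")
  }
  ew <- ew[pops, , drop = FALSE]
  ez <- scale(ew)
  envd <- as.matrix(dist(ez))
  dimnames(envd) <- list(pops, pops)
  gen <- linearize_fst(fst_mat)
  list(genetic = gen, geographic_km = geo, environmental = envd)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of lower-triangle entries, with significance from
#' row/column label permutation (one-sided, greater — the isolation-by-
#' distance direction). The permutation machinery is vegan's;
#' `p = (1 + #{permuted r >= observed}) / (n_perm + 1)`.
#'
#' @param a,b symmetric distance matrices with matching labels.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed for reproducible permutation.
#' @return List: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(a, b, n_perm = 9999, seed = NULL) {
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!identical(rownames(a), rownames(b))) {
      stop("distance matrices must share the same label order")
    }
  }
  stopifnot(nrow(a) >= 4)
  if (sd(a[lower.tri(a)]) == 0 || sd(b[lower.tri(b)]) == 0) {
    stop("constant distance matrix: Mantel r undefined")
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(as.dist(a), as.dist(b), method = "pearson",
                       permutations = n_perm)
  list(r = unname(fit$statistic), p = fit$signif, n_perm = n_perm)
}

#' Iterative collinearity filter on environmental variables
#'
#' While any pair of variables correlates beyond `r_max` in absolute value
#' across populations, the member of the worst offending pair with the
#' larger mean absolute correlation to all other retained variables is
#' dropped (ties broken by dropping the alphabetically later name).
#'
#' @param env environment table (long-by-horizon; present-day values used)
#'   or a populations x variables numeric matrix.
#' @param r_max correlation ceiling (default 0.8 — pairs with |r| above
#'   this are broken up).
#' @return Character vector of retained variable names.
#' @export
collinearity_filter <- function(env, r_max = 0.8) {
  m <- if (is.data.frame(env) && "horizon" %in% names(env)) {
    env_wide(env, "present")
  } else {
    as.matrix(env)
  }
  vars <- colnames(m)
  stopifnot(length(vars) >= 2)
  repeat {
    r <- abs(cor(m[, vars, drop = FALSE]))
    diag(r) <- 0
    if (max(r) <= r_max) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- vars[worst]
    mean_abs <- rowMeans(abs(r))[pair]
    drop <- if (mean_abs[1] > mean_abs[2]) pair[1]
            else if (mean_abs[2] > mean_abs[1]) pair[2]
            else sort(pair)[2]
    vars <- setdiff(vars, drop)
    if (length(vars) < 2) break
  }
  vars
}

# least-squares multivariate fit machinery shared by RDA functions
check_full_rank <- function(X, what = "predictor") {
  q <- qr(cbind(1, X))
  if (q$rank < ncol(X) + 1) {
    idx <- q$pivot[seq(q$rank + 1, ncol(X) + 1)] - 1
    bad <- colnames(X)[idx[idx >= 1]]
    stop("rank-deficient ", what, " matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
}

project_fit <- function(Y, X) {
  # fitted values of Y on (intercept-free, pre-centered) X
  qx <- qr(X)
  qr.fitted(qx, Y)
}

#' Redundancy-analysis explained variance
#'
#' The RDA R-squared: trace of the fitted covariance over trace of the
#' total covariance, from a least-squares multivariate regression of the
#' (centered) response matrix on standardized predictors. With conditioning
#' predictors `Z` (partial RDA), both response and predictors are first
#' residualized on `Z`; the returned fraction is still relative to the
#' total variance of the full, unconditioned response, so that marginal and
#' conditional fractions obey the additive variance-partition identities.
#' Significance is by permutation of the reduced-model residuals.
#'
#' @param Y response matrix (rows = samples/populations), e.g. an
#'   individual-level allele-frequency matrix (dosage / 2).
#' @param X predictor matrix.
#' @param Z optional conditioning predictors.
#' @param n_perm permutations for the p-value (default 999); 0 skips.
#' @param seed optional seed.
#' @return List: `r2`, `r2_adj`, `p` (`NA` when `n_perm = 0`).
#' @export
rda_r2 <- function(Y, X, Z = NULL, n_perm = 999, seed = NULL) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  if (!is.null(Z) && ncol(as.matrix(Z)) == 0) Z <- NULL
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  check_full_rank(X)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(X)
  ss_tot <- sum(Yc^2)
  if (ss_tot == 0) stop("response has zero variance")
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    stopifnot(nrow(Z) == n, n > ncol(X) + ncol(Z))
    Zs <- scale(Z)
    Yr <- Yc - project_fit(Yc, Zs)
    Xr <- Xs - project_fit(Xs, Zs)
  } else {
    stopifnot(n > ncol(X))
    Yr <- Yc
    Xr <- Xs
  }
  qx <- qr(Xr)
  fit <- qr.fitted(qx, Yr)
  ss_fit <- sum(fit^2)
  r2 <- ss_fit / ss_tot
  q <- ncol(X)
  pz <- if (is.null(Z)) 0 else ncol(Z)
  df_res <- n - 1 - q - pz
  r2_adj <- 1 - (1 - r2) * (n - 1 - pz) / df_res
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      Yp <- Yr[sample.int(n), , drop = FALSE]
      if (sum(qr.fitted(qx, Yp)^2) >= ss_fit) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
  }
  list(r2 = r2, r2_adj = r2_adj, p = p)
}

#' Variance-partition arithmetic
#'
#' The additive identities that decompose a two-block redundancy analysis:
#' conditional fractions by subtraction from the full model, the confounded
#' (jointly explained) fraction, and the unexplained remainder.
#'
#' @param r2_full explained fraction of the full (both-block) model.
#' @param r2_geo,r2_env marginal explained fractions of each block alone.
#' @return List: the inputs plus `r2_geo_given_env`, `r2_env_given_geo`,
#'   `confounded`, `unexplained`.
#' @export
variance_partition <- function(r2_full, r2_geo, r2_env) {
  list(
    r2_full = r2_full, r2_geo = r2_geo, r2_env = r2_env,
    r2_geo_given_env = r2_full - r2_env,
    r2_env_given_geo = r2_full - r2_geo,
    confounded = r2_geo + r2_env - r2_full,
    unexplained = 1 - r2_full
  )
}

#' Partial-RDA variance partitioning over environment and geography
#'
#' Fits the full model (environment + geography), the two marginal models,
#' and the two conditional (partial) models on a genetic response matrix,
#' and assembles the variance-partition table. The conditional fractions
#' from the partial fits equal the subtraction identities exactly (nested
#' least-squares projections), and are asserted to 1e-12 on every run.
#'
#' @param Y genetic response matrix (samples x loci allele frequencies).
#' @param X_env environmental predictor block.
#' @param X_geo geographic predictor block (e.g. lon, lat).
#' @param n_perm permutations per testable fraction (default 999).
#' @param seed optional seed.
#' @return List of class `variance_partition`: all fractions from
#'   [variance_partition()], adjusted R-squareds, and permutation p-values
#'   (`p_full`, `p_geo`, `p_env` marginal; `p_geo_given_env`,
#'   `p_env_given_geo` conditional).
#' @export
prda_partition <- function(Y, X_env, X_geo, n_perm = 999, seed = NULL) {
  X_env <- as.matrix(X_env)
  X_geo <- as.matrix(X_geo)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 5)
  full <- rda_r2(Y, cbind(X_env, X_geo), n_perm = n_perm, seed = seeds[1])
  env <- rda_r2(Y, X_env, n_perm = n_perm, seed = seeds[2])
  geo <- rda_r2(Y, X_geo, n_perm = n_perm, seed = seeds[3])
  env_g <- rda_r2(Y, X_env, Z = X_geo, n_perm = n_perm, seed = seeds[4])
  geo_e <- rda_r2(Y, X_geo, Z = X_env, n_perm = n_perm, seed = seeds[5])
  part <- variance_partition(full$r2, geo$r2, env$r2)
  stopifnot(abs(part$r2_env_given_geo - env_g$r2) < 1e-12,
            abs(part$r2_geo_given_env - geo_e$r2) < 1e-12)
  out <- c(part, list(
    r2_adj_full = full$r2_adj, r2_adj_geo = geo$r2_adj,
    r2_adj_env = env$r2_adj,
    r2_adj_env_given_geo = env_g$r2_adj,
    r2_adj_geo_given_env = geo_e$r2_adj,
    p_full = full$p, p_geo = geo$p, p_env = env$p,
    p_env_given_geo = env_g$p, p_geo_given_env = geo_e$p
  ))
  class(out) <- "variance_partition"
  out
}

#' @export
print.variance_partition <- function(x, ...) {
  fmt <- function(v) formatC(v, digits = 4, format = "f")
  cat("pRDA variance partition\n")
  cat("  full (env + geo):  r2 =", fmt(x$r2_full), " p =", x$p_full, "\n")
  cat("  env (marginal):    r2 =", fmt(x$r2_env), " p =", x$p_env, "\n")
  cat("  geo (marginal):    r2 =", fmt(x$r2_geo), " p =", x$p_geo, "\n")
  cat("  env | geo:         r2 =", fmt(x$r2_env_given_geo),
      " p =", x$p_env_given_geo, "\n")
  cat("  geo | env:         r2 =", fmt(x$r2_geo_given_env),
      " p =", x$p_geo_given_env, "\n")
  cat("  confounded:        ", fmt(x$confounded), "\n")
  cat("  unexplained:       ", fmt(x$unexplained), "\n")
  invisible(x)
}
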