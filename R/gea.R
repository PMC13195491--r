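#' Mean-imputed numeric dosage matrix
#'
#' Missing dosages are replaced by the per-site mean of the called
#' genotypes — the standard preparation before SVD and ordination, where
#' mean imputation leaves the centered column orthogonal to the missing
#' pattern.
#'
#' @param gm a [genotype_matrix()].
#' @param sites column selector (default: all).
#' @return Numeric samples x sites matrix without missing values.
#' @export
impute_dosage <- function(gm, sites = NULL) {
  d <- gm$dosage[, if (is.null(sites)) TRUE else sites, drop = FALSE]
  storage.mode(d) <- "double"
  mu <- colMeans(d, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  na_idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(na_idx)) d[na_idx] <- mu[na_idx[, 2]]
  d
}

#' Latent population-structure factors
#'
#' Top-K left singular vectors of the centered (mean-imputed) dosage
#' matrix, unit-scaled — the deterministic analogue of the latent factors a
#' mixed-model association method estimates. K = 2 mirrors a two-group
#' population structure.
#'
#' When the factors are destined for a genotype-environment association
#' scan, pass the environmental covariate(s) through `covariates`: the
#' dosage matrix is then projected onto the orthogonal complement of the
#' covariate space before the SVD, so the factors capture structure that is
#' not attributable to the tested gradient. This is how latent-factor
#' association models avoid conditioning the environmental effect away
#' when a strong polygenic cline itself forms a leading axis of variation.
#'
#' @param gm a [genotype_matrix()], ideally LD-pruned variant sites.
#' @param K number of factors (0 gives an empty matrix and reduces any
#'   downstream association to simple regression).
#' @param covariates optional samples x q numeric matrix (e.g. standardized
#'   per-sample environment values) projected out before factor extraction.
#' @return Samples x K matrix of unit-norm factor columns.
#' @export
latent_factors <- function(gm, K = 2, covariates = NULL) {
  n <- nrow(gm$dosage)
  m <- ncol(gm$dosage)
  if (K >= min(n, m)) stop("K must be smaller than min(samples, sites)")
  if (K == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(rownames(gm$dosage), NULL)))
  }
  d <- impute_dosage(gm)
  dc <- scale(d, center = TRUE, scale = FALSE)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    stopifnot(nrow(cv) == n)
    dc <- dc - qr.fitted(qr(cbind(1, cv)), dc)
  }
  sv <- svd(dc, nu = K, nv = 0)
  u <- sv$u
  rownames(u) <- rownames(gm$dosage)
  colnames(u) <- paste0("U", seq_len(K))
  u
}

# multi-response OLS of each dosage column on (intercept, env, factors);
# returns per-site env coefficient, its t statistic and two-sided p
env_assoc_ols <- function(D, env_z, factors) {
  X <- cbind(1, env = env_z, factors)
  n <- nrow(X)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) stop("association design matrix is rank deficient")
  coefs <- qr.coef(qx, D)
  res <- D - qr.fitted(qx, D)
  rss <- colSums(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qx))
  se_env <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- coefs[2, ]
  t_stat <- beta / se_env
  list(beta = beta, t = t_stat,
       p = 2 * pt(abs(t_stat), df = n - p, lower.tail = FALSE))
}

#' Genotype-environment association scan
#'
#' Two-stage latent-factor association: per site, ordinary least squares of
#' dosage on the standardized environmental variable plus the latent
#' factors (and an intercept); the t test on the environmental coefficient
#' gives the p-value, Benjamini-Hochberg adjustment gives q, and q < 0.05
#' flags significance. The genomic inflation factor lambda
#' (median chi-squared over 0.456) is attached for calibration checks.
#'
#' @param gm a [genotype_matrix()].
#' @param env environment table (long-by-horizon) or a named per-population
#'   numeric vector of the variable's present-day values.
#' @param frame sample frame mapping samples to populations.
#' @param factors samples x K latent-factor matrix from [latent_factors()]
#'   (or a 0-column matrix for simple regression).
#' @param variable environment variable name (when `env` is a table).
#' @param sites column selector restricting the scan (default: variant
#'   sites).
#' @param q_threshold significance threshold on q (default 0.05).
#' @return Data frame of class `gea_hits`: site_id, variable, beta, p, q,
#'   significant; monomorphic sites are skipped. Attribute `lambda` holds
#'   the inflation factor.
#' @export
gea_scan <- function(gm, env, frame, factors, variable = "bio12",
                     sites = NULL, q_threshold = 0.05) {
  if (is.null(sites)) sites <- which(gm$is_variant)
  pops <- frame$population
  if (is.data.frame(env)) {
    ep <- env[env$horizon == "present", ]
    vals <- ep[[variable]][match(pops, ep$population)]
  } else {
    vals <- env[pops]
  }
  if (anyNA(vals)) stop("environment value missing for some samples")
  if (sd(vals) == 0) stop("environment variable '", variable,
                          "' is constant: no association test possible")
  env_z <- (vals - mean(vals)) / sd(vals)
  D <- impute_dosage(gm, sites)
  poly <- apply(D, 2, function(x) var(x) > 0)
  use <- sites[poly]
  D <- D[, poly, drop = FALSE]
  fit <- env_assoc_ols(D, env_z, factors)
  q <- p.adjust(fit$p, method = "BH")
  lambda <- median(fit$t^2) / qchisq(0.5, df = 1)
  out <- data.frame(site_id = use, variable = variable,
                    beta = fit$beta, p = fit$p, q = q,
                    significant = q < q_threshold, row.names = NULL)
  attr(out, "lambda") <- lambda
  class(out) <- c("gea_hits", class(out))
  out
}

#' Per-site FST outlier scan (Lewontin-Krakauer style)
#'
#' Per-site Hudson FST across populations (ratio of within- to between-
#' population heterozygosity sums over all population pairs), scaled into
#' the Lewontin-Krakauer statistic t = (k - 1) * fst / mean(fst) and
#' referred to a chi-squared distribution with k - 1 degrees of freedom
#' (upper tail: diversifying selection). Benjamini-Hochberg q-values flag
#' outliers at q < 0.05. This scan fills the divergence-outlier role of a
#' Bayesian FST outlier method with a transparent, testable statistic.
#'
#' @param gm a [genotype_matrix()].
#' @param frame sample frame with a `population` column.
#' @param sites column selector (default: variant sites).
#' @param q_threshold significance threshold (default 0.05).
#' @return Data frame: site_id, fst_site, t_stat, p, q, significant.
#'   Sites called in fewer than two populations are skipped.
#' @export
fst_outlier_scan <- function(gm, frame, sites = NULL, q_threshold = 0.05) {
  if (is.null(sites)) sites <- which(gm$is_variant)
  pops <- unique(frame$population)
  k <- length(pops)
  if (k < 2) stop("need at least two populations")
  # per-pop per-site allele counts
  refs <- alts <- ns <- matrix(0, k, length(sites))
  for (i in seq_len(k)) {
    ac <- allele_counts(gm, which(frame$population == pops[i]))
    refs[i, ] <- ac$n_ref[sites]
    alts[i, ] <- ac$n_alt[sites]
    ns[i, ] <- ac$n_alleles[sites]
  }
  w_diff <- colSums(refs * alts)
  w_comp <- colSums(ns * (ns - 1) / 2)
  tot_ref <- colSums(refs); tot_alt <- colSums(alts); tot_n <- colSums(ns)
  # between = all cross-population pairs = all pairs minus within pairs
  b_diff <- (tot_ref * tot_alt) - w_diff
  b_comp <- tot_n * (tot_n - 1) / 2 - w_comp
  called_pops <- colSums(ns > 0)
  ok <- called_pops >= 2 & b_comp > 0
  hw <- w_diff / w_comp
  hb <- b_diff / b_comp
  fst <- ifelse(ok & hb > 0, 1 - hw / hb, NA_real_)
  use <- which(!is.na(fst))
  fst_u <- fst[use]
  mean_fst <- mean(fst_u)
  if (mean_fst > 0) {
    t_stat <- (k - 1) * fst_u / mean_fst
    p <- pchisq(t_stat, df = k - 1, lower.tail = FALSE)
  } else {
    # no average divergence at all: nothing can be an outlier
    t_stat <- rep(NA_real_, length(use))
    p <- rep(1, length(use))
  }
  q <- p.adjust(p, method = "BH")
  data.frame(site_id = sites[use], fst_site = fst_u, t_stat = t_stat,
             p = p, q = q, significant = q < q_threshold, row.names = NULL)
}

#' Intersect association and outlier candidate sets
#'
#' The Venn step: sites significant for at least one environmental variable
#' intersected with the divergence-outlier set, with counts at the given
#' threshold.
#'
#' @param gea_hits a `gea_hits` data frame (possibly row-bound across
#'   variables, see [gea_scan()]).
#' @param outlier_hits output of [fst_outlier_scan()].
#' @param use_q intersect on the q < threshold flags (default) or on raw
#'   p-value thresholds.
#' @param threshold threshold applied when `use_q = FALSE`.
#' @return List: `shared` (sorted site ids), `n_gea`, `n_outlier`,
#'   `n_shared`.
#' @export
intersect_candidates <- function(gea_hits, outlier_hits, use_q = TRUE,
                                 threshold = 0.05) {
  gea_set <- if (use_q) unique(gea_hits$site_id[gea_hits$significant])
             else unique(gea_hits$site_id[gea_hits$p <= threshold])
  out_set <- if (use_q) outlier_hits$site_id[outlier_hits$significant]
             else outlier_hits$site_id[outlier_hits$p <= threshold]
  shared <- sort(intersect(gea_set, out_set))
  list(shared = shared, n_gea = length(gea_set),
       n_outlier = length(out_set), n_shared = length(shared))
}

#' Risk of non-adaptedness under a future climate
#'
#' Per candidate site, population allele frequency is regressed on the
#' present-day value of one environmental variable across populations; only
#' sites whose regression achieves p < `significance_p` enter. For each
#' population, RONA is the mean over qualifying sites of the absolute
#' difference between the frequency predicted under the future value and
#' under the present value, with predictions clamped to [0, 1] before
#' differencing. Zero climate change gives RONA exactly zero.
#'
#' @param freq populations x sites allele-frequency matrix
#'   ([population_frequencies()]).
#' @param env environment table with present and future horizons.
#' @param variable environmental variable name.
#' @param scenario future horizon label (e.g. `"SSP585_2081_2100"`).
#' @param sites candidate site columns (default: all).
#' @param significance_p per-site regression p-value gate (default 0.05).
#' @return Data frame: population, variable, scenario, rona, n_snps_used.
#'   `rona` is `NA` when no site qualifies.
#' @export
rona <- function(freq, env, variable, scenario = "SSP585_2081_2100",
                 sites = NULL, significance_p = 0.05) {
  if (is.null(sites)) sites <- seq_len(ncol(freq))
  pops <- rownames(freq)
  ep <- env[env$horizon == "present", ]
  ef <- env[env$horizon == scenario, ]
  x_now <- ep[[variable]][match(pops, ep$population)]
  x_fut <- ef[[variable]][match(pops, ef$population)]
  if (anyNA(x_now) || anyNA(x_fut)) {
    stop("environment values missing for some populations")
  }
  Y <- freq[, sites, drop = FALSE]
  ok_site <- colSums(is.finite(Y)) >= 3
  n <- length(pops)
  xc <- x_now - mean(x_now)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("environment variable '", variable, "' is constant")
  # per-site simple regression with complete rows (frequencies rarely
  # missing; fall back to lm when they are)
  slope <- intercept <- pval <- rep(NA_real_, ncol(Y))
  complete <- colSums(!is.finite(Y)) == 0
  if (any(complete)) {
    Yc <- Y[, complete, drop = FALSE]
    b <- as.numeric(crossprod(xc, sweep(Yc, 2, colMeans(Yc)))) / sxx
    a <- colMeans(Yc) - b * mean(x_now)
    fitted <- outer(x_now, b) + rep(a, each = n)
    rss <- colSums((Yc - fitted)^2)
    se_b <- sqrt(rss / (n - 2) / sxx)
    pv <- 2 * pt(abs(b / se_b), df = n - 2, lower.tail = FALSE)
    # a perfect linear fit has zero residual: infinitely significant slope
    pv[se_b == 0] <- ifelse(b[se_b == 0] != 0, 0, 1)
    slope[complete] <- b
    intercept[complete] <- a
    pval[complete] <- pv
  }
  for (j in which(ok_site & !complete)) {
    rows <- is.finite(Y[, j])
    fit <- lm(Y[rows, j] ~ x_now[rows])
    slope[j] <- coef(fit)[2]
    intercept[j] <- coef(fit)[1]
    pval[j] <- summary(fit)$coefficients[2, 4]
  }
  qualifying <- which(is.finite(pval) & pval < significance_p)
  if (!length(qualifying)) {
    return(data.frame(population = pops, variable = variable,
                      scenario = scenario, rona = NA_real_,
                      n_snps_used = 0L, row.names = NULL))
  }
  b <- slope[qualifying]
  a <- intercept[qualifying]
  pred_now <- pmin(pmax(outer(x_now, b) + rep(a, each = n), 0), 1)
  pred_fut <- pmin(pmax(outer(x_fut, b) + rep(a, each = n), 0), 1)
  data.frame(population = pops, variable = variable, scenario = scenario,
             rona = rowMeans(abs(pred_fut - pred_now)),
             n_snps_used = length(qualifying), row.names = NULL)
}
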