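#' Pairwise difference and comparison counts at a single site
#'
#' The counting kernel behind the invariant-site-aware estimators. With one
#' sample set, all unordered pairs of the non-missing alleles within the set
#' are considered: `n_comp = choose(N, 2)` and `n_diff = n_ref * n_alt`,
#' where N counts alleles of called genotypes only. With two sets, only
#' cross-set pairs count: `n_comp = N1 * N2`,
#' `n_diff = ref1 * alt2 + alt1 * ref2`.
#'
#' @param column dosage vector (0/1/2/NA).
#' @param set1 indices of the first sample set.
#' @param set2 optional indices of a second, disjoint sample set.
#' @return Named numeric vector `c(n_diff, n_comp)`; `c(0, 0)` when no
#'   comparison is possible.
#' @export
site_diff_counts <- function(column, set1, set2 = NULL) {
  count <- function(idx) {
    v <- column[idx]
    v <- v[!is.na(v)]
    n_alt <- sum(v)
    n_all <- 2 * length(v)
    c(ref = n_all - n_alt, alt = n_alt, n = n_all)
  }
  a <- count(set1)
  if (is.null(set2)) {
    c(n_diff = unname(a["ref"] * a["alt"]),
      n_comp = unname(a["n"] * (a["n"] - 1) / 2))
  } else {
    if (length(intersect(set1, set2))) stop("sample sets must be disjoint")
    b <- count(set2)
    c(n_diff = unname(a["ref"] * b["alt"] + a["alt"] * b["ref"]),
      n_comp = unname(a["n"] * b["n"]))
  }
}

# vectorized per-site counts for a sample set: within-set diffs/comps
within_counts <- function(gm, samples) {
  ac <- allele_counts(gm, samples)
  list(diff = as.numeric(ac$n_ref) * ac$n_alt,
       comp = as.numeric(ac$n_alleles) * (ac$n_alleles - 1) / 2)
}

# vectorized per-site cross-set diffs/comps
between_counts <- function(gm, samples1, samples2) {
  a <- allele_counts(gm, samples1)
  b <- allele_counts(gm, samples2)
  list(diff = as.numeric(a$n_ref) * b$n_alt + as.numeric(a$n_alt) * b$n_ref,
       comp = as.numeric(a$n_alleles) * b$n_alleles)
}

# window tiling over the observed extent of each chromosome
tile_windows <- function(gm, size, step = size) {
  out <- list()
  for (ch in unique(gm$chrom)) {
    pmax_ <- max(gm$pos[gm$chrom == ch])
    starts <- seq(1L, pmax_, by = step)
    ends <- pmin(starts + size - 1L, pmax_)
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Tajima's D for a sample set over a set of sites
#'
#' Canonical equal-sample-size formulation applied to complete-case allele
#' counts: segregating sites whose non-missing allele count equals the modal
#' count 2n enter the statistic; sites with fewer calls are excluded. The
#' mean pairwise difference uses the exact per-site `n_diff / choose(2n, 2)`
#' ratio. Returns `NA` when no segregating site qualifies.
#'
#' @param gm a [genotype_matrix()].
#' @param samples row selector for the sample set.
#' @param sites column selector (default: all sites).
#' @return Tajima's D (numeric scalar, `NA` if undefined).
#' @export
tajimas_d <- function(gm, samples = NULL, sites = NULL) {
  if (is.null(sites)) sites <- seq_along(gm$pos)
  sub <- gm$dosage[if (is.null(samples)) TRUE else samples, sites,
                   drop = FALSE]
  called <- colSums(!is.na(sub))
  n_alt <- colSums(sub, na.rm = TRUE)
  n_all <- 2 * called
  seg <- n_alt > 0 & n_alt < n_all
  if (!any(seg)) return(NA_real_)
  counts <- n_all[seg]
  n_modal <- as.integer(names(sort(table(counts), decreasing = TRUE))[1])
  use <- seg & n_all == n_modal
  s_count <- sum(use)
  if (s_count < 1 || n_modal < 4) return(NA_real_)
  n <- n_modal
  n_ref <- n_all[use] - n_alt[use]
  pi_sum <- sum(as.numeric(n_ref) * n_alt[use]) / (n * (n - 1) / 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * s_count + e2 * s_count * (s_count - 1))
  if (denom == 0) return(NA_real_)
  (pi_sum - s_count / a1) / denom
}

#' Windowed diversity and differentiation scan
#'
#' Computes, in non-overlapping windows (default 100 kb), invariant-site
#' aware nucleotide diversity per group, absolute divergence DXY between
#' the two groups, Hudson FST as a ratio of sums over variant sites, and
#' Tajima's D per group. All pi/DXY ratios are ratio-of-sums over sites,
#' never means of per-site ratios. Window filters follow the study design:
#' pi/DXY are reported missing where the fraction of sites with at least
#' one valid comparison falls below `min_site_coverage` of the window span,
#' and FST is reported missing in windows with fewer than `min_snps`
#' variant sites. A genome-wide ratio-of-sums summary row (`chrom =
#' "genome"`) is appended.
#'
#' @param gm a [genotype_matrix()] including invariant sites (a warning is
#'   issued if none are present).
#' @param frame sample frame matching `gm`'s rows, with a `group` column of
#'   exactly two levels.
#' @param size,step window size and step in bp (default 100 kb tiling).
#' @param min_site_coverage minimum effective-site fraction of the window
#'   span for pi/DXY (default 0.10).
#' @param min_snps minimum SNP count for FST (default 20).
#' @return Data frame with one row per window plus the genome summary row:
#'   chrom, start, end, pi by group, dxy, fst, tajima_d by group,
#'   n_effective_sites, n_snps, pass_pi_dxy, pass_fst.
#' @export
scan_windows <- function(gm, frame, size = 100000L, step = size,
                         min_site_coverage = 0.10, min_snps = 20L) {
  groups <- sort(unique(frame$group))
  if (length(groups) != 2) stop("scan_windows expects exactly two groups")
  if (!any(!gm$is_variant)) {
    warning("no invariant sites present; pi and dxy will be inflated")
  }
  idx_a <- which(frame$group == groups[1])
  idx_b <- which(frame$group == groups[2])
  wa <- within_counts(gm, idx_a)
  wb <- within_counts(gm, idx_b)
  bt <- between_counts(gm, idx_a, idx_b)
  eff <- (wa$comp + wb$comp + bt$comp) > 0
  win <- tile_windows(gm, size, step)
  n_win <- nrow(win)
  res <- data.frame(
    chrom = win$chrom, start = win$start, end = win$end,
    pi_a = NA_real_, pi_b = NA_real_, dxy = NA_real_, fst = NA_real_,
    tajima_d_a = NA_real_, tajima_d_b = NA_real_,
    n_effective_sites = 0L, n_snps = 0L,
    pass_pi_dxy = FALSE, pass_fst = FALSE
  )
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  for (k in seq_len(n_win)) {
    in_win <- which(gm$chrom == win$chrom[k] &
                      gm$pos >= win$start[k] & gm$pos <= win$end[k])
    if (!length(in_win)) next
    span <- win$end[k] - win$start[k] + 1L
    n_eff <- sum(eff[in_win])
    snps <- in_win[gm$is_variant[in_win]]
    res$n_effective_sites[k] <- n_eff
    res$n_snps[k] <- length(snps)
    res$pass_pi_dxy[k] <- n_eff >= min_site_coverage * span
    res$pass_fst[k] <- length(snps) >= min_snps
    if (res$pass_pi_dxy[k]) {
      res$pi_a[k] <- ratio(sum(wa$diff[in_win]), sum(wa$comp[in_win]))
      res$pi_b[k] <- ratio(sum(wb$diff[in_win]), sum(wb$comp[in_win]))
      res$dxy[k] <- ratio(sum(bt$diff[in_win]), sum(bt$comp[in_win]))
      res$tajima_d_a[k] <- tajimas_d(gm, idx_a, in_win)
      res$tajima_d_b[k] <- tajimas_d(gm, idx_b, in_win)
    }
    if (res$pass_fst[k] && length(snps)) {
      hw <- ratio(sum(wa$diff[snps]) + sum(wb$diff[snps]),
                  sum(wa$comp[snps]) + sum(wb$comp[snps]))
      hb <- ratio(sum(bt$diff[snps]), sum(bt$comp[snps]))
      res$fst[k] <- if (!is.na(hb) && hb > 0) 1 - hw / hb else NA_real_
    }
  }
  names(res)[names(res) == "pi_a"] <- paste0("pi_", groups[1])
  names(res)[names(res) == "pi_b"] <- paste0("pi_", groups[2])
  names(res)[names(res) == "tajima_d_a"] <- paste0("tajima_d_", groups[1])
  names(res)[names(res) == "tajima_d_b"] <- paste0("tajima_d_", groups[2])
  g <- genome_stats(gm, frame)
  genome_row <- res[1, ]
  genome_row[1, ] <- NA
  genome_row$chrom <- "genome"
  genome_row[[paste0("pi_", groups[1])]] <- g$pi[1]
  genome_row[[paste0("pi_", groups[2])]] <- g$pi[2]
  genome_row$dxy <- g$dxy
  genome_row$fst <- g$fst
  genome_row$n_effective_sites <- sum(eff)
  genome_row$n_snps <- sum(gm$is_variant)
  rbind(res, genome_row)
}

#' Windowed pi and DXY only
#'
#' Convenience wrapper around [scan_windows()] returning just the
#' diversity/divergence columns (without the genome summary row).
#'
#' @inheritParams scan_windows
#' @param windows optional precomputed window table (chrom, start, end);
#'   default 100-kb tiling.
#' @return Data frame of windows with pi per group and dxy.
#' @export
window_pi_dxy <- function(gm, frame, windows = NULL, size = 100000L) {
  res <- scan_windows(gm, frame, size = size)
  res <- res[res$chrom != "genome", ]
  res[, !(names(res) %in% c("fst", "pass_fst",
                            grep("tajima", names(res), value = TRUE)))]
}

#' Windowed Hudson FST only
#'
#' @inheritParams window_pi_dxy
#' @return Data frame of windows with fst, n_snps and pass_fst.
#' @export
window_fst_hudson <- function(gm, frame, windows = NULL, size = 100000L) {
  res <- scan_windows(gm, frame, size = size)
  res <- res[res$chrom != "genome", ]
  res[, c("chrom", "start", "end", "fst", "n_snps", "pass_fst")]
}

#' Genome-wide ratio-of-sums diversity summary
#'
#' Single-pass ratio-of-sums estimates over the whole matrix: per-group
#' nucleotide diversity and between-group DXY over all sites, and Hudson
#' FST over variant sites.
#'
#' @inheritParams scan_windows
#' @return List with `pi` (named per group), `dxy` and `fst`.
#' @export
genome_stats <- function(gm, frame) {
  groups <- sort(unique(frame$group))
  if (length(groups) != 2) stop("genome_stats expects exactly two groups")
  idx_a <- which(frame$group == groups[1])
  idx_b <- which(frame$group == groups[2])
  wa <- within_counts(gm, idx_a)
  wb <- within_counts(gm, idx_b)
  bt <- between_counts(gm, idx_a, idx_b)
  snps <- gm$is_variant
  pi <- c(sum(wa$diff) / sum(wa$comp), sum(wb$diff) / sum(wb$comp))
  names(pi) <- groups
  dxy <- sum(bt$diff) / sum(bt$comp)
  hw <- (sum(wa$diff[snps]) + sum(wb$diff[snps])) /
    (sum(wa$comp[snps]) + sum(wb$comp[snps]))
  hb <- sum(bt$diff[snps]) / sum(bt$comp[snps])
  fst <- if (is.finite(hb) && hb > 0) 1 - hw / hb else NA_real_
  list(pi = pi, dxy = dxy, fst = fst)
}
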