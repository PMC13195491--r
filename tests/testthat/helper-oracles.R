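# Independent brute-force oracles. These deliberately use the slowest,
# most literal formulation of each quantity (explicit allele enumeration,
# exhaustive window scans) so they share no code path with the package.

# expand a dosage column into an explicit allele vector for a sample set
expand_alleles <- function(column, idx) {
  out <- integer(0)
  for (i in idx) {
    g <- column[i]
    if (is.na(g)) next
    out <- c(out, switch(as.character(g),
                         "0" = c(0L, 0L), "1" = c(0L, 1L), "2" = c(1L, 1L)))
  }
  out
}

# within- or cross-set difference/comparison counts by explicit pair loops
brute_site_counts <- function(column, set1, set2 = NULL) {
  a <- expand_alleles(column, set1)
  if (is.null(set2)) {
    n_diff <- 0; n_comp <- 0
    if (length(a) >= 2) {
      for (i in seq_len(length(a) - 1)) {
        for (j in (i + 1):length(a)) {
          n_comp <- n_comp + 1
          if (a[i] != a[j]) n_diff <- n_diff + 1
        }
      }
    }
  } else {
    b <- expand_alleles(column, set2)
    n_diff <- 0; n_comp <- 0
    for (x in a) for (y in b) {
      n_comp <- n_comp + 1
      if (x != y) n_diff <- n_diff + 1
    }
  }
  c(n_diff = n_diff, n_comp = n_comp)
}

# ratio-of-sums pi / dxy / hudson fst over a set of sites by enumeration
brute_genome_stats <- function(gm, idx_a, idx_b) {
  wa_d <- wa_c <- wb_d <- wb_c <- bt_d <- bt_c <- 0
  fa_d <- fa_c <- fb_d <- fb_c <- fb2_d <- fb2_c <- 0
  for (j in seq_along(gm$pos)) {
    col <- gm$dosage[, j]
    a <- brute_site_counts(col, idx_a)
    b <- brute_site_counts(col, idx_b)
    x <- brute_site_counts(col, idx_a, idx_b)
    wa_d <- wa_d + a[1]; wa_c <- wa_c + a[2]
    wb_d <- wb_d + b[1]; wb_c <- wb_c + b[2]
    bt_d <- bt_d + x[1]; bt_c <- bt_c + x[2]
    if (gm$is_variant[j]) {
      fa_d <- fa_d + a[1] + b[1]; fa_c <- fa_c + a[2] + b[2]
      fb2_d <- fb2_d + x[1]; fb2_c <- fb2_c + x[2]
    }
  }
  list(pi_a = wa_d / wa_c, pi_b = wb_d / wb_c, dxy = bt_d / bt_c,
       fst = 1 - (fa_d / fa_c) / (fb2_d / fb2_c))
}

# Tajima's D from scratch: canonical constants evaluated directly
brute_tajima <- function(alt_counts, n_alleles) {
  seg <- alt_counts > 0 & alt_counts < n_alleles
  stopifnot(length(unique(n_alleles[seg])) == 1)
  n <- n_alleles[seg][1]
  S <- sum(seg)
  pi_sum <- 0
  for (j in which(seg)) {
    pi_sum <- pi_sum + alt_counts[j] * (n - alt_counts[j]) / choose(n, 2)
  }
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# PLINK-style ROH rules by direct enumeration of every window and run
brute_roh <- function(v, pos, window_snps = 20, max_het = 1,
                      max_missing = 5, hit_threshold = 0.05, min_kb = 10,
                      min_snps = 50, max_density_kb_per_snp = 50) {
  m <- length(v)
  if (m < window_snps) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  n_win <- m - window_snps + 1
  hom <- logical(n_win)
  for (w in seq_len(n_win)) {
    g <- v[w:(w + window_snps - 1)]
    hom[w] <- sum(!is.na(g) & g == 1) <= max_het &&
      sum(is.na(g)) <= max_missing
  }
  elig <- logical(m)
  for (i in seq_len(m)) {
    wins <- intersect(seq_len(n_win), (i - window_snps + 1):i)
    elig[i] <- mean(hom[wins]) > hit_threshold
  }
  segs <- list()
  i <- 1
  while (i <= m) {
    if (elig[i]) {
      j <- i
      while (j < m && elig[j + 1]) j <- j + 1
      span_kb <- (pos[j] - pos[i]) / 1000
      n <- j - i + 1
      if (span_kb >= min_kb && n >= min_snps &&
          span_kb / n <= max_density_kb_per_snp) {
        segs[[length(segs) + 1]] <- data.frame(start = pos[i], end = pos[j])
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(segs)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, segs)
}

# ABBA/BABA sums by per-site loop
brute_abba_sums <- function(p1, p2, p3, po) {
  abba <- baba <- 0
  for (i in seq_along(p1)) {
    if (anyNA(c(p1[i], p2[i], p3[i], po[i]))) next
    q1 <- p1[i]; q2 <- p2[i]; q3 <- p3[i]; qo <- po[i]
    if (qo > 0.5) {
      q1 <- 1 - q1; q2 <- 1 - q2; q3 <- 1 - q3; qo <- 1 - qo
    }
    abba <- abba + (1 - q1) * q2 * q3 * (1 - qo)
    baba <- baba + q1 * (1 - q2) * q3 * (1 - qo)
  }
  c(abba = abba, baba = baba)
}

# haversine great-circle distance, written out from the formula
brute_haversine_km <- function(lat1, lon1, lat2, lon2, r_km = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  h <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r_km * asin(sqrt(h))
}

# quick genotype_matrix from a dosage matrix with evenly spaced sites
make_gm <- function(dosage, spacing = 1000L, chrom = "chr1",
                    is_variant = NULL, depth = NULL) {
  dosage <- as.matrix(dosage)
  genotype_matrix(dosage, rep(chrom, ncol(dosage)),
                  spacing * seq_len(ncol(dosage)),
                  is_variant = is_variant, depth = depth)
}

# two-group frame for n_a + n_b samples matching a gm's rows
make_frame <- function(gm, n_a, n_b = nrow(gm$dosage) - n_a) {
  data.frame(sample = rownames(gm$dosage),
             population = rep(c("pA", "pB"), c(n_a, n_b)),
             group = rep(c("A", "B"), c(n_a, n_b)),
             lon = rep(c(115, 135), c(n_a, n_b)),
             lat = rep(c(28, 33), c(n_a, n_b)))
}
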