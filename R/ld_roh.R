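#' LD decay curve with half-maximum decay distance
#'
#' For every intra-chromosomal pair of variant sites within `max_dist_bp`,
#' the squared Pearson correlation of dosage vectors over jointly
#' non-missing samples (the composite genotype r-squared) is computed,
#' binned by distance, and averaged per bin. The curve maximum and the
#' distance at which the curve first falls to half of that maximum
#' (linearly interpolated between bin midpoints at the first downward
#' crossing) summarize the decay.
#'
#' @param gm a [genotype_matrix()].
#' @param samples row selector for the sample set (e.g. one group).
#' @param max_dist_bp largest pair distance considered (default 100 kb).
#' @param bin_width_bp distance bin width (default 1 kb).
#' @return List of class `ld_curve`: `curve` (data frame distance_bin
#'   midpoint, mean_r2, n_pairs), `r2_max`, `half_decay_bp` (`NA` if the
#'   curve never falls below half its maximum).
#' @export
ld_decay <- function(gm, samples = NULL, max_dist_bp = 100000L,
                     bin_width_bp = 1000L) {
  var_idx <- which(gm$is_variant)
  dos <- gm$dosage[if (is.null(samples)) TRUE else samples, var_idx,
                   drop = FALSE]
  chrom <- gm$chrom[var_idx]
  pos <- gm$pos[var_idx]
  n_bins <- ceiling(max_dist_bp / bin_width_bp)
  sum_r2 <- numeric(n_bins)
  n_pairs <- integer(n_bins)
  for (ch in unique(chrom)) {
    j <- which(chrom == ch)
    if (length(j) < 2) next
    p <- pos[j]
    d <- dos[, j, drop = FALSE]
    # restrict pair enumeration to the max_dist_bp band
    r2m <- suppressWarnings(cor(d, use = "pairwise.complete.obs")^2)
    for (a in seq_len(length(j) - 1)) {
      b <- which(p > p[a] & p - p[a] <= max_dist_bp)
      b <- b[b > a]
      if (!length(b)) next
      r2 <- r2m[a, b]
      keep <- !is.na(r2)
      if (!any(keep)) next
      bins <- pmin(ceiling((p[b[keep]] - p[a]) / bin_width_bp), n_bins)
      tab <- tapply(r2[keep], bins, sum)
      cnt <- tapply(rep(1L, sum(keep)), bins, sum)
      ix <- as.integer(names(tab))
      sum_r2[ix] <- sum_r2[ix] + tab
      n_pairs[ix] <- n_pairs[ix] + cnt
    }
  }
  mids <- (seq_len(n_bins) - 0.5) * bin_width_bp
  mean_r2 <- ifelse(n_pairs > 0, sum_r2 / n_pairs, NA_real_)
  curve <- data.frame(distance_bin = mids, mean_r2 = mean_r2,
                      n_pairs = n_pairs)
  ld_curve_summary(curve)
}

# attach r2_max and half-decay distance to a binned curve
ld_curve_summary <- function(curve) {
  ok <- !is.na(curve$mean_r2)
  r2_max <- if (any(ok)) max(curve$mean_r2[ok]) else NA_real_
  half <- NA_real_
  if (any(ok) && is.finite(r2_max)) {
    x <- curve$distance_bin[ok]
    y <- curve$mean_r2[ok]
    peak <- which.max(y)
    target <- r2_max / 2
    for (i in seq_len(length(y) - 1)) {
      if (i < peak) next
      if (y[i] >= target && y[i + 1] < target) {
        half <- x[i] + (x[i + 1] - x[i]) * (y[i] - target) /
          (y[i] - y[i + 1])
        break
      }
    }
    if (is.na(half) && y[peak] < target) half <- x[peak]
  }
  structure(list(curve = curve, r2_max = r2_max, half_decay_bp = half),
            class = "ld_curve")
}

#' @export
print.ld_curve <- function(x, ...) {
  cat("LD decay curve:", sum(x$curve$n_pairs), "pairs in",
      sum(x$curve$n_pairs > 0), "bins\n")
  cat(sprintf("r2_max = %.4f; half-decay distance = %s bp\n", x$r2_max,
              format(round(x$half_decay_bp))))
  invisible(x)
}

#' Detect runs of homozygosity for one sample
#'
#' Sliding-window scan in the PLINK tradition: a window of `window_snps`
#' consecutive sites (within a chromosome) is called homozygous when it
#' contains at most `max_het` heterozygous and at most `max_missing`
#' missing calls. Each site's hit rate is the fraction of windows covering
#' it that are homozygous; sites with hit rate above `hit_threshold` are
#' ROH-eligible. Maximal runs of eligible sites become candidate segments,
#' which must then span at least `min_kb` kb, contain at least `min_snps`
#' sites, and be no sparser than one site per `max_density_kb_per_snp` kb.
#'
#' @param gm a [genotype_matrix()].
#' @param sample sample name or row index.
#' @param min_kb minimum segment span (kb).
#' @param min_snps minimum site count per segment.
#' @param max_density_kb_per_snp maximum kb of span per site.
#' @param window_snps scanning window size in sites.
#' @param max_het,max_missing window disqualification thresholds.
#' @param hit_threshold minimum hit rate for site eligibility.
#' @return Data frame of segments: sample, chrom, start, end, n_snps,
#'   n_het, n_missing (zero rows if none qualify).
#' @export
detect_roh <- function(gm, sample, min_kb = 10, min_snps = 50,
                       max_density_kb_per_snp = 50, window_snps = 20,
                       max_het = 1, max_missing = 5, hit_threshold = 0.05) {
  if (is.character(sample)) sample <- match(sample, rownames(gm$dosage))
  stopifnot(!is.na(sample))
  out <- list()
  for (ch in unique(gm$chrom)) {
    j <- which(gm$chrom == ch)
    v <- gm$dosage[sample, j]
    pos <- gm$pos[j]
    m <- length(j)
    if (m < window_snps) next
    is_het <- as.integer(!is.na(v) & v == 1L)
    is_mis <- as.integer(is.na(v))
    # windows start at 1..m-window+1; cumulative sums give window contents
    ch_cum <- c(0L, cumsum(is_het))
    mi_cum <- c(0L, cumsum(is_mis))
    n_win <- m - window_snps + 1L
    w_het <- ch_cum[(window_snps + 1):(m + 1)] - ch_cum[1:n_win]
    w_mis <- mi_cum[(window_snps + 1):(m + 1)] - mi_cum[1:n_win]
    w_hom <- as.integer(w_het <= max_het & w_mis <= max_missing)
    # per-site: windows containing site i are max(1, i-w+1) .. min(i, n_win)
    hom_cum <- c(0L, cumsum(w_hom))
    lo <- pmax(1L, seq_len(m) - window_snps + 1L)
    hi <- pmin(seq_len(m), n_win)
    n_cover <- hi - lo + 1L
    n_hit <- hom_cum[hi + 1L] - hom_cum[lo]
    eligible <- n_cover > 0 & (n_hit / n_cover) > hit_threshold
    r <- rle(eligible)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    for (seg in which(r$values)) {
      a <- starts_i[seg]; b <- ends_i[seg]
      span_kb <- (pos[b] - pos[a]) / 1000
      n <- b - a + 1L
      if (span_kb < min_kb) next
      if (n < min_snps) next
      if (span_kb / n > max_density_kb_per_snp) next
      out[[length(out) + 1]] <- data.frame(
        sample = rownames(gm$dosage)[sample], chrom = ch,
        start = pos[a], end = pos[b], n_snps = n,
        n_het = sum(is_het[a:b]), n_missing = sum(is_mis[a:b])
      )
    }
  }
  if (!length(out)) {
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), n_het = integer(0),
                      n_missing = integer(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# merge overlapping intervals within sample x chrom, warning when needed
merge_segments <- function(segments) {
  if (!nrow(segments)) return(segments)
  pieces <- split(segments, paste(segments$sample, segments$chrom))
  merged_any <- FALSE
  out <- lapply(pieces, function(s) {
    s <- s[order(s$start), ]
    keep <- s[1, , drop = FALSE]
    for (i in seq_len(nrow(s))[-1]) {
      last <- nrow(keep)
      if (s$start[i] <= keep$end[last]) {
        keep$end[last] <- max(keep$end[last], s$end[i])
        merged_any <<- TRUE
      } else {
        keep <- rbind(keep, s[i, ])
      }
    }
    keep
  })
  if (merged_any) warning("overlapping ROH segments merged")
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Inbreeding coefficient from runs of homozygosity
#'
#' FROH = total ROH length / Lauto, where Lauto defaults to the physical
#' span covered by sites (first to last site per chromosome, summed) —
#' the genome extent a SNP panel can actually interrogate.
#'
#' @param segments output of [detect_roh()], possibly for many samples.
#' @param lauto_bp denominator in bp; computed from `gm` when `NULL`.
#' @param gm the [genotype_matrix()] used for detection (needed when
#'   `lauto_bp` is `NULL`, and for the sample universe).
#' @return Data frame: sample, froh, total_roh_bp, lauto_bp. Samples with
#'   no segments get froh 0.
#' @export
f_roh <- function(segments, lauto_bp = NULL, gm = NULL) {
  if (is.null(lauto_bp)) {
    if (is.null(gm)) stop("either lauto_bp or gm must be given")
    lauto_bp <- sum(vapply(unique(gm$chrom), function(ch) {
      p <- gm$pos[gm$chrom == ch]
      max(p) - min(p) + 1
    }, numeric(1)))
  }
  stopifnot(lauto_bp > 0)
  samples <- if (!is.null(gm)) rownames(gm$dosage)
             else unique(segments$sample)
  segments <- merge_segments(segments)
  total <- vapply(samples, function(s) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    if (!nrow(seg)) 0 else sum(seg$end - seg$start + 1)
  }, numeric(1))
  data.frame(sample = samples, froh = total / lauto_bp,
             total_roh_bp = total, lauto_bp = lauto_bp,
             row.names = NULL)
}
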