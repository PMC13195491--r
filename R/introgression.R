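#' Frequency-based ABBA-BABA D statistic for one trio
#'
#' Population formulation of the four-taxon test. Sites are polarized by
#' the outgroup: where the outgroup alternate-allele frequency exceeds 0.5
#' all four frequencies are flipped, so the outgroup carries the ancestral
#' allele. Sites with a missing frequency in any member are skipped. Then
#' `abba = sum (1-p1) p2 p3 (1-pout)` and
#' `baba = sum p1 (1-p2) p3 (1-pout)`, and
#' `d = (abba - baba) / (abba + baba)`.
#'
#' @param p1,p2,p3,pout per-site alternate-allele frequencies of the trio
#'   populations and the outgroup (equal-length numeric vectors).
#' @param labels optional character vector of length 4 naming p1, p2, p3
#'   and the outgroup.
#' @return List of class `trio_result`: `d`, `abba_sum`, `baba_sum`,
#'   per-site `abba`/`baba` vectors (for jackknifing), `n_sites_used`, and
#'   the labels. `d` is `NA` when `abba + baba` is zero.
#' @export
d_statistic <- function(p1, p2, p3, pout, labels = c("P1", "P2", "P3", "O")) {
  stopifnot(length(p1) == length(p2), length(p2) == length(p3),
            length(p3) == length(pout))
  ok <- is.finite(p1) & is.finite(p2) & is.finite(p3) & is.finite(pout)
  flip <- ok & pout > 0.5
  p1[flip] <- 1 - p1[flip]
  p2[flip] <- 1 - p2[flip]
  p3[flip] <- 1 - p3[flip]
  pout[flip] <- 1 - pout[flip]
  abba <- ifelse(ok, (1 - p1) * p2 * p3 * (1 - pout), 0)
  baba <- ifelse(ok, p1 * (1 - p2) * p3 * (1 - pout), 0)
  tot <- sum(abba) + sum(baba)
  structure(list(
    p1 = labels[1], p2 = labels[2], p3 = labels[3], outgroup = labels[4],
    d = if (tot > 0) (sum(abba) - sum(baba)) / tot else NA_real_,
    abba_sum = sum(abba), baba_sum = sum(baba),
    abba = abba, baba = baba, n_sites_used = sum(ok)
  ), class = "trio_result")
}

#' @export
print.trio_result <- function(x, ...) {
  cat(sprintf("D(%s, %s; %s | %s) = %.4f  (ABBA %.2f, BABA %.2f, %d sites)\n",
              x$p1, x$p2, x$p3, x$outgroup, x$d, x$abba_sum, x$baba_sum,
              x$n_sites_used))
  if (!is.null(x$z)) cat(sprintf("block-jackknife Z = %.2f (%d blocks)\n",
                                 x$z, x$n_blocks))
  invisible(x)
}

#' Block-jackknife Z score for a D statistic
#'
#' Contiguous blocks of `block_size_sites` sites are deleted one at a time;
#' the jackknife standard error is
#' `sqrt((m-1)/m * sum((d_(-j) - mean(d_(-j)))^2))` over the m blocks, and
#' `z = d / SE`. Requires at least 20 blocks for a usable error estimate.
#'
#' @param trio a `trio_result` from [d_statistic()] (with per-site sums).
#' @param block_size_sites sites per block (default 500).
#' @return The `trio_result` with `z`, `se` and `n_blocks` added; `z` is
#'   `NA` when the jackknife SE is zero.
#' @export
jackknife_z <- function(trio, block_size_sites = 500L) {
  n <- length(trio$abba)
  m <- floor(n / block_size_sites)
  if (m * block_size_sites < n) m <- m + 1L
  if (m < 20) stop("need at least 20 jackknife blocks; got ", m)
  block <- pmin(ceiling(seq_len(n) / block_size_sites), m)
  abba_b <- tapply(trio$abba, block, sum)
  baba_b <- tapply(trio$baba, block, sum)
  A <- sum(abba_b); B <- sum(baba_b)
  d_del <- vapply(seq_len(m), function(j) {
    a <- A - abba_b[j]; b <- B - baba_b[j]
    if (a + b > 0) (a - b) / (a + b) else NA_real_
  }, numeric(1))
  if (anyNA(d_del)) {
    trio$z <- NA_real_; trio$se <- NA_real_; trio$n_blocks <- m
    return(trio)
  }
  se <- sqrt((m - 1) / m * sum((d_del - mean(d_del))^2))
  trio$se <- se
  trio$z <- if (se > 0) trio$d / se else NA_real_
  trio$n_blocks <- m
  trio
}

#' All-trio D table and signed heatmap matrix
#'
#' Runs [d_statistic()] (plus [jackknife_z()] when enough sites) over every
#' ordered-by-convention trio from a set of populations against one
#' outgroup. Within each trio, P1 and P2 are arranged so that D is
#' non-negative (a swap is recorded). For the heatmap matrix, each trio
#' deposits +D in cell (P2, P3) and -D in cell (P1, P3); where several
#' trios hit the same cell, the entry with the largest |D| is retained.
#'
#' @param freq populations x sites frequency matrix (e.g. from
#'   [population_frequencies()]); row names are population labels.
#' @param outgroup label of the outgroup row in `freq`.
#' @param pops populations to use (default: all rows except the outgroup),
#'   also fixing the matrix ordering.
#' @param block_size_sites jackknife block size; Z is skipped when fewer
#'   than 20 blocks are available.
#' @return List with `table` (one row per trio: P1, P2, P3, D, Z, swapped)
#'   and `matrix` (square signed-D matrix over `pops`).
#' @export
trio_table <- function(freq, outgroup, pops = NULL,
                       block_size_sites = 500L) {
  if (is.null(pops)) pops <- setdiff(rownames(freq), outgroup)
  stopifnot(outgroup %in% rownames(freq), all(pops %in% rownames(freq)))
  trios <- combn(pops, 3)
  mat <- matrix(0, length(pops), length(pops),
                dimnames = list(pops, pops))
  rows <- list()
  n_sites <- ncol(freq)
  can_z <- floor(n_sites / block_size_sites) >= 20
  for (k in seq_len(ncol(trios))) {
    tr <- trios[, k]
    res <- d_statistic(freq[tr[1], ], freq[tr[2], ], freq[tr[3], ],
                       freq[outgroup, ], labels = c(tr, outgroup))
    swapped <- FALSE
    if (!is.na(res$d) && res$d < 0) {
      res <- d_statistic(freq[tr[2], ], freq[tr[1], ], freq[tr[3], ],
                         freq[outgroup, ], labels = c(tr[2], tr[1], tr[3],
                                                      outgroup))
      swapped <- TRUE
    }
    if (can_z) res <- jackknife_z(res, block_size_sites)
    rows[[k]] <- data.frame(
      p1 = res$p1, p2 = res$p2, p3 = res$p3, outgroup = outgroup,
      d = res$d, z = if (is.null(res$z)) NA_real_ else res$z,
      n_blocks = if (is.null(res$n_blocks)) NA_integer_ else res$n_blocks,
      swapped = swapped
    )
    if (!is.na(res$d)) {
      if (abs(res$d) > abs(mat[res$p2, res$p3])) {
        mat[res$p2, res$p3] <- res$d
      }
      if (abs(res$d) > abs(mat[res$p1, res$p3])) {
        mat[res$p1, res$p3] <- -res$d
      }
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       matrix = mat)
}
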