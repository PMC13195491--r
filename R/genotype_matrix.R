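#' Genotype matrix container
#'
#' The substrate of every statistic in the package: a samples x sites matrix
#' of allele dosages (0, 1, 2 or `NA` for missing), together with per-site
#' chromosome labels, 1-based positions, an invariant-site flag, and an
#' optional per-genotype sequencing depth matrix.
#'
#' @param dosage integer matrix, samples in rows, sites in columns; entries
#'   must be 0, 1, 2 or `NA`. Row names are sample IDs.
#' @param chrom character vector of per-site chromosome labels.
#' @param pos integer vector of 1-based per-site positions, strictly
#'   increasing within each chromosome.
#' @param is_variant logical vector; `FALSE` marks sites known to be
#'   monomorphic (invariant). Defaults to flagging columns that segregate.
#' @param depth optional integer matrix of per-genotype depths, same
#'   dimensions as `dosage`.
#' @param biallelic optional logical vector; `FALSE` marks sites whose VCF
#'   record carried more than one alternate allele (their dosages are all
#'   missing and they are removed by [filter_variants()]). Defaults to all
#'   `TRUE`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `chrom`, `pos`, `is_variant`, `depth` and `biallelic`.
#' @export
genotype_matrix <- function(dosage, chrom, pos, is_variant = NULL,
                            depth = NULL, biallelic = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n_sites <- ncol(dosage)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (length(chrom) != n_sites || length(pos) != n_sites) {
    stop("chrom and pos must have one entry per site")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0L)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  if (is.null(is_variant)) {
    is_variant <- apply(dosage, 2, function(col) {
      v <- col[!is.na(col)]
      length(v) > 0L && any(v != v[1L])
    })
  }
  is_variant <- as.logical(is_variant)
  if (length(is_variant) != n_sites) {
    stop("is_variant must have one entry per site")
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!identical(dim(depth), dim(dosage))) {
      stop("depth must match dosage dimensions")
    }
  }
  if (is.null(biallelic)) biallelic <- rep(TRUE, n_sites)
  biallelic <- as.logical(biallelic)
  if (length(biallelic) != n_sites) {
    stop("biallelic must have one entry per site")
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  }
  structure(
    list(dosage = dosage, chrom = chrom, pos = pos,
         is_variant = is_variant, depth = depth, biallelic = biallelic),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "sites (", sum(x$is_variant), "variant )\n")
  cat("chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample index (integer, logical or character row selector).
#' @param sites site index (integer or logical column selector).
#' @return A `genotype_matrix` restricted to the selection.
#' @export
gm_subset <- function(gm, samples = NULL, sites = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(gm$dosage))
  if (is.null(sites)) sites <- seq_len(ncol(gm$dosage))
  genotype_matrix(
    dosage = gm$dosage[samples, sites, drop = FALSE],
    chrom = gm$chrom[sites],
    pos = gm$pos[sites],
    is_variant = gm$is_variant[sites],
    depth = if (!is.null(gm$depth)) gm$depth[samples, sites, drop = FALSE],
    biallelic = gm$biallelic[sites]
  )
}

#' Per-site allele counts for a set of samples
#'
#' Counts reference and alternate alleles among non-missing genotypes,
#' column by column. The workhorse behind the diversity estimators and
#' population allele frequencies.
#'
#' @param gm a [genotype_matrix()].
#' @param samples row selector (default: all samples).
#' @return A list with integer vectors `n_ref`, `n_alt` and `n_alleles`
#'   (= `n_ref + n_alt`), one entry per site.
#' @export
allele_counts <- function(gm, samples = NULL) {
  d <- if (is.null(samples)) gm$dosage else gm$dosage[samples, , drop = FALSE]
  called <- !is.na(d)
  n_alt <- colSums(d, na.rm = TRUE)
  n_alleles <- 2L * colSums(called)
  list(n_ref = as.integer(n_alleles - n_alt),
       n_alt = as.integer(n_alt),
       n_alleles = as.integer(n_alleles))
}

#' Population allele frequencies (alternate allele)
#'
#' @param gm a [genotype_matrix()].
#' @param frame a sample frame (see [read_tables()]) mapping samples to
#'   populations; row order must match `gm`.
#' @return A populations x sites matrix of alternate-allele frequencies
#'   (`NaN` where a population has no calls at a site).
#' @export
population_frequencies <- function(gm, frame) {
  pops <- unique(frame$population)
  out <- matrix(NA_real_, nrow = length(pops), ncol = ncol(gm$dosage),
                dimnames = list(pops, NULL))
  for (p in pops) {
    idx <- which(frame$population == p)
    ac <- allele_counts(gm, idx)
    out[p, ] <- ac$n_alt / ac$n_alleles
  }
  out
}
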