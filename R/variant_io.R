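#' Read a multi-sample VCF into a genotype matrix
#'
#' Decodes GT (phased or unphased) into allele dosages; half calls and
#' `./.` become missing. Records with ALT `.` — or where no alternate
#' allele is observed among the calls — are flagged invariant. The DP
#' format field, when present, fills the depth matrix.
#'
#' @param path path to a VCF 4.x file (gzip-transparent via vcfR).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  alt <- fix[, "ALT"]
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) {
    stop("duplicate positions in VCF: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  biallelic <- !grepl(",", alt)
  gt <- vcfR::extract.gt(v, element = "GT")
  # dosage decoding: count '1' alleles; any '.' allele -> missing;
  # genotypes carrying an allele index > 1 (multiallelic record) -> missing
  code <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow(code), ncol(code),
                dimnames = dimnames(code))
  ok <- !is.na(code)
  vals <- code[ok]
  decoded <- rep(NA_integer_, length(vals))
  decoded[vals %in% c("0/0", "0")] <- 0L
  decoded[vals %in% c("0/1", "1/0")] <- 1L
  decoded[vals %in% c("1/1", "1")] <- 2L
  known <- grepl("^[0-9.](/[0-9.])?$", vals)
  if (!all(known)) {
    bad_idx <- which(ok)[which(!known)[1]]
    bad_rec <- ((bad_idx - 1) %% nrow(code)) + 1
    stop("malformed GT at record ", bad_rec,
         " (", chrom[bad_rec], ":", pos[bad_rec], "): ",
         vals[which(!known)[1]])
  }
  dos[ok] <- decoded
  dos <- t(dos) # vcfR is sites x samples; we keep samples x sites
  depth <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth <- t(dp)
    storage.mode(depth) <- "integer"
  }
  called <- colSums(!is.na(dos))
  alt_count <- colSums(dos, na.rm = TRUE)
  is_var <- alt != "." & !is.na(alt) & alt_count > 0 &
    alt_count < 2 * called
  genotype_matrix(dos, chrom, pos, is_variant = is_var, depth = depth,
                  biallelic = biallelic)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits GT:DP records (DP omitted if the matrix has no depth); invariant
#' sites are written with ALT `.`. Output is deterministic: identical input
#' gives identical bytes.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  n_samp <- nrow(gm$dosage)
  samples <- rownames(gm$dosage)
  has_dp <- !is.null(gm$depth)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=oakscape",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp)
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_along(gm$pos), function(j) {
    col <- gm$dosage[, j]
    g <- ifelse(is.na(col), "./.", gt_code[col + 1L])
    if (has_dp) g <- paste0(g, ":", gm$depth[, j])
    # invariant ref-fixed records get ALT "."; invariant alt-fixed columns
    # keep an explicit ALT (the reader re-flags all-alt columns invariant)
    v <- col[!is.na(col)]
    alt_fixed <- !gm$is_variant[j] && length(v) && v[1] == 2L
    alt <- if (gm$is_variant[j] || alt_fixed) "T" else "."
    paste(c(gm$chrom[j], gm$pos[j], ".", "A", alt, ".", "PASS", ".",
            if (has_dp) "GT:DP" else "GT", g), collapse = "\t")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Apply the study's variant filters
#'
#' Genotype-level first: calls with depth outside `[min_dp, max_dp]` are set
#' missing. Then site-level: non-biallelic sites dropped (a dosage matrix is
#' biallelic by construction, so this only drops sites that became entirely
#' missing), sites with missing-call fraction above `1 - max_missing`
#' dropped, and variant sites with minor-allele frequency strictly below
#' `maf` dropped (computed on non-missing alleles; sites at exactly the
#' threshold are retained). Invariant sites are exempt from the MAF rule.
#'
#' @param gm a [genotype_matrix()].
#' @param min_dp,max_dp per-genotype depth bounds (default 5 and 50);
#'   ignored with a warning if the matrix carries no depth.
#' @param max_missing minimum call-rate to keep a site, VCFtools-style:
#'   0.8 keeps sites with at most 20 percent missing calls.
#' @param maf minor-allele-frequency threshold (default 0.05).
#' @param biallelic_only kept for interface completeness; dosage input is
#'   always biallelic.
#' @return A filtered `genotype_matrix` (possibly with zero sites, with a
#'   warning).
#' @export
filter_variants <- function(gm, min_dp = 5, max_dp = 50, max_missing = 0.8,
                            maf = 0.05, biallelic_only = TRUE) {
  stopifnot(max_missing >= 0, max_missing <= 1, maf >= 0, maf <= 0.5)
  dos <- gm$dosage
  if (!is.null(min_dp) || !is.null(max_dp)) {
    if (is.null(gm$depth)) {
      warning("no depth in genotype matrix; depth filters skipped")
    } else {
      bad <- (!is.na(gm$depth)) &
        (gm$depth < min_dp | gm$depth > max_dp)
      dos[bad] <- NA_integer_
    }
  }
  n_samp <- nrow(dos)
  called <- colSums(!is.na(dos))
  miss_frac <- 1 - called / n_samp
  keep <- miss_frac <= (1 - max_missing) & called > 0
  if (biallelic_only) keep <- keep & gm$biallelic
  alt <- colSums(dos, na.rm = TRUE)
  freq <- ifelse(called > 0, alt / (2 * called), NA_real_)
  m_af <- pmin(freq, 1 - freq)
  still_variant <- gm$is_variant & !is.na(freq) & freq > 0 & freq < 1
  keep <- keep & (!still_variant | m_af >= maf)
  # sites flagged variant that lost all polymorphism to depth-masking stay,
  # reclassified as invariant
  if (!any(keep)) warning("all sites removed by filters")
  genotype_matrix(dos[, keep, drop = FALSE], gm$chrom[keep], gm$pos[keep],
                  is_variant = still_variant[keep],
                  depth = if (!is.null(gm$depth))
                    gm$depth[, keep, drop = FALSE],
                  biallelic = gm$biallelic[keep])
}

# r^2 between two dosage columns over jointly non-missing samples
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' Greedy window-based LD pruning
#'
#' PLINK-style `--indep-pairwise` pruning: within each window of
#' `window_snps` variant sites, while any retained pair has r-squared above
#' `r2_max`, the member of the currently worst (highest r-squared) pair with
#' the smaller non-missing count is removed (ties: the larger site index).
#' The window then slides by `step_snps`; a site removed in any window stays
#' removed.
#'
#' @param gm a [genotype_matrix()]; only variant sites are considered.
#' @param window_snps,step_snps,r2_max window size, step and r-squared
#'   ceiling; defaults 50, 10, 0.2.
#' @return Integer vector of retained site indices (into `gm`'s columns),
#'   in increasing order. Invariant sites are never part of the result.
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 10, r2_max = 0.2) {
  var_idx <- which(gm$is_variant)
  n <- length(var_idx)
  if (n == 0) return(integer(0))
  removed <- logical(n)
  n_called <- colSums(!is.na(gm$dosage[, var_idx, drop = FALSE]))
  starts <- seq(1L, max(1L, n), by = step_snps)
  starts <- starts[starts <= n]
  for (s in starts) {
    win <- s:min(s + window_snps - 1L, n)
    win <- win[!removed[win]]
    if (length(win) < 2) next
    dos <- gm$dosage[, var_idx[win], drop = FALSE]
    r2 <- suppressWarnings(cor(dos, use = "pairwise.complete.obs")^2)
    diag(r2) <- NA
    repeat {
      alive <- which(!removed[win])
      if (length(alive) < 2) break
      sub <- r2[alive, alive, drop = FALSE]
      worst <- suppressWarnings(max(sub, na.rm = TRUE))
      if (!is.finite(worst) || worst <= r2_max) break
      hit <- which(sub == worst, arr.ind = TRUE)[1, ]
      a <- win[alive[hit[1]]]
      b <- win[alive[hit[2]]]
      ca <- n_called[a]; cb <- n_called[b]
      drop_local <- if (ca < cb) a else if (cb < ca) b else max(a, b)
      removed[drop_local] <- TRUE
    }
  }
  var_idx[!removed]
}

#' Read sample metadata and environment tables
#'
#' Metadata CSV must carry columns sample, population, group, lon, lat;
#' the environment CSV is long-by-horizon with columns population, horizon
#' and the six bioclimatic variables. Cross-checks both against the
#' genotype sample list when one is supplied.
#'
#' @param metadata_path,env_path CSV paths.
#' @param gm optional [genotype_matrix()] whose samples must all appear in
#'   the metadata.
#' @param env_vars required environment variables.
#' @return A list with `frame` (metadata data frame, ordered to match `gm`
#'   when given) and `env` (environment data frame).
#' @export
read_tables <- function(metadata_path, env_path = NULL, gm = NULL,
                        env_vars = c("bio5", "bio8", "bio9", "bio12",
                                     "bio15", "bio17")) {
  frame <- read.csv(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample", "population", "group", "lon", "lat")
  miss <- setdiff(need, names(frame))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(abs(frame$lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(frame$lon) > 180)) stop("longitude outside [-180, 180]")
  if (anyDuplicated(frame$sample)) stop("duplicate sample IDs in metadata")
  if (!is.null(gm)) {
    absent <- setdiff(rownames(gm$dosage), frame$sample)
    if (length(absent)) {
      stop("sample(s) in VCF absent from metadata: ",
           paste(absent, collapse = ", "))
    }
    frame <- frame[match(rownames(gm$dosage), frame$sample), ]
    rownames(frame) <- NULL
  }
  env <- NULL
  if (!is.null(env_path)) {
    env <- read.csv(env_path, stringsAsFactors = FALSE)
    if (!all(c("population", "horizon") %in% names(env))) {
      stop("environment table needs population and horizon columns")
    }
    for (v in env_vars) {
      if (!v %in% names(env)) stop("environment table missing variable ", v)
      bad <- env$population[env$horizon == "present" &
                              !is.finite(env[[v]])]
      if (length(bad)) {
        stop("missing present-day ", v, " for population(s): ",
             paste(bad, collapse = ", "))
      }
    }
    pops <- unique(frame$population)
    absent <- setdiff(pops, env$population[env$horizon == "present"])
    if (length(absent)) {
      stop("population(s) missing from environment table: ",
           paste(absent, collapse = ", "))
    }
  }
  list(frame = frame, env = env)
}

#' Environment table in wide (population x variable) form
#'
#' @param env long-by-horizon environment data frame.
#' @param horizon horizon label to extract.
#' @param vars variables wanted (default: all bio columns present).
#' @return Numeric matrix, populations in rows.
#' @export
env_wide <- function(env, horizon = "present", vars = NULL) {
  sub <- env[env$horizon == horizon, , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows for horizon ", horizon)
  if (is.null(vars)) vars <- grep("^bio", names(env), value = TRUE)
  m <- as.matrix(sub[, vars, drop = FALSE])
  rownames(m) <- sub$population
  m
}
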