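#' Simulation configuration
#'
#' Parameters of the hierarchical Balding-Nichols generator used to build
#' genotype, metadata and environment fixtures with known ground truth.
#' Defaults emulate the sampling design of a two-lineage oak system: two
#' deeply diverged groups (continental vs. insular) with within-group
#' population substructure, admixed contact populations, environment-linked
#' loci, distance-decaying linkage disequilibrium and plantable autozygous
#' tracts.
#'
#' @param n_groups number of top-level groups (fixed at 2).
#' @param n_pops_per_group populations per group.
#' @param n_samples_per_pop diploid samples per population.
#' @param n_sites total number of sites (variant + invariant).
#' @param invariant_fraction fraction of sites forced monomorphic; the
#'   default 0.85 mirrors the share of non-polymorphic sites in an
#'   all-sites resequencing call set.
#' @param f_group Balding-Nichols drift parameter between groups; the
#'   expected Hudson FST between the two groups. Default 0.03, the scale of
#'   differentiation between the two lineages.
#' @param f_pop within-group drift parameter (population substructure).
#' @param n_adaptive number of environment-linked (cline) loci.
#' @param beta_env per-adaptive-locus slope on the logit-frequency scale,
#'   per standard-deviation unit of the driving environmental variable.
#' @param env_var name of the bioclimatic variable driving the clines.
#' @param admix_pops named numeric vector: for each named population, the
#'   mixture weight w in `[0,1]` on group A frequencies
#'   (p = w * pA + (1 - w) * pB), applied before genotype draws. The default
#'   plants two contact populations, one on each side of the divide.
#' @param ld_decay_bp characteristic length (bp) of the haplotype
#'   copying-chain correlation; default 10 kb, the scale of observed LD
#'   half-decay distances.
#' @param roh_plants data frame (sample, chrom, start, end) of autozygous
#'   tracts to force homozygous, or `NULL`.
#' @param missing_rate per-genotype missingness, uniform at random.
#' @param mean_depth Poisson mean of per-genotype sequencing depth.
#' @param n_chrom number of chromosomes; sites are split evenly.
#' @param site_spacing_bp fixed inter-site distance in bp.
#' @param seed integer seed; identical config and seed give bit-identical
#'   output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 2L,
                       n_pops_per_group = 10L,
                       n_samples_per_pop = 5L,
                       n_sites = 5000L,
                       invariant_fraction = 0.85,
                       f_group = 0.03,
                       f_pop = 0.01,
                       n_adaptive = 50L,
                       beta_env = 1.5,
                       env_var = "bio12",
                       admix_pops = c(A10 = 0.7, B1 = 0.3),
                       ld_decay_bp = 10000,
                       roh_plants = NULL,
                       missing_rate = 0.05,
                       mean_depth = 20,
                       n_chrom = 2L,
                       site_spacing_bp = 1000L,
                       seed = 1L) {
  if (n_groups != 2L) stop("the generator models exactly two groups")
  stopifnot(
    n_pops_per_group >= 1, n_samples_per_pop >= 1, n_sites >= 1,
    invariant_fraction >= 0, invariant_fraction <= 1,
    f_group > 0, f_group < 1, f_pop > 0, f_pop < 1,
    n_adaptive >= 0, missing_rate >= 0, missing_rate <= 1,
    ld_decay_bp >= 0, mean_depth > 0, n_chrom >= 1, site_spacing_bp >= 1
  )
  n_variant <- n_sites - round(n_sites * invariant_fraction)
  adaptive_default <- missing(n_adaptive)
  if (n_adaptive > n_variant) {
    if (!adaptive_default) stop("n_adaptive exceeds the number of variant sites")
    n_adaptive <- n_variant # default count scaled down for small designs
  }
  if (missing(admix_pops)) {
    # default contact populations only exist in sufficiently large designs
    pops <- c(paste0("A", seq_len(n_pops_per_group)),
              paste0("B", seq_len(n_pops_per_group)))
    admix_pops <- admix_pops[names(admix_pops) %in% pops]
  }
  if (length(admix_pops) && (any(admix_pops < 0) || any(admix_pops > 1))) {
    stop("admixture weights must lie in [0, 1]")
  }
  if (!is.null(roh_plants)) {
    roh_plants <- as.data.frame(roh_plants)
    stopifnot(all(c("sample", "chrom", "start", "end") %in% names(roh_plants)))
  }
  cfg <- list(
    n_groups = as.integer(n_groups),
    n_pops_per_group = as.integer(n_pops_per_group),
    n_samples_per_pop = as.integer(n_samples_per_pop),
    n_sites = as.integer(n_sites),
    invariant_fraction = invariant_fraction,
    f_group = f_group, f_pop = f_pop,
    n_adaptive = as.integer(n_adaptive),
    beta_env = beta_env, env_var = env_var,
    admix_pops = admix_pops,
    ld_decay_bp = ld_decay_bp,
    roh_plants = roh_plants,
    missing_rate = missing_rate,
    mean_depth = mean_depth,
    n_chrom = as.integer(n_chrom),
    site_spacing_bp = as.integer(site_spacing_bp),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

sim_site_map <- function(config) {
  n <- config$n_sites
  per <- rep(n %/% config$n_chrom, config$n_chrom)
  if (n %% config$n_chrom) {
    per[seq_len(n %% config$n_chrom)] <- per[seq_len(n %% config$n_chrom)] + 1L
  }
  chrom <- rep(paste0("chr", seq_len(config$n_chrom)), per)
  pos <- unlist(lapply(per, function(k) config$site_spacing_bp * seq_len(k)))
  list(chrom = chrom, pos = as.integer(pos))
}

#' Sample metadata for a simulated design
#'
#' Populations of group A are placed in a continental coordinate box and
#' group B in an insular box east of it, so that geographic distance
#' correlates with group membership (isolation by distance is built in).
#'
#' @param config a [sim_config()].
#' @return A data frame (sample, population, group, lon, lat).
#' @export
simulate_metadata <- function(config) {
  set.seed(config$seed + 11L)
  pops_a <- paste0("A", seq_len(config$n_pops_per_group))
  pops_b <- paste0("B", seq_len(config$n_pops_per_group))
  place <- function(pops, lon_range, lat_range) {
    # pops ordered west-to-east inside the box so contact pops sit nearest
    # the divide
    lon <- sort(runif(length(pops), lon_range[1], lon_range[2]))
    lat <- runif(length(pops), lat_range[1], lat_range[2])
    data.frame(population = pops, lon = lon, lat = lat)
  }
  pop_tab <- rbind(
    cbind(place(pops_a, c(108, 122), c(24, 32)), group = "A"),
    cbind(place(pops_b, c(126, 140), c(31, 36)), group = "B")
  )
  frame <- do.call(rbind, lapply(seq_len(nrow(pop_tab)), function(i) {
    data.frame(
      sample = paste0(pop_tab$population[i], "_s",
                      seq_len(config$n_samples_per_pop)),
      population = pop_tab$population[i],
      group = pop_tab$group[i],
      lon = pop_tab$lon[i],
      lat = pop_tab$lat[i]
    )
  }))
  rownames(frame) <- NULL
  frame
}

#' Bioclimatic environment table for a simulated design
#'
#' Generates six bioclimatic variables (bio5, bio8, bio9, bio12, bio15,
#' bio17) per population for the present and two future horizons. Values
#' follow latitudinal/longitudinal gradients with noise; bio17 is built as a
#' near-affine function of bio12 (correlation above 0.8) so the
#' collinearity filter always has work to do. Future shifts under SSP585 are
#' exactly 2.5 times the SSP126 shifts, pop by pop, making vulnerability
#' monotone in emissions by construction.
#'
#' @param config a [sim_config()].
#' @param frame output of [simulate_metadata()].
#' @return A long-by-horizon data frame with columns `population`,
#'   `horizon` (one of `present`, `SSP126_2081_2100`, `SSP585_2081_2100`)
#'   and the six variables.
#' @export
simulate_env <- function(config, frame) {
  set.seed(config$seed + 23L)
  pops <- unique(frame$population)
  lat <- frame$lat[match(pops, frame$population)]
  lon <- frame$lon[match(pops, frame$population)]
  n <- length(pops)
  # present-day values: mild latitudinal trends plus dominant local noise,
  # loosely on real bioclim scales (degC, mm). Spatial trends are kept weak
  # so environment is largely orthogonal to the two-group structure — the
  # regime of weak isolation-by-environment with a small env/geo confounded
  # fraction that motivates conditioning analyses in the first place.
  bio5 <- 36 - 0.2 * (lat - 24) + rnorm(n, 0, 1.5)
  bio8 <- 25 - 0.2 * (lat - 24) + rnorm(n, 0, 1.5)
  bio9 <- 7 - 0.25 * (lat - 24) + rnorm(n, 0, 2.0)
  bio12 <- 1650 - 8 * (lat - 24) + rnorm(n, 0, 150)
  bio15 <- 55 + 0.3 * (lat - 24) + rnorm(n, 0, 5)
  bio17 <- 0.08 * bio12 + rnorm(n, 0, 5) # planted collinear pair with bio12
  present <- data.frame(population = pops, horizon = "present",
                        bio5 = bio5, bio8 = bio8, bio9 = bio9,
                        bio12 = bio12, bio15 = bio15, bio17 = bio17)
  # per-population SSP126 shifts; SSP585 = 2.5 x the same shift
  d5 <- rnorm(n, 1.2, 0.2)
  d8 <- rnorm(n, 1.0, 0.2)
  d9 <- rnorm(n, 1.4, 0.25)
  d12 <- rnorm(n, -60, 15)
  d15 <- rnorm(n, 2.5, 0.5)
  d17 <- rnorm(n, -10, 2.5)
  shift <- cbind(bio5 = d5, bio8 = d8, bio9 = d9,
                 bio12 = d12, bio15 = d15, bio17 = d17)
  future <- function(label, mult) {
    out <- present
    out$horizon <- label
    out[, colnames(shift)] <- out[, colnames(shift)] + mult * shift
    out
  }
  env <- rbind(present,
               future("SSP126_2081_2100", 1),
               future("SSP585_2081_2100", 2.5))
  rownames(env) <- NULL
  env
}

#' Simulate population allele frequencies (hierarchical Balding-Nichols)
#'
#' Ancestral frequencies p0 ~ Uniform(0.05, 0.95) per variant site; group
#' frequencies drawn from Beta(p0(1-F)/F, (1-p0)(1-F)/F) with F = `f_group`;
#' population frequencies nested likewise around their group frequency with
#' `f_pop`. Adaptive sites receive a logit-scale shift
#' `beta_env * z(env_pop)`; admixed populations mix the two group
#' frequencies before any genotype draw. Invariant sites are fixed at 0 or 1.
#'
#' @param config a [sim_config()].
#' @return A list with elements `p_pop` (populations x sites frequency
#'   matrix), `p_group` (2 x sites), `p0` (ancestral frequencies — usable
#'   as a perfectly polarizing outgroup), `truth` (ground-truth record:
#'   adaptive site ids, slopes, admixture weights, planted tracts, drift
#'   parameters), `site` (chrom/pos/is_variant), `frame` and `env`.
#' @export
simulate_frequencies <- function(config) {
  frame <- simulate_metadata(config)
  env <- simulate_env(config, frame)
  set.seed(config$seed)
  n_sites <- config$n_sites
  n_inv <- as.integer(round(n_sites * config$invariant_fraction))
  is_variant <- rep(TRUE, n_sites)
  if (n_inv > 0) {
    is_variant[sample.int(n_sites, n_inv)] <- FALSE
  }
  pops <- unique(frame$population)
  groups <- frame$group[match(pops, frame$population)]
  n_pop <- length(pops)

  p0 <- runif(n_sites, 0.05, 0.95)
  bn_draw <- function(p, f) {
    rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  p_group <- rbind(A = bn_draw(p0, config$f_group),
                   B = bn_draw(p0, config$f_group))
  p_pop <- matrix(NA_real_, n_pop, n_sites, dimnames = list(pops, NULL))
  for (i in seq_len(n_pop)) {
    p_pop[i, ] <- bn_draw(p_group[groups[i], ], config$f_pop)
  }

  # admixture: mixture of the two *group* frequencies
  admix <- config$admix_pops
  if (length(admix)) {
    unknown <- setdiff(names(admix), pops)
    if (length(unknown)) stop("unknown admixed population(s): ",
                              paste(unknown, collapse = ", "))
    for (p in names(admix)) {
      w <- admix[[p]]
      p_pop[p, ] <- w * p_group["A", ] + (1 - w) * p_group["B", ]
    }
  }

  # environmental clines on the logit scale
  adaptive_ids <- integer(0)
  beta_by_site <- numeric(0)
  if (config$n_adaptive > 0) {
    variant_ids <- which(is_variant)
    adaptive_ids <- sort(sample(variant_ids, config$n_adaptive))
    env_p <- env[env$horizon == "present", ]
    z <- env_p[[config$env_var]][match(pops, env_p$population)]
    z <- (z - mean(z)) / sd(z)
    beta_by_site <- rep(config$beta_env, length(adaptive_ids))
    names(beta_by_site) <- as.character(adaptive_ids)
    lg <- log(p_pop[, adaptive_ids, drop = FALSE] /
                (1 - p_pop[, adaptive_ids, drop = FALSE]))
    lg <- lg + outer(z, beta_by_site)
    shifted <- 1 / (1 + exp(-lg))
    if (any(!is.finite(shifted))) {
      warning("logit overflow at adaptive sites; frequencies clamped")
    }
    p_pop[, adaptive_ids] <- pmin(pmax(shifted, 1e-6), 1 - 1e-6)
  }

  # invariant sites: monomorphic across all populations
  if (any(!is_variant)) {
    fixed_allele <- rbinom(sum(!is_variant), 1, 0.05)
    p_pop[, !is_variant] <- matrix(fixed_allele, n_pop, sum(!is_variant),
                                   byrow = TRUE)
    p_group[, !is_variant] <- matrix(fixed_allele, 2, sum(!is_variant),
                                     byrow = TRUE)
  }
  p_pop <- pmin(pmax(p_pop, 0), 1)

  truth <- list(
    adaptive_site_ids = adaptive_ids,
    beta_by_site = beta_by_site,
    admix_weights = admix,
    planted_roh = config$roh_plants,
    f_group = config$f_group,
    f_pop = config$f_pop
  )
  p0[!is_variant] <- p_pop[1, !is_variant]
  list(p_pop = p_pop, p_group = p_group, p0 = p0, truth = truth,
       site = c(sim_site_map(config), list(is_variant = is_variant)),
       frame = frame, env = env)
}

# missingness + Poisson depth, shared by both genotype generators
apply_missing_depth <- function(dosage, config) {
  n <- length(dosage)
  depth <- matrix(rpois(n, config$mean_depth), nrow(dosage), ncol(dosage))
  if (config$missing_rate > 0) {
    drop <- matrix(runif(n) < config$missing_rate, nrow(dosage))
    dosage[drop] <- NA_integer_
    depth[drop] <- 0L
  }
  list(dosage = dosage, depth = depth)
}

#' Draw genotypes from population frequencies (independent sites)
#'
#' Per sample and site, dosage ~ Binomial(2, p_pop); missingness is applied
#' uniformly at random and per-genotype depth drawn from a Poisson so that
#' depth filters are exercisable. Sites are independent; use
#' [simulate_haplotypes_ld()] when linkage structure matters.
#'
#' @param freqs output of [simulate_frequencies()].
#' @param config the same [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(freqs, config) {
  set.seed(config$seed + 101L)
  frame <- freqs$frame
  p <- freqs$p_pop[frame$population, , drop = FALSE]
  stopifnot(all(p >= 0 & p <= 1))
  dosage <- matrix(rbinom(length(p), 2L, p), nrow(p), ncol(p))
  rownames(dosage) <- frame$sample
  md <- apply_missing_depth(dosage, config)
  genotype_matrix(md$dosage, freqs$site$chrom, freqs$site$pos,
                  is_variant = freqs$site$is_variant, depth = md$depth)
}

#' Draw phased haplotypes with distance-decaying linkage
#'
#' Copying-chain model: each haplotype carries a latent uniform that is
#' retained from the previous site with probability exp(-d / ld_decay_bp)
#' (d = inter-site distance, chains restart across chromosomes) and
#' refreshed otherwise; the allele is the indicator latent < p. Marginal
#' allele frequencies equal p exactly, while adjacent sites are correlated
#' with strength decaying in distance, so genotype r-squared declines
#' monotonically. Genotype = sum of the two haplotypes.
#'
#' @param freqs output of [simulate_frequencies()].
#' @param config the same [sim_config()].
#' @return A list with `h1`, `h2` (samples x sites 0/1 haplotype matrices)
#'   and `gm`, the resulting [genotype_matrix()] (with missingness and depth
#'   applied).
#' @export
simulate_haplotypes_ld <- function(freqs, config) {
  set.seed(config$seed + 211L)
  frame <- freqs$frame
  site <- freqs$site
  for (ch in unique(site$chrom)) {
    if (any(diff(site$pos[site$chrom == ch]) <= 0)) {
      stop("site positions must be sorted within chromosome")
    }
  }
  p <- freqs$p_pop[frame$population, , drop = FALSE]
  n_s <- nrow(p)
  n_sites <- ncol(p)
  d <- c(Inf, diff(site$pos))
  d[c(1L, which(site$chrom[-1L] != site$chrom[-n_sites]) + 1L)] <- Inf
  copy_prob <- if (config$ld_decay_bp > 0) exp(-d / config$ld_decay_bp)
               else rep(0, n_sites)
  draw_hap <- function() {
    h <- matrix(0L, n_s, n_sites)
    u <- runif(n_s)
    for (j in seq_len(n_sites)) {
      if (copy_prob[j] < 1) {
        refresh <- runif(n_s) >= copy_prob[j]
        if (any(refresh)) u[refresh] <- runif(sum(refresh))
      }
      h[, j] <- as.integer(u < p[, j])
    }
    h
  }
  h1 <- draw_hap()
  h2 <- draw_hap()
  dosage <- h1 + h2
  rownames(dosage) <- frame$sample
  md <- apply_missing_depth(dosage, config)
  gm <- genotype_matrix(md$dosage, site$chrom, site$pos,
                        is_variant = site$is_variant, depth = md$depth)
  list(h1 = h1, h2 = h2, gm = gm)
}

#' Force planted autozygous tracts into a genotype matrix
#'
#' Inside each planted interval the sample's heterozygous calls are set to
#' the homozygote of the locally more frequent allele; homozygous and
#' missing entries are untouched, as is everything outside the plants.
#'
#' @param gm a [genotype_matrix()].
#' @param roh_plants data frame (sample, chrom, start, end); intervals must
#'   not overlap within a sample.
#' @return The modified `genotype_matrix`.
#' @export
plant_roh <- function(gm, roh_plants) {
  if (is.null(roh_plants) || nrow(as.data.frame(roh_plants)) == 0) return(gm)
  plants <- as.data.frame(roh_plants)
  for (s in unique(plants$sample)) {
    iv <- plants[plants$sample == s, ]
    for (ch in unique(iv$chrom)) {
      ivc <- iv[iv$chrom == ch, ]
      ivc <- ivc[order(ivc$start), ]
      if (nrow(ivc) > 1 && any(ivc$start[-1] <= ivc$end[-nrow(ivc)])) {
        stop("overlapping ROH plants for sample ", s, " on ", ch)
      }
      if (any(ivc$start < 1) ||
          any(ivc$end > max(gm$pos[gm$chrom == ch]))) {
        stop("ROH plant outside chromosome bounds on ", ch)
      }
    }
  }
  samp_idx <- match(plants$sample, rownames(gm$dosage))
  if (anyNA(samp_idx)) stop("unknown sample in ROH plants")
  # homozygote target per site: the majority allele among non-missing calls
  afreq <- allele_counts(gm)
  target <- ifelse(afreq$n_alt > afreq$n_ref, 2L, 0L)
  for (k in seq_len(nrow(plants))) {
    sites <- which(gm$chrom == plants$chrom[k] &
                     gm$pos >= plants$start[k] & gm$pos <= plants$end[k])
    row <- gm$dosage[samp_idx[k], sites]
    het <- which(!is.na(row) & row == 1L)
    gm$dosage[samp_idx[k], sites[het]] <- target[sites[het]]
  }
  gm
}

#' Simulate a complete study dataset
#'
#' Runs the full generator: metadata and environment, hierarchical
#' Balding-Nichols frequencies, linked haplotypes, and planted autozygous
#' tracts. This is the in-memory equivalent of the fixture files written by
#' [write_dataset()].
#'
#' @param config a [sim_config()].
#' @param linked if `TRUE` (default) genotypes come from the haplotype
#'   copying chain; otherwise sites are drawn independently.
#' @return A list with `gm`, `frame`, `env`, `truth`, `freqs`.
#' @export
simulate_dataset <- function(config, linked = TRUE) {
  freqs <- simulate_frequencies(config)
  gm <- if (linked) simulate_haplotypes_ld(freqs, config)$gm
        else simulate_genotypes(freqs, config)
  gm <- plant_roh(gm, config$roh_plants)
  list(gm = gm, frame = freqs$frame, env = freqs$env,
       truth = freqs$truth, freqs = freqs)
}

#' Write a simulated dataset to disk
#'
#' Writes a VCF 4.2 (GT:DP), a sample metadata CSV (sample, population,
#' group, lon, lat), an environment CSV (population, horizon, six
#' bioclimatic variables) and a ground-truth JSON.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    meta = file.path(dir, "metadata.csv"),
    env = file.path(dir, "environment.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(sim$gm, paths$vcf)
  write.csv(sim$frame, paths$meta, row.names = FALSE, quote = FALSE)
  write.csv(sim$env, paths$env, row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  truth$planted_roh <- if (is.null(truth$planted_roh)) list()
                       else truth$planted_roh
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             paths$truth)
  invisible(paths)
}
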