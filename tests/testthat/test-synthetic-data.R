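test_that("identical config and seed give bit-identical VCF output", {
  cfg <- sim_config(n_sites = 300, n_pops_per_group = 2,
                    n_samples_per_pop = 3, seed = 11)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in c("genotypes.vcf", "metadata.csv", "environment.csv",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("zero-drift limit collapses population frequencies onto p0", {
  cfg <- sim_config(n_sites = 500, invariant_fraction = 0, n_adaptive = 0,
                    admix_pops = c(), f_group = 1e-8, f_pop = 1e-8,
                    n_pops_per_group = 3, n_samples_per_pop = 4, seed = 2)
  fr <- simulate_frequencies(cfg)
  spread <- apply(fr$p_pop, 2, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-3)
  sim <- simulate_dataset(cfg, linked = FALSE)
  expect_lt(abs(genome_stats(sim$gm, sim$frame)$fst), 0.01)
})

test_that("admixture weight 1 reproduces group A frequencies exactly", {
  cfg <- sim_config(n_sites = 200, invariant_fraction = 0, n_adaptive = 0,
                    admix_pops = c(B2 = 1.0), n_pops_per_group = 2,
                    n_samples_per_pop = 2, seed = 3)
  fr <- simulate_frequencies(cfg)
  expect_equal(unname(fr$p_pop["B2", ]), unname(fr$p_group["A", ]))
})

test_that("group FST estimator recovers f_group in the no-substructure limit", {
  # 100 replicates, 1 population per group with vanishing within-group
  # drift: the ratio-of-sums Hudson estimator should be unbiased for
  # f_group to within 2 Monte-Carlo standard errors
  fsts <- vapply(1:100, function(s) {
    cfg <- sim_config(n_pops_per_group = 1, n_samples_per_pop = 10,
                      n_sites = 800, invariant_fraction = 0.5,
                      n_adaptive = 0, admix_pops = c(), f_group = 0.03,
                      f_pop = 1e-4, seed = 4000 + s)
    sim <- simulate_dataset(cfg, linked = FALSE)
    genome_stats(sim$gm, sim$frame)$fst
  }, numeric(1))
  mc_se <- sd(fsts) / sqrt(length(fsts))
  expect_lt(abs(mean(fsts) - 0.03), 2 * mc_se + 1e-4)
  expect_lt(abs(mean(fsts) - 0.03), 0.01)
})

test_that("binomial genotype draws have the right mean at p = 0.5", {
  cfg <- sim_config(n_sites = 500, invariant_fraction = 0, n_adaptive = 0,
                    admix_pops = c(), n_pops_per_group = 5,
                    n_samples_per_pop = 2, missing_rate = 0, seed = 5)
  fr <- simulate_frequencies(cfg)
  fr$p_pop[] <- 0.5
  gm <- simulate_genotypes(fr, cfg)
  n_draws <- length(gm$dosage)
  se <- sqrt(2 * 0.5 * 0.5 / n_draws)
  expect_lt(abs(mean(gm$dosage) - 1.0), 3 * se)
  # degenerate frequencies give constant matrices
  fr$p_pop[] <- 0
  expect_true(all(simulate_genotypes(fr, cfg)$dosage == 0L))
  fr$p_pop[] <- 1
  expect_true(all(simulate_genotypes(fr, cfg)$dosage == 2L))
})

test_that("haplotype copying chain has the analytic copying probability scale", {
  # at distance L*ln(2) the copy probability is exactly one half; verify
  # via the adjacent-site allele concordance at matched p = 0.5, which is
  # P(copy) + (1 - P(copy))/2 = 0.75 at that spacing
  L <- 10000
  spacing <- as.integer(round(L * log(2)))
  cfg <- sim_config(n_sites = 2000, invariant_fraction = 0, n_adaptive = 0,
                    admix_pops = c(), n_pops_per_group = 1,
                    n_samples_per_pop = 10, n_chrom = 1,
                    site_spacing_bp = spacing, ld_decay_bp = L,
                    missing_rate = 0, seed = 6)
  fr <- simulate_frequencies(cfg)
  fr$p_pop[] <- 0.5
  hp <- simulate_haplotypes_ld(fr, cfg)
  conc <- mean(hp$h1[, -1] == hp$h1[, -ncol(hp$h1)])
  n_adj <- length(hp$h1[, -1])
  expect_lt(abs(conc - 0.75), 4 * sqrt(0.75 * 0.25 / n_adj) + 0.005)
})

test_that("LD limits behave: infinite decay length copies, zero decouples", {
  base <- function(L, seed) {
    cfg <- sim_config(n_sites = 400, invariant_fraction = 0, n_adaptive = 0,
                      admix_pops = c(), n_pops_per_group = 1,
                      n_samples_per_pop = 20, n_chrom = 1,
                      site_spacing_bp = 100L, ld_decay_bp = L,
                      missing_rate = 0, seed = seed)
    fr <- simulate_frequencies(cfg)
    fr$p_pop[] <- 0.5
    hp <- simulate_haplotypes_ld(fr, cfg)
    r2 <- suppressWarnings(cor(hp$gm$dosage[, -1], hp$gm$dosage[, -400]))
    mean(diag(r2)^2, na.rm = TRUE)
  }
  expect_gt(base(1e12, 7), 0.95) # near-perfect adjacent correlation
  expect_lt(base(1e-9, 7), 0.08) # independence up to 1/(2n) background
})

test_that("ROH planting forces homozygosity inside and only inside plants", {
  plants <- data.frame(sample = "A1_s1", chrom = "chr1",
                       start = 1, end = 400000)
  cfg <- sim_config(n_sites = 400, invariant_fraction = 0, n_adaptive = 0,
                    admix_pops = c(), n_pops_per_group = 1,
                    n_samples_per_pop = 3, n_chrom = 1, missing_rate = 0,
                    roh_plants = plants, seed = 8)
  sim <- simulate_dataset(cfg)
  row <- sim$gm$dosage["A1_s1", sim$gm$chrom == "chr1"]
  expect_false(any(row == 1L, na.rm = TRUE))
  # other samples untouched relative to an unplanted run
  cfg0 <- cfg; cfg0$roh_plants <- NULL
  sim0 <- simulate_dataset(cfg0)
  expect_identical(sim$gm$dosage["A1_s2", ], sim0$gm$dosage["A1_s2", ])
  # empty plant list is the identity
  expect_identical(plant_roh(sim0$gm, NULL), sim0$gm)
  # overlapping plants rejected
  bad <- data.frame(sample = "A1_s1", chrom = "chr1",
                    start = c(1, 1000), end = c(5000, 8000))
  expect_error(plant_roh(sim0$gm, bad), "overlap")
})

test_that("planted environmental clines are recoverable from the truth record", {
  cfg <- sim_config(n_sites = 2000, invariant_fraction = 0.5,
                    n_adaptive = 40, beta_env = 1.5, admix_pops = c(),
                    seed = 9)
  fr <- simulate_frequencies(cfg)
  expect_length(fr$truth$adaptive_site_ids, 40)
  expect_true(all(fr$site$is_variant[fr$truth$adaptive_site_ids]))
  envp <- fr$env[fr$env$horizon == "present", ]
  z <- scale(envp$bio12[match(rownames(fr$p_pop), envp$population)])[, 1]
  cors <- apply(fr$p_pop[, fr$truth$adaptive_site_ids], 2,
                function(p) cor(p, z))
  expect_gt(mean(cors > 0.5), 0.9)
})

test_that("environment generator plants a collinear pair and scaled futures", {
  cfg <- sim_config(seed = 10)
  env <- simulate_env(cfg, simulate_metadata(cfg))
  ew <- env_wide(env, "present")
  expect_gt(abs(cor(ew[, "bio12"], ew[, "bio17"])), 0.8)
  d126 <- env_wide(env, "SSP126_2081_2100") - ew
  d585 <- env_wide(env, "SSP585_2081_2100") - ew
  expect_equal(d585, 2.5 * d126, tolerance = 1e-10)
})
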