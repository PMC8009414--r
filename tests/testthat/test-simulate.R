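test_that("simulated map is linear without jitter and reproducible", {
  cfg <- sim_config(populations = sim_populations(12), n_loci = 10,
                    n_chromosomes = 1, chromosome_length_bp = 1e7,
                    map_rate_cM_per_Mb = 1, map_jitter = 0, seed = 5)
  map <- simulate_map(cfg)
  expect_equal(max(map$cM), 10, tolerance = 1e-5)
  expect_equal(min(map$cM), 0)
  expect_identical(map, simulate_map(cfg))
})

test_that("map increments stay non-negative under strong jitter", {
  cfg <- sim_config(populations = sim_populations(12), n_loci = 10,
                    n_chromosomes = 2, chromosome_length_bp = 1e7,
                    map_anchor_spacing_bp = 5e5,  # ~20 anchors per chromosome
                    map_jitter = 0.5, seed = 9)
  map <- simulate_map(cfg)
  for (ch in unique(map$chrom)) {
    expect_true(all(diff(map$cM[map$chrom == ch]) >= 0))
    expect_true(all(diff(map$bp[map$chrom == ch]) > 0))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(populations = sim_populations(12), n_loci = 0),
               class = "arraybias_config_error")
  expect_error(sim_config(populations = sim_populations(12),
                          chromosome_length_bp = -1),
               class = "arraybias_config_error")
  pops <- sim_populations(12)
  pops$f[1] <- 1.5
  expect_error(sim_config(populations = pops),
               class = "arraybias_config_error")
  pops2 <- sim_populations(12)
  pops2$is_outgroup <- FALSE
  expect_error(sim_config(populations = pops2),
               class = "arraybias_config_error")
})

test_that("panels are bit-identical under a fixed seed", {
  cfg <- small_config(n_loci = 500)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$freq, p2$freq)
  expect_identical(p1$loci, p2$loci)
  expect_identical(p1$truth, p2$truth)
})

test_that("panel respects positional and frequency invariants", {
  panel <- simulate_panel(small_config(n_loci = 2000))
  expect_true(all(panel$freq >= 0 & panel$freq <= 1))
  expect_identical(ncol(panel$freq), nrow(panel$pop_meta))
  for (ch in unique(panel$loci$chrom)) {
    i <- panel$loci$chrom == ch
    expect_true(all(diff(panel$loci$bp[i]) > 0))
    expect_true(all(diff(panel$loci$cM[i]) >= 0))
  }
  expect_true(all(panel$loci$quality >= 0))
})

test_that("no-drift, infinite-depth limit recovers the ancestral frequency", {
  pops <- sim_populations(12)
  pops$f <- 1e-6
  pops$mode <- "individual"
  pops$n <- 500000L
  cfg <- sim_config(populations = pops,
                    cluster_f = setNames(rep(1e-7, 7),
                                         unique(pops$cluster)),
                    outgroup_private_fraction = 1e-9,
                    prob_ref_ancestral = 1,
                    n_loci = 2000, seed = 21)
  panel <- simulate_panel(cfg)
  truth_ref <- 1 - panel$truth$derived   # ancestral always reference here
  ingroup <- panel$pop_meta$name[!panel$pop_meta$is_outgroup]
  for (pop in ingroup[1:4]) {
    dev <- panel$freq[, pop] - truth_ref
    se <- sd(dev) / sqrt(length(dev))
    expect_lt(abs(mean(dev)), 3 * se + 1e-4)
  }
})

test_that("observed frequencies are unbiased for both observation modes", {
  pops <- sim_populations(12)
  cfg <- sim_config(populations = pops, n_loci = 3000, seed = 8)
  panel <- simulate_panel(cfg, keep_truth_freq = TRUE)
  for (mode in c("individual", "pool")) {
    pop <- panel$pop_meta$name[panel$pop_meta$mode == mode][1]
    dev <- panel$freq[, pop] - panel$truth$freq_true[, pop]
    se <- sd(dev) / sqrt(length(dev))
    expect_lt(abs(mean(dev)), 3 * se)
  }
})

test_that("the truncated 1/x spectrum is rich in rare alleles", {
  cfg <- sim_config(populations = sim_populations(24), n_loci = 50000,
                    sfs_truncation = 0.001, seed = 13)
  panel <- simulate_panel(cfg)
  panel$ancestral_is_ref <- panel$truth$ancestral_is_ref
  ingroup <- panel$pop_meta$name[!panel$pop_meta$is_outgroup]
  d <- derived_frequencies(panel, populations = ingroup)
  expect_gt(mean(d < 0.05), mean(d >= 0.45 & d <= 0.55))
})

test_that("population drift variance matches the Balding-Nichols moment", {
  for (f_target in c(0.01, 0.1)) {
    pops <- sim_populations(12)
    pops$f <- f_target
    pops$mode <- "individual"
    pops$n <- 500000L
    cfg <- sim_config(populations = pops,
                      cluster_f = setNames(rep(1e-13, 7),
                                           unique(pops$cluster)),
                      outgroup_private_fraction = 1e-9,
                      sfs_truncation = 0.05,
                      n_loci = 30000, seed = 31)
    panel <- simulate_panel(cfg, keep_truth_freq = TRUE)
    pop <- "LOC01"
    x <- ifelse(panel$truth$ancestral_is_ref,
                1 - panel$truth$derived, panel$truth$derived)
    ratio <- (panel$truth$freq_true[, pop] - x)^2 / (x * (1 - x))
    expect_equal(mean(ratio), f_target, tolerance = 0.1)
  }
})

test_that("the outgroup is more distant than any ingroup pair", {
  cfg <- sim_config(populations = sim_populations(16), n_loci = 4000,
                    outgroup_divergence = 0.6, seed = 17)
  panel <- simulate_panel(cfg)
  d <- nei_matrix(panel)
  og <- panel$pop_meta$name[panel$pop_meta$is_outgroup]
  ing <- setdiff(panel$pop_meta$name, og)
  expect_gt(mean(d[og, ing]), max(d[ing, ing]))
})

test_that("group assignment honours sizes and keeps the outgroup fixed", {
  panel <- simulate_panel(sim_config(populations = sim_populations(46),
                                     n_loci = 300, seed = 2))
  g <- assign_groups(panel, 8, 19, seed = 4)
  expect_identical(sum(g$group == "application"), 18L)
  expect_identical(sum(g$group == "outgroup"), 1L)
  expect_identical(g$population[g$group == "outgroup"], "GV")
  expect_identical(g, assign_groups(panel, 8, 19, seed = 4))

  # boundary: leave exactly one validation and one application population
  g2 <- assign_groups(panel, 43, 1, seed = 4)
  expect_identical(sum(g2$group == "validation"), 1L)
  expect_identical(sum(g2$group == "application"), 1L)
  expect_error(assign_groups(panel, 44, 1, seed = 4),
               class = "arraybias_config_error")
})

test_that("nearest-mode discovery takes next-nearest when neighbours collide", {
  # 6 populations; S1 and S2 both have N as their nearest neighbour
  freq <- cbind(
    S1 = c(0.50, 0.50, 0.50, 0.50),
    S2 = c(0.52, 0.52, 0.52, 0.52),
    N  = c(0.51, 0.51, 0.51, 0.51),
    M  = c(0.60, 0.60, 0.60, 0.60),
    F1 = c(0.90, 0.10, 0.90, 0.10),
    F2 = c(0.80, 0.20, 0.80, 0.20),
    OG = c(0.01, 0.99, 0.01, 0.99)
  )
  panel <- toy_panel(freq, outgroup = "OG", seed_pops = c("S1", "S2"))
  d <- nei_matrix(panel)
  # exhaustive ranking: N is nearest to both seeds, M is S2's next-nearest
  expect_identical(names(which.min(d["S1", c("N", "M", "F1")])), "N")
  expect_identical(names(which.min(d["S2", c("N", "M", "F1")])), "N")
  g <- assign_groups(panel, n_validation = 1, seed = 1, mode = "nearest")
  disc <- g$population[g$group == "discovery"]
  expect_setequal(disc, c("S1", "S2", "N", "M"))
  expect_identical(length(disc), 4L)  # exactly 2x the number of seeds
})
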