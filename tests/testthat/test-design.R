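disc_groups <- function(pops, clusters = NULL) {
  tibble::tibble(
    population = pops,
    group = factor("discovery",
                   levels = c("discovery", "validation", "application",
                              "outgroup")),
    cluster = clusters %||% rep("c1", length(pops))
  )
}

all_loci_set <- function(panel) {
  arraybias:::new_snp_set(seq_len(nrow(panel$loci)),
                          rep("x", nrow(panel$loci)), "candidate")
}

test_that("discovery filter applies quality, coverage and panel-MAF rules", {
  # 8 discovery populations; first locus has mean 0.99125 -> MAF 0.00875
  freq <- rbind(
    c(0.98, 0.99, 1.0, 0.97, 1.0, 1.0, 0.99, 1.0),
    c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    c(0.6, 0.4, 0.6, 0.4, 0.6, 0.4, 0.6, 0.4)
  )
  colnames(freq) <- paste0("D", 1:8)
  panel <- toy_panel(freq, quality = c(100, 59.9, 100))
  groups <- disc_groups(paste0("D", 1:8))
  kept <- discovery_filter(panel, groups, design_config())
  # locus 1 fails MAF, locus 2 fails quality (59.9 < 60), locus 3 passes
  expect_identical(kept$locus, 3L)

  panel2 <- toy_panel(freq[rep(2, 5), ], quality = 100, depth = 50)
  expect_identical(discovery_filter(panel2, groups)$locus, 1:5)

  # coverage cap: one extreme-depth locus among many at the mean
  panel3 <- toy_panel(freq[rep(2, 30), ], quality = 100,
                      depth = c(rep(50L, 29), 5000L))
  expect_identical(discovery_filter(panel3, groups)$locus, 1:29)

  expect_error(discovery_filter(panel, disc_groups(character())),
               class = "arraybias_config_error")
})

test_that("cluster removal uses the near/far invariant-flank rule", {
  freq <- matrix(0.5, 3, 2, dimnames = list(NULL, c("A", "B")))
  panel <- toy_panel(freq, bp = c(100L, 103L, 110L))
  cand <- all_loci_set(panel)
  kept <- remove_clusters(panel, cand, design_config())
  # flanks of 103 are (2, 6): 2 < 4 and 6 < 10 -> removed; ends have an
  # infinite outer flank and survive
  expect_identical(kept$locus, c(1L, 3L))

  panel2 <- toy_panel(freq, bp = c(100L, 103L, 200L))
  kept2 <- remove_clusters(panel2, all_loci_set(panel2), design_config())
  expect_identical(kept2$locus, 1:3)  # flanks of 103 are (2, 96); 96 >= 10

  panel3 <- toy_panel(freq[1, , drop = FALSE], bp = 100L)
  kept3 <- remove_clusters(panel3, all_loci_set(panel3), design_config())
  expect_identical(kept3$locus, 1L)   # single SNP: infinite flanks
})

test_that("backbone greedy scan enforces the minimum distance", {
  freq <- matrix(0.5, 4, 2, dimnames = list(NULL, c("A", "B")))
  panel <- toy_panel(freq, bp = c(1000L, 2500L, 3100L, 5200L))
  cand <- all_loci_set(panel)
  bb <- build_backbone(panel, cand, c("A", "B"), min_dist_bp = 2000)
  expect_identical(panel$loci$bp[bb$locus], c(1000L, 3100L, 5200L))

  bb1 <- build_backbone(panel, cand, c("A", "B"), min_dist_bp = 1)
  expect_identical(bb1$locus, 1:4)

  # no locus segregates in all populations -> empty backbone
  freq2 <- cbind(A = c(0.5, 0.5), B = c(1, 0))
  panel2 <- toy_panel(freq2, bp = c(1000L, 4000L))
  bb2 <- build_backbone(panel2, all_loci_set(panel2), c("A", "B"), 2000)
  expect_identical(nrow(bb2), 0L)
})

test_that("gap target counts follow round-half-up of density x cM span", {
  # single whole-chromosome gap spanning 0.003001 cM with density 667:
  # round(667 * 0.003001) = 2 fills for the first population; the second
  # population's target is already met by selections segregating in it
  bp <- c(1000L, seq(2000L, 3800L, by = 200L), 4001L)
  freq <- matrix(0.5, length(bp), 2, dimnames = list(NULL, c("A", "B")))
  cM <- (bp - 1) / 1e6
  panel <- toy_panel(freq, bp = bp, cM = cM)
  map <- new_genetic_map(tibble::tibble(chrom = "chr1",
                                        bp = c(1000L, 4001L),
                                        cM = (c(1000, 4001) - 1) / 1e6))
  groups <- disc_groups(c("A", "B"), c("c1", "c2"))
  cfg <- design_config(target_density = 667, use_backbone = FALSE)
  out <- equal_spacing(panel, all_loci_set(panel), groups, map, cfg)
  expect_identical(sum(out$provenance == "gap-fill:A"), 2L)
  expect_identical(nrow(out), 2L)
})

test_that("zero target density with backbone returns exactly the backbones", {
  withr::with_seed(7, {
    freq <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("A", "B")))
    freq[c(3, 9), 2] <- 0  # not segregating in B
  })
  panel <- toy_panel(freq, bp = seq(500L, by = 2500L, length.out = 20))
  map <- toy_map(len_bp = 1e6)
  groups <- disc_groups(c("A", "B"), c("c1", "c2"))
  cfg <- design_config(target_density = 0, use_backbone = TRUE)
  out <- equal_spacing(panel, all_loci_set(panel), groups, map, cfg)
  want <- sort(unique(c(
    oracle_backbone(panel, 1:20, c("A", "B"), 2000),
    oracle_backbone(panel, 1:20, "A", 1),
    oracle_backbone(panel, 1:20, "B", 1)
  )))
  expect_identical(out$locus, as.integer(want))
})

test_that("equal spacing matches the brute-force oracle on random instances", {
  for (seed in 1:30) {
    inst <- random_spacing_instance(seed)
    res <- run_spacing_both(inst)
    expect_identical(res$got, as.integer(res$want),
                     label = sprintf("instance seed %d", seed))
  }
})

test_that("validation keeps loci segregating in enough validation populations", {
  nv <- 19
  freq <- cbind(
    matrix(0.5, 3, 2),                         # discovery pops
    rbind(c(rep(0.4, 8), rep(0, nv - 8)),      # segregates in exactly 8
          c(rep(0.4, 7), rep(1, nv - 7)),      # in exactly 7
          rep(0, nv))                          # fixed everywhere
  )
  colnames(freq) <- c("D1", "D2", paste0("V", seq_len(nv)))
  panel <- toy_panel(freq)
  groups <- tibble::tibble(
    population = colnames(freq),
    group = factor(c("discovery", "discovery", rep("validation", nv)),
                   levels = c("discovery", "validation", "application",
                              "outgroup")),
    cluster = "c1"
  )
  kept <- validate_snps(panel, all_loci_set(panel), groups, design_config())
  expect_identical(kept$locus, 1L)

  # threshold scales with the validation group size: 5 pops -> ceil(8/19*5)=3
  freq2 <- cbind(D1 = rep(0.5, 2), D2 = rep(0.5, 2),
                 V1 = c(0.4, 0.4), V2 = c(0.4, 0.4), V3 = c(0.4, 0),
                 V4 = c(0, 0), V5 = c(1, 1))
  panel2 <- toy_panel(freq2)
  groups2 <- tibble::tibble(
    population = colnames(freq2),
    group = factor(c("discovery", "discovery", rep("validation", 5)),
                   levels = levels(groups$group)),
    cluster = "c1"
  )
  kept2 <- validate_snps(panel2, all_loci_set(panel2), groups2,
                         design_config())
  expect_identical(kept2$locus, 1L)  # locus 2 segregates in only 2 of 5
})

test_that("downsampling keeps exonic loci and honours density multipliers", {
  # all candidates exonic -> output equals candidate set
  freq <- matrix(0.5, 6, 2, dimnames = list(NULL, c("A", "B")))
  panel <- toy_panel(freq, exonic = TRUE)
  map <- toy_map(len_bp = 1e6)
  groups <- disc_groups(c("A", "B"), c("c1", "c2"))
  out <- downsample(panel, all_loci_set(panel), groups, map,
                    design_config(target_density = 0))
  expect_identical(out$locus, 1:6)
  expect_true(all(out$provenance == "exonic-keep"))

  # no exonic loci, density 0 -> all-population backbone only
  panel2 <- toy_panel(freq, exonic = FALSE,
                      bp = seq(500L, by = 2500L, length.out = 6))
  out2 <- downsample(panel2, all_loci_set(panel2), groups, map,
                     design_config(target_density = 0))
  expect_identical(out2$locus,
                   as.integer(oracle_backbone(panel2, 1:6, c("A", "B"), 2000)))
  expect_true(all(out2$provenance == "backbone-all"))
})

test_that("a tripled sub-cluster multiplier draws more gap-fill SNPs", {
  withr::with_seed(11, {
    n <- 400
    bp <- sort(sample.int(2e6, n))
    freq <- cbind(A = runif(n, 0.1, 0.9), B = runif(n, 0.1, 0.9))
    # symmetric: both populations segregate everywhere
    panel <- toy_panel(freq, bp = bp, cM = (bp - 1) / 1e6)
  })
  map <- toy_map(len_bp = 2e6)
  groups <- disc_groups(c("A", "B"), c("c1", "c2"))
  cfg <- design_config(target_density = 30, use_backbone = FALSE,
                       downsample_multipliers = c(c2 = 3))
  out <- downsample(panel, all_loci_set(panel), groups, map, cfg)
  fills <- table(out$provenance)
  expect_gte(fills[["gap-fill:B"]] + 0, fills[["gap-fill:A"]] + 0)
})

test_that("the full design chain is nested, deterministic and shrinking", {
  cfg <- small_config(n_loci = 6000, seed = 19)
  map <- simulate_map(cfg)
  panel <- simulate_panel(cfg, map)
  groups <- assign_groups(panel, 8, 8, seed = 3)
  des <- design_array(panel, groups, map, design_config())
  steps <- des$steps
  expect_true(all(steps$cluster_removal$locus %in% steps$discovery$locus))
  expect_true(all(steps$equal_spacing$locus %in% steps$cluster_removal$locus))
  expect_true(all(steps$validation$locus %in% steps$equal_spacing$locus))
  expect_true(all(steps$downsampling$locus %in% steps$validation$locus))
  expect_lt(nrow(steps$equal_spacing), nrow(steps$discovery))

  des2 <- design_array(panel, groups, map, design_config())
  expect_identical(lapply(des$steps, as.data.frame),
                   lapply(des2$steps, as.data.frame))

  # backbone spacing invariant
  bb <- steps$equal_spacing
  bb <- bb$locus[bb$provenance == "backbone-all"]
  for (ch in unique(panel$loci$chrom[bb])) {
    pos <- panel$loci$bp[bb[panel$loci$chrom[bb] == ch]]
    if (length(pos) > 1) expect_true(all(diff(sort(pos)) >= 2000))
  }
})

test_that("mean discovery-panel MAF rises through the selective steps", {
  cfg <- small_config(n_loci = 6000, seed = 23)
  map <- simulate_map(cfg)
  panel <- simulate_panel(cfg, map)
  groups <- assign_groups(panel, 8, 8, seed = 5)
  des <- design_array(panel, groups, map, design_config())
  dpops <- groups$population[groups$group == "discovery"]
  maf_of <- function(loci) {
    f <- rowMeans(panel$freq[loci, dpops, drop = FALSE])
    mean(pmin(f, 1 - f))
  }
  maf_truth <- maf_of(seq_len(nrow(panel$loci)))
  maf_s1 <- maf_of(des$steps$discovery$locus)
  maf_s2 <- maf_of(des$steps$cluster_removal$locus)
  maf_s3 <- maf_of(des$steps$equal_spacing$locus)
  expect_gte(maf_s1, maf_truth)
  expect_gte(maf_s3, maf_s2)
})
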