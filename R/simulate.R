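#' Simulate a genetic map
#'
#' Draws a piecewise-linear genetic map for each chromosome of the configured
#' genome. Anchors are placed every `map_anchor_spacing_bp` from position 1
#' (0 cM) to the chromosome end; each inter-anchor segment gets the mean rate
#' scaled by an independent normal multiplier (sd `map_jitter`) floored at
#' zero, so cM is non-decreasing in bp with occasional flat segments.
#'
#' @param config A [sim_config()] object.
#' @return A tibble of class `genetic_map` with columns `chrom`, `bp`, `cM`.
#' @export
#' @examples
#' map <- simulate_map(sim_config(populations = sim_populations(24),
#'                                n_loci = 100))
simulate_map <- function(config) {
  if (!inherits(config, "sim_config")) abort_config("need a <sim_config>")
  len <- config$chromosome_length_bp
  if (len <= 0) abort_config("chromosome length must be positive")
  withr::with_seed(config$seed, {
    maps <- lapply(seq_len(config$n_chromosomes), function(ci) {
      n_anchor <- max(2L, ceiling(len / config$map_anchor_spacing_bp) + 1L)
      bp <- round(seq(1, len, length.out = n_anchor))
      bp <- unique(bp)
      seg_mb <- diff(bp) / 1e6
      mult <- pmax(0, rnorm(length(seg_mb), 1, config$map_jitter))
      cm <- c(0, cumsum(config$map_rate_cM_per_Mb * seg_mb * mult))
      tibble(chrom = paste0("chr", ci), bp = as.integer(bp), cM = cm)
    })
    new_genetic_map(bind_rows(maps))
  })
}

#' Construct a genetic map from an anchor table
#'
#' Validates per-chromosome anchors: at least two per chromosome, strictly
#' increasing bp, non-decreasing cM.
#'
#' @param df Data frame with columns `chrom`, `bp`, `cM`.
#' @return A tibble of class `genetic_map`.
#' @export
new_genetic_map <- function(df) {
  df <- as_tibble(df)
  if (!all(c("chrom", "bp", "cM") %in% names(df))) {
    abort_format("a genetic map needs columns chrom, bp, cM")
  }
  by_chrom <- split(df, df$chrom)
  for (m in by_chrom) {
    if (nrow(m) < 2) abort_format("each chromosome needs at least 2 anchors")
    if (any(diff(m$bp) <= 0)) abort_format("map bp must be strictly increasing")
    if (any(diff(m$cM) < 0)) abort_format("map cM must be non-decreasing")
  }
  class(df) <- c("genetic_map", class(df))
  df
}

#' Simulate a multi-population SNP panel
#'
#' Generates the truth panel every downstream stage works on. Per locus the
#' ancestral derived-allele frequency `x` is drawn from a density proportional
#' to 1/x on `[t, 1 - t]` (neutral-equilibrium shape, rich in rare alleles).
#' Cluster frequencies drift around `x` under a Balding-Nichols Beta
#' distribution with the cluster's F, population frequencies drift likewise
#' around their cluster; the outgroup drifts around `x` with
#' `outgroup_divergence`, pushing most shared loci near fixation, and an
#' additional fraction of loci is private to the outgroup (ingroup fixed).
#' Observed frequencies are then drawn per population: individual mode as a
#' binomial genotype frequency over `2 n` alleles, pool mode as the ratio of
#' reference allelic depth to total depth at a Poisson per-locus depth.
#' Quality and total depth covariates are simulated independently of
#' frequency, and exonic flags come from random intervals covering
#' approximately `exonic_fraction` of each chromosome.
#'
#' @param config A [sim_config()] object.
#' @param map Optional [genetic map][simulate_map]; simulated from `config`
#'   when omitted.
#' @param keep_truth_freq Also store the pre-observation true frequency
#'   matrix in `truth$freq_true` (for calibration checks; doubles memory).
#' @return A `snp_panel`: list with `loci` (tibble: chrom, bp, cM, quality,
#'   depth, exonic, ref, alt), `freq` (loci x populations matrix of observed
#'   reference-allele frequencies), `pop_meta`, `ancestral_is_ref` (NULL until
#'   [infer_ancestral()] is run) and `truth` (generator-side derived
#'   frequencies and orientation, for calibration checks).
#' @export
#' @examples
#' cfg <- sim_config(populations = sim_populations(24), n_loci = 500)
#' panel <- simulate_panel(cfg)
#' panel
simulate_panel <- function(config, map = NULL, keep_truth_freq = FALSE) {
  if (!inherits(config, "sim_config")) abort_config("need a <sim_config>")
  if (is.null(map)) map <- simulate_map(config)
  pops <- config$populations
  L <- config$n_loci
  withr::with_seed(config$seed + 1L, {
    # genome positions: allocate loci to chromosomes proportionally, then
    # sample distinct positions
    alloc <- rep(L %/% config$n_chromosomes, config$n_chromosomes)
    extra <- L - sum(alloc)
    if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
    chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), alloc)
    bp <- unlist(lapply(alloc, function(k) {
      sort(sample.int(config$chromosome_length_bp, k))
    }), use.names = FALSE)

    # ancestral derived frequency: inverse-CDF of density c/x on [t, 1-t]
    t0 <- config$sfs_truncation
    x <- t0 * ((1 - t0) / t0)^runif(L)
    ancestral_is_ref <- runif(L) < config$prob_ref_ancestral
    private <- runif(L) < config$outgroup_private_fraction

    # two-level Balding-Nichols drift on the derived-frequency scale
    ingroup <- pops[!pops$is_outgroup, ]
    clusters <- unique(ingroup$cluster)
    cluster_freq <- vapply(clusters, function(cl) {
      rbeta_bn(x, cluster_f_of(config, cl))
    }, numeric(L))
    freq_true <- matrix(NA_real_, L, nrow(pops),
                        dimnames = list(NULL, pops$name))
    for (j in seq_len(nrow(pops))) {
      p <- pops[j, ]
      if (p$is_outgroup) {
        d <- rbeta_bn(x, config$outgroup_divergence)
        d[private] <- rbeta(sum(private), 2, 2)
      } else {
        d <- rbeta_bn(cluster_freq[, p$cluster], p$f)
        d[private] <- 0
      }
      freq_true[, j] <- d
    }
    # orientation: reference-allele frequency
    freq_true[ancestral_is_ref, ] <- 1 - freq_true[ancestral_is_ref, ]

    # observation layer
    freq <- freq_true
    for (j in seq_len(nrow(pops))) {
      p <- pops[j, ]
      if (p$mode == "individual") {
        m <- 2L * p$n
        freq[, j] <- rbinom(L, m, freq_true[, j]) / m
      } else {
        d <- pmax(1L, rpois(L, p$depth))
        freq[, j] <- rbinom(L, d, freq_true[, j]) / d
      }
    }

    # covariates, independent of frequency
    quality <- rnorm_pos(L, config$quality_mean, config$quality_sd)
    depth <- rpois(L, sum(pops$depth))
    exonic <- simulate_exonic_flags(chrom, bp, config)
    ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    alt <- vapply(ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1), USE.NAMES = FALSE)

    loci <- tibble(
      chrom = chrom, bp = as.integer(bp),
      cM = interpolate_cM(map, chrom, bp),
      quality = quality, depth = as.integer(depth),
      exonic = exonic, ref = ref, alt = alt
    )
    new_snp_panel(
      loci = loci, freq = freq, pop_meta = pops,
      truth = list(derived = x, ancestral_is_ref = ancestral_is_ref,
                   private = private,
                   freq_true = if (keep_truth_freq) freq_true),
      map = map
    )
  })
}

simulate_exonic_flags <- function(chrom, bp, config) {
  exonic <- logical(length(bp))
  len <- config$chromosome_length_bp
  n_int <- max(1L, round(len * config$exonic_fraction / config$exon_length_bp))
  for (ch in unique(chrom)) {
    starts <- sort(sample.int(len - config$exon_length_bp, n_int))
    ends <- starts + config$exon_length_bp            # half-open [start, end)
    idx <- chrom == ch
    pos0 <- bp[idx] - 1L                              # 0-based
    hit <- findInterval(pos0, starts)
    inside <- hit > 0 & pos0 < ends[pmax(hit, 1L)]
    exonic[idx] <- inside
  }
  exonic
}

#' Construct a SNP panel from user-supplied tables
#'
#' Entry point for bringing your own data: a per-locus metadata table, a
#' reference-allele frequency matrix (loci x populations) and a population
#' metadata table. Invariants (positions strictly increasing within
#' chromosome, cM non-decreasing, frequencies in `[0, 1]`, matching
#' dimensions) are checked.
#'
#' @param loci Tibble with columns `chrom`, `bp`, `cM`, `quality`, `depth`,
#'   `exonic`, `ref`, `alt` (use `NA` cM before [add_map_positions()]).
#' @param freq Numeric matrix of reference-allele frequencies, one column per
#'   population in `pop_meta` order.
#' @param pop_meta Tibble with at least `name`, `cluster`, `mode`, `n`,
#'   `is_outgroup` (see [sim_populations()] for the full set of columns).
#' @param ancestral_is_ref Optional per-locus logical orientation flags.
#' @param map Optional `genetic_map` to attach.
#' @return A `snp_panel`.
#' @export
snp_panel <- function(loci, freq, pop_meta, ancestral_is_ref = NULL,
                      map = NULL) {
  new_snp_panel(loci, as.matrix(freq), pop_meta,
                ancestral_is_ref = ancestral_is_ref, map = map)
}

new_snp_panel <- function(loci, freq, pop_meta, ancestral_is_ref = NULL,
                          truth = NULL, map = NULL) {
  loci <- as_tibble(loci)
  pop_meta <- as_tibble(pop_meta)
  if (ncol(freq) != nrow(pop_meta)) {
    abort_format("frequency matrix columns must match pop_meta rows")
  }
  if (nrow(freq) != nrow(loci)) {
    abort_format("frequency matrix rows must match loci rows")
  }
  ok <- is.na(freq) | (freq >= 0 & freq <= 1)
  if (!all(ok)) abort_format("all frequencies must lie in [0, 1]")
  for (ch in unique(loci$chrom)) {
    i <- loci$chrom == ch
    if (any(diff(loci$bp[i]) <= 0)) {
      abort_format("bp must be strictly increasing within a chromosome")
    }
    if (!all(is.na(loci$cM[i])) && any(diff(loci$cM[i]) < -1e-9)) {
      abort_format("cM must be non-decreasing with bp within a chromosome")
    }
  }
  colnames(freq) <- pop_meta$name
  structure(list(loci = loci, freq = freq, pop_meta = pop_meta,
                 ancestral_is_ref = ancestral_is_ref, truth = truth,
                 map = map),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel>\n")
  cat(sprintf("  %s loci on %d chromosome(s), %d populations\n",
              format(nrow(x$loci), big.mark = ","),
              length(unique(x$loci$chrom)), nrow(x$pop_meta)))
  modes <- table(x$pop_meta$mode)
  cat(sprintf("  observation: %s\n",
              paste(sprintf("%s=%d", names(modes), modes), collapse = ", ")))
  cat(sprintf("  ancestral orientation: %s\n",
              if (is.null(x$ancestral_is_ref)) "not inferred" else
                sprintf("%.1f%% reference",
                        100 * mean(x$ancestral_is_ref))))
  invisible(x)
}

#' Subset a panel to a set of loci
#'
#' @param panel A `snp_panel`.
#' @param loci Integer locus indices (rows of `panel$loci`).
#' @return A `snp_panel` restricted to those loci.
#' @export
subset_panel <- function(panel, loci) {
  stopifnot_panel(panel)
  new_snp_panel(panel$loci[loci, ], panel$freq[loci, , drop = FALSE],
                panel$pop_meta,
                ancestral_is_ref = panel$ancestral_is_ref[loci],
                truth = if (!is.null(panel$truth)) {
                  lapply(panel$truth, function(v) {
                    if (is.null(v)) NULL
                    else if (is.matrix(v)) v[loci, , drop = FALSE]
                    else v[loci]
                  })
                },
                map = panel$map)
}
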