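#' Population specification for the synthetic panel
#'
#' Builds the table of populations that [simulate_panel()] draws frequencies
#' for. The default layout mirrors a diverse livestock diversity panel: four
#' commercial lines (two individually genotyped layer lines, two individually
#' genotyped broiler lines), four pooled near relatives of the commercial
#' lines, two pooled wild populations close to the ancestral source, one
#' strongly diverged pooled outgroup, and the remainder as pooled local breeds
#' spread over four clusters. Broiler-cluster populations are tightly related
#' (small within-cluster drift), layer-cluster populations are looser, local
#' breeds looser still.
#'
#' @param n_pops Total number of populations including the outgroup (>= 12).
#' @param pool_size Animals per sequenced DNA pool.
#' @param pool_depth Mean sequencing depth of a pool.
#' @param ind_depth Mean per-animal depth for individually sequenced lines
#'   (kept as metadata; individual-mode frequencies come from genotypes).
#' @return A tibble with one row per population: `name`, `cluster`, `f`
#'   (within-cluster drift, in (0,1)), `mode` (`"individual"` or `"pool"`),
#'   `n` (animals), `depth` (mean depth), `is_seed` (commercial analogue used
#'   to seed nearest-neighbour discovery sets), `is_wild` (close to the
#'   ancestral source; used for ancestral-allele inference), `is_outgroup`.
#' @export
#' @examples
#' sim_populations(24)
sim_populations <- function(n_pops = 46, pool_size = 10, pool_depth = 30,
                            ind_depth = 8) {
  if (n_pops < 12) abort_config("`n_pops` must be at least 12")
  core <- tibble(
    name = c("WL", "BL", "BR1", "BR2", "LE", "RI", "MR", "AR",
             "JF1", "JF2"),
    cluster = c("layer", "layer", "broiler", "broiler",
                "layer", "layer", "broiler", "broiler",
                "wild", "wild"),
    f = c(0.30, 0.30, 0.08, 0.08, 0.30, 0.30, 0.10, 0.10, 0.05, 0.05),
    mode = c("individual", "individual", "individual", "individual",
             rep("pool", 6)),
    n = c(25L, 25L, 20L, 20L, rep(as.integer(pool_size), 6)),
    depth = c(rep(ind_depth, 4), rep(pool_depth, 6)),
    is_seed = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6)),
    is_wild = c(rep(FALSE, 8), TRUE, TRUE),
    is_outgroup = FALSE
  )
  n_local <- n_pops - nrow(core) - 1L
  local <- tibble(
    name = sprintf("LOC%02d", seq_len(n_local)),
    cluster = paste0("local", ((seq_len(n_local) - 1L) %% 4L) + 1L),
    f = 0.20,
    mode = "pool",
    n = as.integer(pool_size),
    depth = pool_depth,
    is_seed = FALSE,
    is_wild = FALSE,
    is_outgroup = FALSE
  )
  outg <- tibble(
    name = "GV", cluster = "outgroup", f = 0.05, mode = "pool",
    n = 2L, depth = pool_depth,
    is_seed = FALSE, is_wild = FALSE, is_outgroup = TRUE
  )
  bind_rows(core, local, outg)
}

#' Simulation configuration
#'
#' Collects all parameters of the synthetic SNP panel generator. The defaults
#' define the package's reference study conditions: a scaled-down genome of
#' three 0.6-Mb autosomes at 3 cM/Mb (~5.4 cM) carrying 50,000 biallelic
#' SNPs — preserving a whole-genome panel's marker densities of roughly one
#' SNP per 35 bp and ~9,000 SNPs/cM, so the 667 SNPs/cM equal-spacing target
#' keeps its selectivity — 46 populations (one diverged outgroup), an
#' ancestral derived-allele frequency drawn from a
#' truncated neutral 1/x density, two-level Balding-Nichols drift
#' (cluster around the ancestral frequency, population around its cluster),
#' and an observation layer that turns true frequencies into either
#' individual-genotype frequencies or pooled allelic-depth ratios.
#'
#' @param populations Population table as built by [sim_populations()].
#' @param n_chromosomes,chromosome_length_bp Genome layout.
#' @param n_loci Number of simulated biallelic SNP loci.
#' @param cluster_f Named vector of cluster-level drift parameters in (0,1);
#'   clusters absent from the vector fall back to `cluster_f_default`.
#' @param cluster_f_default Drift used for clusters not named in `cluster_f`.
#' @param outgroup_divergence Balding-Nichols drift of the outgroup around the
#'   ancestral frequency; large values push most shared loci near fixation.
#' @param outgroup_private_fraction Fraction of loci segregating only in the
#'   outgroup (all ingroup populations fixed for the ancestral allele).
#' @param sfs_truncation Lower truncation of the ancestral derived-allele
#'   frequency density 1/x on `[sfs_truncation, 1 - sfs_truncation]`.
#' @param prob_ref_ancestral Per-locus probability that the reference allele
#'   is the ancestral allele.
#' @param exonic_fraction Approximate fraction of each chromosome covered by
#'   simulated exonic intervals.
#' @param exon_length_bp Length of an individual exonic interval.
#' @param map_rate_cM_per_Mb Mean recombination rate of the genetic map.
#' @param map_jitter Relative standard deviation of per-segment map rates;
#'   negative draws are floored at zero, giving occasional flat segments.
#' @param map_anchor_spacing_bp Physical spacing of map anchors.
#' @param quality_mean,quality_sd Per-locus variant quality distribution
#'   (normal truncated at zero).
#' @param seed Integer seed; the whole panel is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(populations = sim_populations(24), n_loci = 1000)
sim_config <- function(populations = sim_populations(),
                       n_chromosomes = 3,
                       chromosome_length_bp = 6e5,
                       n_loci = 50000,
                       cluster_f = c(broiler = 0.10, layer = 0.10, wild = 0.02),
                       cluster_f_default = 0.15,
                       outgroup_divergence = 0.85,
                       outgroup_private_fraction = 0.10,
                       sfs_truncation = 0.001,
                       prob_ref_ancestral = 0.86,
                       exonic_fraction = 0.05,
                       exon_length_bp = 2000,
                       map_rate_cM_per_Mb = 3,
                       map_jitter = 0.3,
                       map_anchor_spacing_bp = 5e4,
                       quality_mean = 80,
                       quality_sd = 15,
                       seed = 1L) {
  if (!is.data.frame(populations) ||
      !all(c("name", "cluster", "f", "mode", "n", "depth",
             "is_outgroup") %in% names(populations))) {
    abort_config("`populations` must be a table as built by sim_populations()")
  }
  if (anyDuplicated(populations$name)) {
    abort_config("population names must be unique")
  }
  if (sum(populations$is_outgroup) != 1L) {
    abort_config("exactly one population must be flagged as the outgroup")
  }
  if (!all(populations$mode %in% c("individual", "pool"))) {
    abort_config("observation mode must be 'individual' or 'pool'")
  }
  if (!all(populations$f > 0 & populations$f < 1)) {
    abort_config("all population drift parameters must lie in (0, 1)")
  }
  if (n_loci < 1) abort_config("`n_loci` must be at least 1")
  if (n_chromosomes < 1 || chromosome_length_bp <= 0) {
    abort_config("genome layout must have positive dimensions")
  }
  if (!(outgroup_divergence > 0 && outgroup_divergence < 1)) {
    abort_config("`outgroup_divergence` must lie in (0, 1)")
  }
  if (!(sfs_truncation > 0 && sfs_truncation < 0.5)) {
    abort_config("`sfs_truncation` must lie in (0, 0.5)")
  }
  if (!(exonic_fraction > 0 && exonic_fraction < 1)) {
    abort_config("`exonic_fraction` must lie in (0, 1)")
  }
  if (map_rate_cM_per_Mb <= 0) abort_config("map rate must be positive")
  structure(list(
    populations = as_tibble(populations),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = as.integer(chromosome_length_bp),
    n_loci = as.integer(n_loci),
    cluster_f = cluster_f,
    cluster_f_default = cluster_f_default,
    outgroup_divergence = outgroup_divergence,
    outgroup_private_fraction = outgroup_private_fraction,
    sfs_truncation = sfs_truncation,
    prob_ref_ancestral = prob_ref_ancestral,
    exonic_fraction = exonic_fraction,
    exon_length_bp = exon_length_bp,
    map_rate_cM_per_Mb = map_rate_cM_per_Mb,
    map_jitter = map_jitter,
    map_anchor_spacing_bp = map_anchor_spacing_bp,
    quality_mean = quality_mean,
    quality_sd = quality_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

cluster_f_of <- function(config, cluster) {
  f <- unname(config$cluster_f[cluster])
  ifelse(is.na(f), config$cluster_f_default, f)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s) x %s bp, %d loci\n",
              x$n_chromosomes, format(x$chromosome_length_bp, big.mark = ","),
              x$n_loci))
  cat(sprintf("  populations: %d (%d outgroup), clusters: %s\n",
              nrow(x$populations), sum(x$populations$is_outgroup),
              paste(unique(x$populations$cluster), collapse = ", ")))
  cat(sprintf("  sfs truncation %.4g, outgroup divergence %.2f, seed %d\n",
              x$sfs_truncation, x$outgroup_divergence, x$seed))
  invisible(x)
}
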