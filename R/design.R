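#' Array design configuration
#'
#' Thresholds and switches of the five-step ascertainment procedure.
#'
#' @param quality_min Minimum per-locus variant quality (step 1).
#' @param maf_min Minimum minor allele frequency of the mean discovery-panel
#'   reference frequency (step 1).
#' @param coverage_sd_mult Keep loci with depth at most
#'   `mean + coverage_sd_mult * sd`, moments taken over all loci (step 1).
#' @param cluster_near_bp,cluster_far_bp SNP-cluster rule (step 2): a locus is
#'   removed when it has fewer than `cluster_near_bp` invariant sites on one
#'   side and fewer than `cluster_far_bp` on the other, distances measured to
#'   the nearest discovery-variable SNP.
#' @param backbone_min_dist_bp Minimum physical spacing of backbone SNPs.
#' @param target_density Target number of within-population segregating SNPs
#'   per cM during equal spacing (steps 3 and 5).
#' @param validation_min_pops A SNP must segregate in at least this many
#'   validation populations (step 4), defined relative to
#'   `validation_ref_group_size`; other group sizes scale the threshold
#'   proportionally (ceiling, minimum 1).
#' @param validation_ref_group_size Validation group size the threshold refers
#'   to.
#' @param use_backbone Whether step 3 starts from the common-SNP backbones.
#' @param spacing_multipliers Named per-cluster density multipliers for
#'   step 3 (default: all 1).
#' @param downsample_multipliers Named per-cluster density multipliers for
#'   step 5 (default: broiler-like lines at 3 x to compensate their lower
#'   linkage disequilibrium).
#' @param seg_tol Segregation tolerance: a frequency counts as segregating
#'   when it lies strictly inside `(seg_tol, 1 - seg_tol)` (default 0, i.e.
#'   strictly inside `(0, 1)`).
#' @return A list of class `design_config`.
#' @export
design_config <- function(quality_min = 60, maf_min = 0.05,
                          coverage_sd_mult = 3,
                          cluster_near_bp = 4, cluster_far_bp = 10,
                          backbone_min_dist_bp = 2000,
                          target_density = 667,
                          validation_min_pops = 8,
                          validation_ref_group_size = 19,
                          use_backbone = TRUE,
                          spacing_multipliers = NULL,
                          downsample_multipliers = c(broiler = 3),
                          seg_tol = 0) {
  if (quality_min < 0 || maf_min < 0 || coverage_sd_mult <= 0 ||
      cluster_near_bp <= 0 || cluster_far_bp <= 0 ||
      backbone_min_dist_bp <= 0 || target_density < 0 ||
      validation_min_pops <= 0 || validation_ref_group_size <= 0) {
    abort_config("all design thresholds must be positive")
  }
  if (cluster_near_bp > cluster_far_bp) {
    abort_config("`cluster_near_bp` must not exceed `cluster_far_bp`")
  }
  structure(list(
    quality_min = quality_min, maf_min = maf_min,
    coverage_sd_mult = coverage_sd_mult,
    cluster_near_bp = cluster_near_bp, cluster_far_bp = cluster_far_bp,
    backbone_min_dist_bp = backbone_min_dist_bp,
    target_density = target_density,
    validation_min_pops = validation_min_pops,
    validation_ref_group_size = validation_ref_group_size,
    use_backbone = use_backbone,
    spacing_multipliers = spacing_multipliers,
    downsample_multipliers = downsample_multipliers,
    seg_tol = seg_tol
  ), class = "design_config")
}

new_snp_set <- function(locus, provenance, step) {
  ord <- order(locus)
  out <- tibble(locus = as.integer(locus[ord]),
                provenance = provenance[ord])
  attr(out, "step") <- step
  class(out) <- c("snp_set", class(out))
  out
}

#' @export
print.snp_set <- function(x, ...) {
  cat(sprintf("<snp_set> step '%s': %s loci\n", attr(x, "step"),
              format(nrow(x), big.mark = ",")))
  tags <- table(x$provenance)
  for (nm in names(tags)) cat(sprintf("  %s: %d\n", nm, tags[[nm]]))
  invisible(x)
}

# logical matrix: does each locus segregate in each of `pops`
segregating <- function(panel, pops, tol = 0) {
  f <- panel$freq[, pops, drop = FALSE]
  !is.na(f) & f > tol & f < 1 - tol
}

#' Step 1: discovery filter
#'
#' Keeps loci with quality at least `quality_min`, total depth at most
#' `mean + coverage_sd_mult * sd` (moments over all loci), and a discovery
#' panel MAF of at least `maf_min`, where the discovery-panel frequency is the
#' unweighted mean of the discovery populations' reference-allele frequencies
#' and MAF is `min(f, 1 - f)`.
#'
#' @param panel A `snp_panel`.
#' @param groups A `pop_groups` assignment.
#' @param cfg A [design_config()].
#' @return A `snp_set` labelled `"discovery"`.
#' @export
discovery_filter <- function(panel, groups, cfg = design_config()) {
  stopifnot_panel(panel)
  dpops <- group_pops(groups, "discovery")
  if (length(dpops) == 0) abort_config("discovery group is empty")
  q_ok <- panel$loci$quality >= cfg$quality_min
  depth <- panel$loci$depth
  d_ok <- depth <= mean(depth) + cfg$coverage_sd_mult * sd(depth)
  f <- rowMeans(panel$freq[, dpops, drop = FALSE])
  maf <- pmin(f, 1 - f)
  keep <- which(q_ok & d_ok & !is.na(maf) & maf >= cfg$maf_min)
  new_snp_set(keep, rep("discovery", length(keep)), "discovery")
}

#' Step 2: SNP-cluster removal
#'
#' Removes candidate loci sitting in tight SNP clusters: with `left` and
#' `right` the number of invariant sites flanking a locus (distance in bp to
#' the nearest discovery-variable SNP on that side minus one, chromosome ends
#' counting as infinite flanks), a locus is dropped iff
#' `(left < near and right < far)` or `(left < far and right < near)`.
#' Discovery-variable means any locus of the candidate (discovery-step) set.
#'
#' @inheritParams discovery_filter
#' @param candidate The step-1 `snp_set`.
#' @return A `snp_set` labelled `"cluster_removal"`.
#' @export
remove_clusters <- function(panel, candidate, cfg = design_config()) {
  stopifnot_panel(panel)
  if (nrow(candidate) == 0) abort_config("candidate set is empty")
  idx <- candidate$locus
  chrom <- panel$loci$chrom[idx]
  bp <- panel$loci$bp[idx]
  left <- rep(Inf, length(idx))
  right <- rep(Inf, length(idx))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (length(i) > 1) {
      gaps <- diff(bp[i]) - 1
      left[i[-1]] <- gaps
      right[i[-length(i)]] <- gaps
    }
  }
  near <- cfg$cluster_near_bp
  far <- cfg$cluster_far_bp
  drop <- (left < near & right < far) | (left < far & right < near)
  keep <- idx[!drop]
  new_snp_set(keep, rep("cluster_removal", length(keep)), "cluster_removal")
}

#' Backbone of common SNPs
#'
#' Among candidate loci segregating in every listed population (frequency
#' strictly inside `(seg_tol, 1 - seg_tol)`), a greedy left-to-right scan per
#' chromosome keeps a locus iff it is at least `min_dist_bp` from the last
#' kept locus.
#'
#' @inheritParams discovery_filter
#' @param candidate A `snp_set` of eligible loci.
#' @param populations Populations the backbone must segregate in.
#' @param min_dist_bp Minimum spacing in bp.
#' @param seg_tol Segregation tolerance (see [design_config()]).
#' @return A `snp_set` labelled `"backbone"` (possibly empty).
#' @export
build_backbone <- function(panel, candidate, populations,
                           min_dist_bp = 2000, seg_tol = 0) {
  stopifnot_panel(panel)
  if (length(populations) == 0) abort_config("backbone population list is empty")
  idx <- candidate$locus
  seg <- segregating(panel, populations, seg_tol)[idx, , drop = FALSE]
  eligible <- idx[rowSums(seg) == length(populations)]
  keep_mask <- logical(length(eligible))
  for (ch in unique(panel$loci$chrom[eligible])) {
    which_e <- which(panel$loci$chrom[eligible] == ch)
    pos <- panel$loci$bp[eligible[which_e]]
    last <- -Inf
    for (k in seq_along(which_e)) {
      if (pos[k] - last >= min_dist_bp) {
        keep_mask[which_e[k]] <- TRUE
        last <- pos[k]
      }
    }
  }
  keep <- eligible[keep_mask]
  new_snp_set(keep, rep("backbone", length(keep)), "backbone")
}

# Gap-filling part of the equal-spacing and downsampling steps.
#
# `seed_loci` (already-selected loci) freeze the gap grid: per chromosome the
# gaps are the open intervals between consecutive seed loci, bounded by the
# terminal map anchors. Populations are visited in a fixed order (sub-cluster
# order of first appearance, then panel order within cluster). For each gap
# the target count is round-half-up(density * multiplier * gap_cM) minus the
# number of already-selected loci inside the gap segregating in the current
# population; the remaining ideal points are placed equidistantly in cM inside
# the open gap, and each ideal point in order takes the unselected candidate
# locus segregating in the population with minimal |cM offset|, ties broken
# toward smaller bp.
fill_gaps <- function(panel, candidate, groups, map, density, multipliers,
                      selected, provenance, seg_tol = 0) {
  loci <- panel$loci
  cand <- setdiff(candidate$locus, which(selected))
  # fixed, documented iteration order: sub-cluster label (alphabetical),
  # then panel order within sub-cluster
  dpops_tbl <- groups %>%
    filter(.data$group == "discovery") %>%
    mutate(ord = match(.data$population, panel$pop_meta$name)) %>%
    arrange(.data$cluster, .data$ord)
  if (nrow(dpops_tbl) == 0) abort_config("discovery group is empty")
  missing_chr <- setdiff(unique(loci$chrom[candidate$locus]), unique(map$chrom))
  if (length(missing_chr) > 0) {
    abort_config(sprintf("map lacks chromosome(s): %s",
                         paste(missing_chr, collapse = ", ")))
  }
  seg <- segregating(panel, dpops_tbl$population, seg_tol)

  chroms <- unique(loci$chrom)
  # frozen gap grid per chromosome
  grid <- lapply(chroms, function(ch) {
    anchors <- map[map$chrom == ch, ]
    seed_ch <- which(selected & loci$chrom == ch)
    seed_ch <- seed_ch[order(loci$bp[seed_ch])]
    bnd_bp <- c(anchors$bp[1] - 1L, loci$bp[seed_ch],
                anchors$bp[nrow(anchors)] + 1L)
    bnd_cm <- c(anchors$cM[1], loci$cM[seed_ch], anchors$cM[nrow(anchors)])
    list(bp = bnd_bp, cM = bnd_cm)
  })
  names(grid) <- chroms

  seed_mask <- selected   # part-one seed: gap boundaries, never counted inside
  for (pi in seq_len(nrow(dpops_tbl))) {
    pop <- dpops_tbl$population[pi]
    mult <- multipliers[dpops_tbl$cluster[pi]]
    mult <- if (length(mult) == 0 || is.na(mult)) 1 else unname(mult)
    seg_pop <- seg[, pop]
    for (ch in chroms) {
      g <- grid[[ch]]
      n_gaps <- length(g$bp) - 1L
      # candidates on this chromosome, segregating in pop, unselected
      cc <- cand[loci$chrom[cand] == ch & seg_pop[cand] & !selected[cand]]
      if (length(cc) == 0) next
      cc_bp <- loci$bp[cc]
      cc_cm <- loci$cM[cc]
      cc_gap <- findInterval(cc_bp, g$bp)
      # earlier gap-fill selections inside gaps, segregating in pop
      sel_ch <- which(selected & !seed_mask & loci$chrom == ch & seg_pop)
      sel_gap <- findInterval(loci$bp[sel_ch], g$bp)
      sel_inside <- tabulate(sel_gap[sel_gap >= 1 & sel_gap <= n_gaps],
                             nbins = n_gaps)
      by_gap <- split(seq_along(cc), cc_gap)
      by_gap <- by_gap[names(by_gap) %in% as.character(seq_len(n_gaps))]
      for (gname in names(by_gap)) {
        gi <- as.integer(gname)
        span <- g$cM[gi + 1L] - g$cM[gi]
        n_target <- round_half_up(density * mult * span) - sel_inside[gi]
        if (n_target <= 0) next
        ideal <- g$cM[gi] + seq_len(n_target) * span / (n_target + 1L)
        avail <- by_gap[[gname]]
        for (pt in ideal) {
          if (length(avail) == 0) break
          off <- abs(cc_cm[avail] - pt)
          best <- avail[order(off, cc_bp[avail])[1]]
          li <- cc[best]
          selected[li] <- TRUE
          provenance[li] <- paste0("gap-fill:", pop)
          avail <- avail[avail != best]
        }
      }
    }
  }
  list(selected = selected, provenance = provenance)
}

#' Step 3: equal spacing with common-SNP backbones
#'
#' Two-part reduction toward approximately equidistant spacing on the genetic
#' map. Part one (when `use_backbone`) selects a backbone of SNPs segregating
#' in all discovery populations at a minimum spacing of
#' `backbone_min_dist_bp`, complemented by one unspaced backbone per
#' discovery sub-cluster (every candidate SNP segregating in all of that
#' sub-cluster's populations). Part two iterates over the discovery
#' populations in a fixed
#' order and fills the gaps between consecutive part-one SNPs with the
#' candidate loci segregating in the current population closest to
#' equidistant cM positions, aiming at `target_density` segregating SNPs per
#' cM (times the sub-cluster's `spacing_multipliers` entry, default 1).
#'
#' @inheritParams discovery_filter
#' @param candidate The step-2 `snp_set`.
#' @param map A `genetic_map` covering all candidate loci.
#' @return A `snp_set` labelled `"equal_spacing"` with provenance tags
#'   `backbone-all`, `backbone-subgroup:<cluster>` and `gap-fill:<population>`.
#' @export
equal_spacing <- function(panel, candidate, groups, map,
                          cfg = design_config()) {
  stopifnot_panel(panel)
  selected <- logical(nrow(panel$loci))
  provenance <- rep(NA_character_, nrow(panel$loci))
  dpops <- group_pops(groups, "discovery")
  if (length(dpops) == 0) abort_config("discovery group is empty")
  if (cfg$use_backbone) {
    bb <- build_backbone(panel, candidate, dpops,
                         cfg$backbone_min_dist_bp, cfg$seg_tol)
    selected[bb$locus] <- TRUE
    provenance[bb$locus] <- "backbone-all"
    subclusters <- sort(unique(groups$cluster[groups$group == "discovery"]))
    for (sc in subclusters) {
      sc_pops <- groups$population[groups$group == "discovery" &
                                     groups$cluster == sc]
      # sub-cluster backbones carry no spacing constraint: every candidate
      # SNP segregating in all of the sub-cluster's populations joins
      bbs <- build_backbone(panel, candidate, sc_pops, 1, cfg$seg_tol)
      new <- bbs$locus[!selected[bbs$locus]]
      selected[new] <- TRUE
      provenance[new] <- paste0("backbone-subgroup:", sc)
    }
  }
  res <- fill_gaps(panel, candidate, groups, map, cfg$target_density,
                   cfg$spacing_multipliers %||% numeric(0),
                   selected, provenance, cfg$seg_tol)
  keep <- which(res$selected)
  new_snp_set(keep, res$provenance[keep], "equal_spacing")
}

#' Step 4: validation
#'
#' Keeps a candidate locus iff it segregates in at least
#' `validation_min_pops` validation populations. When the validation group
#' size differs from `validation_ref_group_size`, the threshold scales
#' proportionally: `ceiling(validation_min_pops / ref_size * group_size)`,
#' minimum 1.
#'
#' @inheritParams discovery_filter
#' @param candidate The step-3 `snp_set`.
#' @return A `snp_set` labelled `"validation"`.
#' @export
validate_snps <- function(panel, candidate, groups, cfg = design_config()) {
  stopifnot_panel(panel)
  vpops <- group_pops(groups, "validation")
  if (length(vpops) == 0) abort_config("validation group is empty")
  thr <- max(1L, ceiling(cfg$validation_min_pops /
                           cfg$validation_ref_group_size * length(vpops)))
  seg <- segregating(panel, vpops, cfg$seg_tol)[candidate$locus, ,
                                                drop = FALSE]
  keep <- candidate$locus[rowSums(seg) >= thr]
  new_snp_set(keep, rep("validation", length(keep)), "validation")
}

#' Step 5: downsampling with exon retention
#'
#' Like the equal-spacing step, but the part-one seed is the union of all
#' exonic candidate loci and the all-discovery-population backbone (no
#' sub-cluster backbones), and the gap-filling densities are scaled by
#' `downsample_multipliers` (default: broiler-like sub-clusters at 3 x).
#'
#' @inheritParams equal_spacing
#' @param candidate The step-4 `snp_set`.
#' @return A `snp_set` labelled `"downsampling"` with provenance tags
#'   `exonic-keep`, `backbone-all` and `gap-fill:<population>`.
#' @export
downsample <- function(panel, candidate, groups, map,
                       cfg = design_config()) {
  stopifnot_panel(panel)
  selected <- logical(nrow(panel$loci))
  provenance <- rep(NA_character_, nrow(panel$loci))
  exonic <- candidate$locus[panel$loci$exonic[candidate$locus]]
  selected[exonic] <- TRUE
  provenance[exonic] <- "exonic-keep"
  dpops <- group_pops(groups, "discovery")
  bb <- build_backbone(panel, candidate, dpops,
                       cfg$backbone_min_dist_bp, cfg$seg_tol)
  new <- bb$locus[!selected[bb$locus]]
  selected[new] <- TRUE
  provenance[new] <- "backbone-all"
  res <- fill_gaps(panel, candidate, groups, map, cfg$target_density,
                   cfg$downsample_multipliers %||% numeric(0),
                   selected, provenance, cfg$seg_tol)
  keep <- which(res$selected)
  new_snp_set(keep, res$provenance[keep], "downsampling")
}

#' Run the full five-step array design
#'
#' Executes discovery filtering, cluster removal, equal spacing, validation
#' and downsampling in order, collecting all intermediate SNP sets. The
#' procedure is deterministic given its inputs.
#'
#' @inheritParams equal_spacing
#' @param verbose Log per-step counts via `message()`.
#' @return An `array_design`: list with `steps` (named list of the five
#'   `snp_set`s), `counts` (tibble step/n), `config` and `groups`.
#' @export
design_array <- function(panel, groups, map, cfg = design_config(),
                         verbose = FALSE) {
  stopifnot_panel(panel)
  s1 <- discovery_filter(panel, groups, cfg)
  s2 <- remove_clusters(panel, s1, cfg)
  s3 <- equal_spacing(panel, s2, groups, map, cfg)
  s4 <- validate_snps(panel, s3, groups, cfg)
  s5 <- downsample(panel, s4, groups, map, cfg)
  steps <- list(discovery = s1, cluster_removal = s2, equal_spacing = s3,
                validation = s4, downsampling = s5)
  counts <- tibble(step = names(steps),
                   n = vapply(steps, nrow, integer(1), USE.NAMES = FALSE))
  if (verbose) {
    for (i in seq_len(nrow(counts))) {
      message(sprintf("%-15s %8d SNPs", counts$step[i], counts$n[i]))
    }
  }
  structure(list(steps = steps, counts = counts, config = cfg,
                 groups = groups),
            class = "array_design")
}

#' @export
print.array_design <- function(x, ...) {
  cat("<array_design>\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-16s %s SNPs\n", x$counts$step[i],
                format(x$counts$n[i], big.mark = ",")))
  }
  invisible(x)
}
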