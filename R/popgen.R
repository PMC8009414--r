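#' Expected heterozygosity
#'
#' Mean over loci of `2 p (1 - p)` with `p` the reference-allele frequency,
#' i.e. the expected heterozygosity under Hardy-Weinberg proportions. Invariant
#' to allele relabelling `p -> 1 - p`, and bounded by 0.5 for biallelic loci.
#'
#' @param p Numeric vector of reference-allele frequencies in `[0, 1]`.
#' @return A single H_exp value.
#' @export
#' @examples
#' expected_heterozygosity(c(0.5, 0.1))  # (0.5 + 0.18) / 2
expected_heterozygosity <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) {
    abort_stat("expected heterozygosity is undefined on an empty locus set")
  }
  mean(2 * p * (1 - p))
}

#' Overestimation of expected heterozygosity (OHE)
#'
#' Relative deviation of an ascertained SNP set's H_exp from the reference
#' H_exp: `(h_set - h_ref) / h_ref`. Zero means unbiased, one means the
#' ascertained set doubles the estimate.
#'
#' @param h_set H_exp computed on the ascertained SNP set.
#' @param h_ref H_exp computed on the reference set (must be > 0).
#' @return The OHE value(s); vectorized.
#' @export
#' @examples
#' ohe(0.15, 0.2)  # -0.25
ohe <- function(h_set, h_ref) {
  if (any(h_ref <= 0)) {
    abort_stat("OHE is undefined for a reference heterozygosity of zero")
  }
  (h_set - h_ref) / h_ref
}

#' Nei's standard genetic distance
#'
#' For biallelic loci with reference frequencies `p_x`, `p_y`:
#' `J_xy = mean(p_x p_y + (1-p_x)(1-p_y))`, `J_x`, `J_y` the within-population
#' homozygosities, and `D = -ln(J_xy / sqrt(J_x J_y))`. Returns `Inf` when the
#' populations share no alleles (`J_xy = 0`).
#'
#' @param px,py Reference-allele frequency vectors over the same loci.
#' @return Non-negative distance (up to floating tolerance).
#' @export
#' @examples
#' nei_distance(c(1, 0.5), c(1, 0.5))  # 0
nei_distance <- function(px, py) {
  if (length(px) != length(py)) abort_config("frequency vectors differ in length")
  ok <- !is.na(px) & !is.na(py)
  px <- px[ok]; py <- py[ok]
  if (length(px) == 0L) abort_stat("Nei distance undefined on an empty set")
  jxy <- mean(px * py + (1 - px) * (1 - py))
  jx <- mean(px^2 + (1 - px)^2)
  jy <- mean(py^2 + (1 - py)^2)
  if (jxy == 0) return(Inf)
  -log(jxy / sqrt(jx * jy))
}

#' Pairwise Nei distance matrix
#'
#' @param panel A `snp_panel`.
#' @param loci Optional locus indices; defaults to all loci.
#' @return Symmetric matrix of Nei's standard genetic distances.
#' @export
nei_matrix <- function(panel, loci = NULL) {
  stopifnot_panel(panel)
  f <- if (is.null(loci)) panel$freq else panel$freq[loci, , drop = FALSE]
  k <- ncol(f)
  d <- matrix(0, k, k, dimnames = list(colnames(f), colnames(f)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <- nei_distance(f[, i], f[, j])
    }
  }
  d
}

#' Infer the ancestral allele from wild populations
#'
#' Orients each locus by the weighted mean reference-allele frequency over
#' three populations close to the species' ancestral source (by default the
#' two wild populations and the outgroup, the outgroup weighted twice).
#' Under neutral evolution the major allele among these is most likely
#' ancestral: the reference allele is called ancestral iff the weighted
#' frequency is at least 0.5 (ties go to the reference).
#'
#' @param panel A `snp_panel`.
#' @param wild_pops Character vector of three population names, ordered; the
#'   default picks the panel's `is_wild` populations followed by the outgroup.
#' @param weights Positive weights, one per population (default `c(1, 1, 2)`).
#' @return The panel with `ancestral_is_ref` set.
#' @export
infer_ancestral <- function(panel, wild_pops = NULL, weights = c(1, 1, 2)) {
  stopifnot_panel(panel)
  if (is.null(wild_pops)) {
    wild_pops <- c(panel$pop_meta$name[panel$pop_meta$is_wild],
                   panel$pop_meta$name[panel$pop_meta$is_outgroup])
  }
  if (length(wild_pops) != length(weights)) {
    abort_config("`wild_pops` and `weights` must have equal length")
  }
  missing <- setdiff(wild_pops, panel$pop_meta$name)
  if (length(missing) > 0) {
    abort_config(sprintf("population(s) absent from panel: %s",
                         paste(missing, collapse = ", ")))
  }
  f <- panel$freq[, wild_pops, drop = FALSE]
  w <- as.numeric(f %*% weights) / sum(weights)
  panel$ancestral_is_ref <- w >= 0.5
  panel
}

#' Derived allele frequencies over a locus set
#'
#' Per locus, the mean reference-allele frequency over the chosen populations
#' is polarized by the inferred ancestral state: derived frequency is
#' `1 - f_ref` where the reference is ancestral and `f_ref` otherwise.
#'
#' @param panel A `snp_panel` with ancestral flags (see [infer_ancestral()]).
#' @param loci Optional locus indices or a `snp_set`; defaults to all loci.
#' @param populations Population names to average over; defaults to all.
#' @return Numeric vector of derived allele frequencies.
#' @export
derived_frequencies <- function(panel, loci = NULL, populations = NULL) {
  stopifnot_panel(panel)
  if (is.null(panel$ancestral_is_ref)) {
    abort_state("ancestral flags absent: run infer_ancestral() first")
  }
  idx <- resolve_loci(panel, loci)
  pops <- populations %||% panel$pop_meta$name
  f <- rowMeans(panel$freq[idx, pops, drop = FALSE], na.rm = TRUE)
  ifelse(panel$ancestral_is_ref[idx], 1 - f, f)
}

resolve_loci <- function(panel, loci) {
  if (is.null(loci)) return(seq_len(nrow(panel$loci)))
  if (inherits(loci, "snp_set")) return(loci$locus)
  as.integer(loci)
}

#' Derived allele-frequency spectrum
#'
#' Histogram of [derived_frequencies()] over equal-width bins on `[0, 1]`,
#' normalized to proportions. Loci at exactly 0 or 1 fall into the terminal
#' bins.
#'
#' @inheritParams derived_frequencies
#' @param bins Number of equal-width bins (default 50).
#' @param group_label,step_label Optional labels carried into the result for
#'   plotting and bookkeeping.
#' @return A tibble of class `afs_summary` with columns `bin`, `lo`, `hi`,
#'   `mid`, `density` (summing to one).
#' @export
derived_afs <- function(panel, loci = NULL, populations = NULL, bins = 50,
                        group_label = NA_character_,
                        step_label = NA_character_) {
  d <- derived_frequencies(panel, loci, populations)
  d <- d[!is.na(d)]
  if (length(d) == 0L) abort_stat("no loci to bin")
  bin <- pmin(pmax(ceiling(d * bins), 1L), bins)
  counts <- tabulate(bin, nbins = bins)
  edges <- seq(0, 1, length.out = bins + 1)
  out <- tibble(
    bin = seq_len(bins),
    lo = edges[-(bins + 1)],
    hi = edges[-1],
    mid = (edges[-(bins + 1)] + edges[-1]) / 2,
    density = counts / length(d),
    group = group_label,
    step = step_label
  )
  class(out) <- c("afs_summary", class(out))
  out
}

#' Per-population expected heterozygosity over a locus set
#'
#' @param panel A `snp_panel`.
#' @param loci Optional locus indices or `snp_set`; defaults to all loci.
#' @param populations Population names; defaults to all.
#' @return Tibble with columns `population`, `h_exp`.
#' @export
hexp_by_pop <- function(panel, loci = NULL, populations = NULL) {
  stopifnot_panel(panel)
  idx <- resolve_loci(panel, loci)
  pops <- populations %||% panel$pop_meta$name
  tibble(
    population = pops,
    h_exp = vapply(pops, function(p) {
      expected_heterozygosity(panel$freq[idx, p])
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' OHE per population and design step
#'
#' For every population and every step of an [array design][design_array],
#' computes the H_exp of the ascertained set, the H_exp of the reference set
#' (by default the full truth panel — the whole-genome analogue), and their
#' relative deviation (OHE).
#'
#' @param panel The truth `snp_panel` the design was run on.
#' @param design An `array_design`.
#' @param groups A population-group assignment from [assign_groups()].
#' @param reference_loci Locus indices of the reference set; default all.
#' @return A tibble with columns `population`, `group`, `step`, `h_set`,
#'   `h_ref`, `ohe`; steps are ordered as in the design.
#' @export
ohe_table <- function(panel, design, groups, reference_loci = NULL) {
  stopifnot_panel(panel)
  if (!inherits(design, "array_design")) {
    abort_config("`design` must be an <array_design>")
  }
  ref_idx <- reference_loci %||% seq_len(nrow(panel$loci))
  href <- hexp_by_pop(panel, ref_idx)
  rows <- lapply(names(design$steps), function(step) {
    set <- design$steps[[step]]
    h <- hexp_by_pop(panel, set)
    tibble(population = h$population, step = step, h_set = h$h_exp)
  })
  out <- bind_rows(rows) %>%
    left_join(href %>% dplyr::rename(h_ref = "h_exp"), by = "population") %>%
    left_join(groups %>% select("population", "group"), by = "population") %>%
    mutate(
      ohe = ohe(.data$h_set, .data$h_ref),
      step = factor(.data$step, levels = names(design$steps))
    ) %>%
    select("population", "group", "step", "h_set", "h_ref", "ohe")
  class(out) <- c("ohe_table", class(out))
  out
}
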