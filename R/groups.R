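#' Assign populations to design groups
#'
#' Splits the panel's populations into the four roles of the array design:
#' discovery (SNPs are ascertained from them), validation (draft array SNPs
#' must segregate in enough of them), application (genotyped with the final
#' array but never involved in its design) and outgroup (always the panel's
#' flagged outgroup population).
#'
#' In `"random"` mode the discovery and validation populations are drawn
#' uniformly without replacement from the non-outgroup populations. In
#' `"nearest"` mode the discovery set is seeded by the populations flagged
#' `is_seed` (the commercial-line analogues) and, for each seed in order, its
#' nearest not-yet-selected population by Nei's standard genetic distance is
#' added (a seed whose nearest neighbour is taken falls through to the
#' next-nearest), giving exactly twice as many discovery populations as seeds;
#' the remaining populations are split at random into validation and
#' application.
#'
#' @param panel A `snp_panel`.
#' @param n_discovery,n_validation Group sizes; the application group receives
#'   the remaining non-outgroup populations. In `"nearest"` mode
#'   `n_discovery` is ignored (it is `2 x` the number of seeds).
#' @param seed Optional integer seed for the random draws.
#' @param mode `"random"` or `"nearest"`.
#' @return A tibble of class `pop_groups` with columns `population`, `group`
#'   (factor: discovery, validation, application, outgroup) and `cluster`:
#'   the discovery sub-cluster label used for the sub-group backbones and
#'   density multipliers. In `"nearest"` mode this is the population's panel
#'   cluster (e.g. broiler/layer); in `"random"` mode the discovery set is
#'   split into two relatedness-sorted halves `sub1`/`sub2`, mirroring the
#'   layer and broiler sub-group backbones of the original design.
#'   Non-discovery populations keep their panel cluster label.
#' @export
#' @examples
#' cfg <- sim_config(populations = sim_populations(24), n_loci = 200)
#' panel <- simulate_panel(cfg)
#' assign_groups(panel, n_discovery = 8, n_validation = 8, seed = 7)
assign_groups <- function(panel, n_discovery = 8, n_validation = 19,
                          seed = NULL, mode = c("random", "nearest")) {
  stopifnot_panel(panel)
  mode <- match.arg(mode)
  meta <- panel$pop_meta
  outgroup <- meta$name[meta$is_outgroup]
  ingroup <- meta$name[!meta$is_outgroup]
  run <- function() {
    if (mode == "random") {
      if (n_discovery + n_validation >= length(ingroup)) {
        abort_config("group sizes leave no application populations")
      }
      disc <- sample(ingroup, n_discovery)
      rest <- setdiff(ingroup, disc)
      valid <- sample(rest, n_validation)
    } else {
      seeds <- meta$name[!meta$is_outgroup & meta$is_seed]
      if (length(seeds) == 0) {
        abort_config("nearest mode requires populations flagged `is_seed`")
      }
      d <- nei_matrix(panel)
      disc <- seeds
      for (s in seeds) {
        cand <- setdiff(ingroup, disc)
        if (length(cand) == 0) abort_config("no candidates left for nearest mode")
        disc <- c(disc, cand[which.min(d[s, cand])])
      }
      rest <- setdiff(ingroup, disc)
      if (n_validation >= length(rest)) {
        abort_config("group sizes leave no application populations")
      }
      valid <- sample(rest, n_validation)
    }
    app <- setdiff(rest, valid)
    out <- tibble(population = meta$name) %>%
      mutate(group = dplyr::case_when(
        .data$population %in% outgroup ~ "outgroup",
        .data$population %in% disc ~ "discovery",
        .data$population %in% valid ~ "validation",
        TRUE ~ "application"
      )) %>%
      mutate(group = factor(.data$group, levels = c(
        "discovery", "validation", "application", "outgroup"
      ))) %>%
      left_join(meta %>% select(population = "name", "cluster"),
                by = "population")
    if (mode == "random") {
      # a random discovery set has no natural layer/broiler split: form two
      # sub-clusters of (near-)equal size from relatedness-sorted halves,
      # mirroring the two sub-group backbones of the design
      di <- which(out$group == "discovery")
      ord <- di[order(out$cluster[di], di)]
      half <- ceiling(length(ord) / 2)
      out$cluster[ord] <- rep(c("sub1", "sub2"),
                              c(half, length(ord) - half))
    }
    out
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- c("pop_groups", class(out))
  out
}

group_pops <- function(groups, which) {
  groups$population[groups$group == which]
}
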