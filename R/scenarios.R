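new_sweep_result <- function(ohe, counts, type) {
  structure(list(ohe = ohe, counts = counts, type = type),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> type '%s': %d OHE record(s), %d design run(s)\n",
              x$type, nrow(x$ohe),
              nrow(dplyr::distinct(x$counts, dplyr::pick(-dplyr::any_of(c("step", "n")))))))
  invisible(x)
}

run_design_steps <- function(panel, groups, map, cfg, through) {
  s1 <- discovery_filter(panel, groups, cfg)
  steps <- list(discovery = s1)
  if (through != "discovery") {
    steps$cluster_removal <- remove_clusters(panel, s1, cfg)
  }
  if (through %in% c("equal_spacing", "validation", "downsampling")) {
    steps$equal_spacing <- equal_spacing(panel, steps$cluster_removal,
                                         groups, map, cfg)
  }
  if (through %in% c("validation", "downsampling")) {
    steps$validation <- validate_snps(panel, steps$equal_spacing, groups, cfg)
  }
  if (through == "downsampling") {
    steps$downsampling <- downsample(panel, steps$validation, groups, map, cfg)
  }
  counts <- tibble(step = names(steps),
                   n = vapply(steps, nrow, integer(1), USE.NAMES = FALSE))
  structure(list(steps = steps, counts = counts, config = cfg,
                 groups = groups),
            class = "array_design")
}

#' Repeat the design with random population groupings
#'
#' Runs the whole five-step design repeatedly with populations randomly
#' assigned to the discovery, validation and application groups (the outgroup
#' is always kept as the outgroup) and records the OHE of every population at
#' every step. Replicate seeds are derived from the master seed plus the
#' replicate index, so the sweep is reproducible and order-independent.
#'
#' @param panel A `snp_panel`.
#' @param map A `genetic_map`.
#' @param cfg A [design_config()].
#' @param n_reps Number of random groupings.
#' @param sizes Integer pair: discovery and validation group sizes; the
#'   application group receives the rest.
#' @param seed Master seed.
#' @param through Last design step to run (default the full chain).
#' @return A `sweep_result` with `$ohe` (population, group, replicate, step,
#'   h_set, h_ref, ohe) and `$counts` (replicate, step, n).
#' @export
run_random_groupings <- function(panel, map, cfg = design_config(),
                                 n_reps = 50, sizes = c(8, 19), seed = 1,
                                 through = "downsampling") {
  stopifnot_panel(panel)
  ohe_rows <- vector("list", n_reps)
  count_rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    groups <- assign_groups(panel, sizes[1], sizes[2], seed = seed + r)
    des <- run_design_steps(panel, groups, map, cfg, through)
    ot <- ohe_table(panel, des, groups) %>%
      mutate(replicate = r, seed = seed + r)
    ohe_rows[[r]] <- ot
    count_rows[[r]] <- des$counts %>% mutate(replicate = r)
  }
  new_sweep_result(bind_rows(ohe_rows), bind_rows(count_rows),
                   "random_groupings")
}

#' Sweep the number of discovery populations
#'
#' Varies the discovery-group size over `counts` with `reps` random groupings
#' per size; the remaining non-outgroup populations are split into validation
#' and application groups of equal size, an odd remainder going to
#' validation.
#'
#' @inheritParams run_random_groupings
#' @param counts Discovery-group sizes to sweep.
#' @param reps Random groupings per size.
#' @return A `sweep_result`; `$ohe` gains an `n_discovery` column.
#' @export
sweep_discovery_count <- function(panel, map, cfg = design_config(),
                                  counts = seq(4, 40, by = 4), reps = 20,
                                  seed = 1, through = "downsampling") {
  stopifnot_panel(panel)
  n_in <- sum(!panel$pop_meta$is_outgroup)
  if (max(counts) >= n_in) {
    abort_config("discovery counts must be below the non-outgroup population count")
  }
  ohe_rows <- list()
  count_rows <- list()
  for (ci in seq_along(counts)) {
    nd <- counts[ci]
    nv <- ceiling((n_in - nd) / 2)
    for (r in seq_len(reps)) {
      rep_seed <- seed + 1000L * ci + r
      groups <- assign_groups(panel, nd, nv, seed = rep_seed)
      des <- run_design_steps(panel, groups, map, cfg, through)
      ot <- ohe_table(panel, des, groups) %>%
        mutate(n_discovery = nd, replicate = r, seed = rep_seed)
      ohe_rows[[length(ohe_rows) + 1L]] <- ot
      count_rows[[length(count_rows) + 1L]] <- des$counts %>%
        mutate(n_discovery = nd, replicate = r)
    }
  }
  new_sweep_result(bind_rows(ohe_rows), bind_rows(count_rows),
                   "discovery_count")
}

#' Sweep the equal-spacing target density
#'
#' Runs the design through the equal-spacing step over a grid of target
#' densities, with and/or without the initial common-SNP backbone, with
#' `reps` independent population groupings per density. Groupings are shared
#' between the backbone settings of a given (density, replicate) pair so the
#' on/off comparison is paired.
#'
#' @inheritParams run_random_groupings
#' @param densities Target densities (segregating SNPs per cM).
#' @param backbone Logical vector of backbone settings to run.
#' @param reps Groupings per density.
#' @return A `sweep_result`; `$ohe` gains `target_density` and `use_backbone`
#'   columns and contains the equal-spacing step only.
#' @export
sweep_density <- function(panel, map, cfg = design_config(),
                          densities = c(33, 100, 333, 1000, 3333),
                          backbone = c(TRUE, FALSE), reps = 20,
                          sizes = c(8, 19), seed = 1) {
  stopifnot_panel(panel)
  if (any(densities <= 0)) abort_config("densities must be positive")
  ohe_rows <- list()
  count_rows <- list()
  for (di in seq_along(densities)) {
    for (r in seq_len(reps)) {
      rep_seed <- seed + 1000L * di + r
      groups <- assign_groups(panel, sizes[1], sizes[2], seed = rep_seed)
      for (bb in backbone) {
        cfg_i <- cfg
        cfg_i$target_density <- densities[di]
        cfg_i$use_backbone <- bb
        des <- run_design_steps(panel, groups, map, cfg_i, "equal_spacing")
        ot <- ohe_table(panel, des, groups) %>%
          filter(.data$step == "equal_spacing") %>%
          mutate(target_density = densities[di], use_backbone = bb,
                 replicate = r, seed = rep_seed)
        ohe_rows[[length(ohe_rows) + 1L]] <- ot
        count_rows[[length(count_rows) + 1L]] <- des$counts %>%
          mutate(target_density = densities[di], use_backbone = bb,
                 replicate = r)
      }
    }
  }
  new_sweep_result(bind_rows(ohe_rows), bind_rows(count_rows), "density")
}
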