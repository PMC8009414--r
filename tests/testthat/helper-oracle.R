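# independent brute-force reference implementations; deliberately naive,
# written straight from the procedure definitions, sharing no code with R/

oracle_seg <- function(panel, locus, pop) {
  f <- panel$freq[locus, pop]
  !is.na(f) && f > 0 && f < 1
}

oracle_backbone <- function(panel, cand, pops, min_dist) {
  sel <- integer(0)
  for (ch in unique(panel$loci$chrom)) {
    last <- NULL
    for (l in cand[panel$loci$chrom[cand] == ch]) {
      ok <- all(vapply(pops, function(p) oracle_seg(panel, l, p), logical(1)))
      if (ok && (is.null(last) ||
                 panel$loci$bp[l] - panel$loci$bp[last] >= min_dist)) {
        sel <- c(sel, l)
        last <- l
      }
    }
  }
  sel
}

oracle_discovery_order <- function(panel, groups) {
  disc <- groups[groups$group == "discovery", ]
  disc[order(disc$cluster, match(disc$population, panel$pop_meta$name)), ]
}

oracle_equal_spacing <- function(panel, cand, groups, map, density,
                                 min_dist = 2000, use_backbone = TRUE,
                                 multipliers = c()) {
  L <- nrow(panel$loci)
  selected <- logical(L)
  disc <- oracle_discovery_order(panel, groups)
  if (use_backbone) {
    selected[oracle_backbone(panel, cand, disc$population, min_dist)] <- TRUE
    for (sc in sort(unique(disc$cluster))) {
      sc_pops <- disc$population[disc$cluster == sc]
      # sub-cluster backbones are unspaced
      selected[oracle_backbone(panel, cand, sc_pops, 1)] <- TRUE
    }
  }
  seed <- selected
  for (pi in seq_len(nrow(disc))) {
    pop <- disc$population[pi]
    mult <- multipliers[disc$cluster[pi]]
    mult <- if (length(mult) == 0 || is.na(mult)) 1 else unname(mult)
    for (ch in unique(panel$loci$chrom)) {
      anchors <- map[map$chrom == ch, ]
      seed_ch <- which(seed & panel$loci$chrom == ch)
      seed_ch <- seed_ch[order(panel$loci$bp[seed_ch])]
      bnd_bp <- c(anchors$bp[1] - 0.5, panel$loci$bp[seed_ch],
                  anchors$bp[nrow(anchors)] + 0.5)
      bnd_cm <- c(anchors$cM[1], panel$loci$cM[seed_ch],
                  anchors$cM[nrow(anchors)])
      for (g in seq_len(length(bnd_bp) - 1L)) {
        in_gap <- function(l) {
          panel$loci$chrom[l] == ch &&
            panel$loci$bp[l] > bnd_bp[g] && panel$loci$bp[l] < bnd_bp[g + 1L]
        }
        n_in <- 0L
        for (l in which(selected & !seed)) {
          if (in_gap(l) && oracle_seg(panel, l, pop)) n_in <- n_in + 1L
        }
        span <- bnd_cm[g + 1L] - bnd_cm[g]
        n <- floor(density * mult * span + 0.5) - n_in
        if (n <= 0) next
        for (k in seq_len(n)) {
          pt <- bnd_cm[g] + k * span / (n + 1)
          best <- NA_integer_
          best_off <- Inf
          for (l in cand) {
            if (selected[l] || !in_gap(l) || !oracle_seg(panel, l, pop)) next
            off <- abs(panel$loci$cM[l] - pt)
            if (off < best_off ||
                (off == best_off &&
                 panel$loci$bp[l] < panel$loci$bp[best])) {
              best <- l
              best_off <- off
            }
          }
          if (is.na(best)) break
          selected[best] <- TRUE
        }
      }
    }
  }
  which(selected)
}

# brute-force per-record allele tally from raw VCF text
oracle_vcf_freq <- function(lines, pop_map, sex_chromosomes = character()) {
  header <- lines[grepl("^#CHROM", lines)]
  cols <- strsplit(header, "\t")[[1]]
  samples <- cols[-(1:9)]
  recs <- lines[!grepl("^#", lines)]
  out <- list()
  for (rec in recs) {
    f <- strsplit(rec, "\t")[[1]]
    if (f[1] %in% sex_chromosomes) next
    if (grepl(",", f[5]) || nchar(f[4]) != 1 || nchar(f[5]) != 1) next
    fmt <- strsplit(f[9], ":")[[1]]
    freqs <- c()
    for (pop in unique(pop_map$population)) {
      rows <- pop_map[pop_map$population == pop, ]
      if (rows$mode[1] == "pool") {
        ref_d <- 0; tot_d <- 0
        for (s in rows$sample) {
          v <- strsplit(f[9 + match(s, samples)], ":")[[1]]
          ad <- as.numeric(strsplit(v[match("AD", fmt)], ",")[[1]])
          ref_d <- ref_d + ad[1]; tot_d <- tot_d + ad[1] + ad[2]
        }
        freqs[pop] <- if (tot_d > 0) ref_d / tot_d else NA_real_
      } else {
        nref <- 0; ncalled <- 0
        for (s in rows$sample) {
          v <- strsplit(f[9 + match(s, samples)], ":")[[1]]
          gt <- strsplit(gsub("\\|", "/", v[match("GT", fmt)]), "/")[[1]]
          if (all(gt %in% c("0", "1"))) {
            nref <- nref + sum(gt == "0")
            ncalled <- ncalled + 1
          }
        }
        freqs[pop] <- if (ncalled > 0) nref / (2 * ncalled) else NA_real_
      }
    }
    out[[length(out) + 1L]] <- c(chrom = f[1], pos = f[2], freqs)
  }
  out
}

# brute-force exonic membership: test every interval
oracle_exonic <- function(chrom, bp, intervals) {
  vapply(seq_along(bp), function(i) {
    any(intervals$chrom == chrom[i] &
          intervals$start <= bp[i] - 1 & bp[i] - 1 < intervals$end)
  }, logical(1))
}

# random toy instance for the equal-spacing oracle comparison
random_spacing_instance <- function(seed) {
  withr::with_seed(seed, {
    n_loci <- sample(6:15, 1)
    bp <- sort(sample.int(1e6, n_loci))
    freq <- cbind(
      P1 = round(runif(n_loci), 2),
      P2 = round(runif(n_loci), 2)
    )
    # force some fixation so segregation patterns differ between populations
    fix <- sample.int(n_loci, max(1, n_loci %/% 4))
    freq[fix, sample(1:2, length(fix), replace = TRUE)] <-
      sample(c(0, 1), length(fix), replace = TRUE)
    panel <- toy_panel(freq, bp = bp, cluster = c("a", "b"))
    map <- toy_map(len_bp = 1e6)
    groups <- tibble::tibble(
      population = c("P1", "P2"),
      group = factor("discovery",
                     levels = c("discovery", "validation", "application",
                                "outgroup")),
      cluster = c("a", "b")
    )
    density <- sample(c(1, 2, 5, 10), 1)
    use_backbone <- runif(1) < 0.5
    list(panel = panel, map = map, groups = groups, density = density,
         use_backbone = use_backbone)
  })
}

run_spacing_both <- function(inst) {
  cand <- arraybias:::new_snp_set(seq_len(nrow(inst$panel$loci)),
                                  rep("x", nrow(inst$panel$loci)), "candidate")
  cfg <- design_config(target_density = inst$density,
                       use_backbone = inst$use_backbone,
                       backbone_min_dist_bp = 2000)
  got <- equal_spacing(inst$panel, cand, inst$groups, inst$map, cfg)
  want <- oracle_equal_spacing(inst$panel, cand$locus, inst$groups, inst$map,
                               inst$density, 2000, inst$use_backbone)
  list(got = got$locus, want = want)
}
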