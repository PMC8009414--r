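# toy-panel builders used across test files

# hand-built panel: loci at given bp (one chromosome unless `chrom` given),
# frequency matrix with named population columns
toy_panel <- function(freq, bp = NULL, chrom = NULL, cM = NULL,
                      quality = 100, depth = 50, exonic = FALSE,
                      mode = "pool", cluster = NULL, outgroup = NULL,
                      seed_pops = NULL, wild_pops = NULL) {
  freq <- as.matrix(freq)
  L <- nrow(freq)
  pops <- colnames(freq)
  stopifnot(!is.null(pops))
  bp <- bp %||% seq(1000L, by = 1000L, length.out = L)
  chrom <- chrom %||% rep("chr1", L)
  cM <- cM %||% ((bp - 1) / 1e6)  # 1 cM/Mb, matching toy_map()
  loci <- tibble::tibble(
    chrom = chrom, bp = as.integer(bp), cM = cM,
    quality = rep_len(quality, L), depth = as.integer(rep_len(depth, L)),
    exonic = rep_len(exonic, L), ref = "A", alt = "C"
  )
  pop_meta <- tibble::tibble(
    name = pops,
    cluster = cluster %||% rep("c1", length(pops)),
    f = 0.1, mode = rep_len(mode, length(pops)), n = 10L, depth = 30,
    is_seed = pops %in% (seed_pops %||% character()),
    is_wild = pops %in% (wild_pops %||% character()),
    is_outgroup = pops %in% (outgroup %||% character())
  )
  snp_panel(loci, freq, pop_meta)
}

toy_map <- function(chrom = "chr1", len_bp = 1e6, rate = 1) {
  maps <- lapply(chrom, function(ch) {
    tibble::tibble(chrom = ch, bp = c(1L, as.integer(len_bp)),
                   cM = c(0, rate * (len_bp - 1) / 1e6))
  })
  new_genetic_map(dplyr::bind_rows(maps))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small default synthetic study shared by several test files; the genome is
# scaled with the locus count so per-bp and per-cM marker densities match the
# full-size default conditions
small_config <- function(n_pops = 24, n_loci = 4000, seed = 42, ...) {
  sim_config(populations = sim_populations(n_pops), n_loci = n_loci,
             chromosome_length_bp = max(1e4, round(6e5 * n_loci / 50000)),
             seed = seed, ...)
}
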