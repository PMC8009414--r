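#' Interpolate genetic-map positions
#'
#' Piecewise-linear interpolation of cM from bp on a per-chromosome anchor
#' list. Queries outside the anchor range are clamped to the terminal anchor's
#' cM with a warning; queries at anchors return the anchor cM exactly. Flat
#' map segments evaluate to the left anchor's cM.
#'
#' @param map A `genetic_map` (tibble with chrom, bp, cM).
#' @param chrom Chromosome of each query (recycled if length 1).
#' @param bp Base-pair positions (1-based).
#' @return Numeric cM positions, one per query.
#' @export
#' @examples
#' map <- new_genetic_map(tibble::tibble(chrom = "chr1",
#'                                       bp = c(1L, 1000001L), cM = c(0, 1)))
#' interpolate_cM(map, "chr1", 500001L)
interpolate_cM <- function(map, chrom, bp) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(bp))
  if (length(chrom) != length(bp)) {
    abort_config("`chrom` and `bp` must have equal length")
  }
  out <- rep(NA_real_, length(bp))
  clamped <- 0L
  for (ch in unique(chrom)) {
    anchors <- map[map$chrom == ch, ]
    if (nrow(anchors) == 0) {
      abort_config(sprintf("chromosome '%s' is absent from the map", ch))
    }
    i <- which(chrom == ch)
    q <- bp[i]
    lo <- q < anchors$bp[1]
    hi <- q > anchors$bp[nrow(anchors)]
    clamped <- clamped + sum(lo) + sum(hi)
    qc <- pmin(pmax(q, anchors$bp[1]), anchors$bp[nrow(anchors)])
    # bp anchors are strictly increasing; linear interpolation makes flat
    # segments evaluate to the (shared) anchor cM
    out[i] <- approx(anchors$bp, anchors$cM, xout = qc, method = "linear",
                     ties = "ordered")$y
  }
  if (clamped > 0) {
    warning(sprintf("%d position(s) outside the map range were clamped to terminal anchors",
                    clamped))
  }
  out
}

#' Attach map positions to a panel
#'
#' Fills the `cM` column of the loci table by interpolating the supplied map.
#'
#' @param panel A `snp_panel`.
#' @param map A `genetic_map`.
#' @return The panel with `cM` filled and the map attached.
#' @export
add_map_positions <- function(panel, map) {
  stopifnot_panel(panel)
  panel$loci$cM <- interpolate_cM(map, panel$loci$chrom, panel$loci$bp)
  panel$map <- map
  panel
}

#' Read / write a genetic map
#'
#' Tab-separated map exchange format with columns `chrom`, `bp`, `cM`.
#'
#' @param path File path.
#' @param map A `genetic_map`.
#' @return `read_genetic_map()` returns a `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          chrom = readr::col_character(),
                          bp = readr::col_integer(),
                          cM = readr::col_double()))
  new_genetic_map(df)
}

#' @rdname read_genetic_map
#' @export
write_genetic_map <- function(map, path) {
  readr::write_tsv(as_tibble(map), path)
  invisible(path)
}

#' Serialize a SNP panel to a directory
#'
#' Writes three tab-separated files: `loci.tsv` (per-locus metadata plus the
#' inferred ancestral flag when present), `freq.tsv` (reference-allele
#' frequency matrix, one named column per population) and `pop_meta.tsv`.
#' Generator-side truth is not serialized. `read_panel()` restores the panel;
#' frequencies round-trip at full double precision.
#'
#' @param panel A `snp_panel`.
#' @param dir Directory (created if needed).
#' @return `read_panel()` returns a `snp_panel`; `write_panel()` the directory.
#' @export
write_panel <- function(panel, dir) {
  stopifnot_panel(panel)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci <- panel$loci
  if (!is.null(panel$ancestral_is_ref)) {
    loci$ancestral_is_ref <- panel$ancestral_is_ref
  }
  readr::write_tsv(loci, file.path(dir, "loci.tsv"))
  readr::write_tsv(as_tibble(as.data.frame(panel$freq)),
                   file.path(dir, "freq.tsv"))
  readr::write_tsv(panel$pop_meta, file.path(dir, "pop_meta.tsv"))
  if (!is.null(panel$map)) {
    write_genetic_map(panel$map, file.path(dir, "map.tsv"))
  }
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  loci <- readr::read_tsv(file.path(dir, "loci.tsv"), show_col_types = FALSE)
  loci$bp <- as.integer(loci$bp)
  loci$depth <- as.integer(loci$depth)
  freq <- as.matrix(readr::read_tsv(file.path(dir, "freq.tsv"),
                                    show_col_types = FALSE))
  pop_meta <- readr::read_tsv(file.path(dir, "pop_meta.tsv"),
                              show_col_types = FALSE)
  anc <- NULL
  if ("ancestral_is_ref" %in% names(loci)) {
    anc <- loci$ancestral_is_ref
    loci$ancestral_is_ref <- NULL
  }
  map_path <- file.path(dir, "map.tsv")
  map <- if (file.exists(map_path)) read_genetic_map(map_path) else NULL
  new_snp_panel(loci, freq, pop_meta, ancestral_is_ref = anc, map = map)
}

#' Read per-population allele frequencies from a VCF
#'
#' Real-data entry point. Keeps biallelic SNP records only (multiallelic or
#' non-SNP records are skipped with a logged count) and excludes user-listed
#' non-autosomal chromosomes. For populations observed as pools the
#' reference-allele frequency is the summed reference allelic depth divided by
#' the summed total depth of the pool's samples; for individually genotyped
#' populations it is the reference-allele count over `2 x` called genotypes,
#' with missing genotypes excluded from the denominator. Records where a
#' population has no usable data get a missing frequency; use
#' [drop_missing_freq()] before design.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param pop_map Data frame with columns `sample`, `population`, `mode`
#'   (`"pool"` uses the AD field, `"individual"` the GT field).
#' @param sex_chromosomes Chromosome names to exclude (default none).
#' @return A `snp_panel` (cM column is `NA` until [add_map_positions()]).
#' @export
read_frequency_vcf <- function(path, pop_map, sex_chromosomes = character()) {
  pop_map <- as_tibble(pop_map)
  if (!all(c("sample", "population", "mode") %in% names(pop_map))) {
    abort_config("`pop_map` needs columns sample, population, mode")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fixed <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  keep <- !grepl(",", fixed$ALT, fixed = TRUE) &
    nchar(fixed$REF) == 1L & nchar(fixed$ALT) == 1L &
    fixed$REF %in% c("A", "C", "G", "T") & fixed$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(sprintf("skipped %d multiallelic/non-SNP record(s)", n_skipped))
  }
  autosomal <- !(fixed$CHROM %in% sex_chromosomes)
  keep <- keep & autosomal
  if (sum(!autosomal) > 0) {
    message(sprintf("excluded %d record(s) on non-autosomal chromosomes",
                    sum(!autosomal)))
  }
  if (!any(keep)) abort_format("no biallelic autosomal SNP records in VCF")

  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  has_ad <- "AD" %in% fmt_keys
  has_gt <- "GT" %in% fmt_keys
  if (!has_ad && !has_gt) {
    abort_format("VCF has neither AD nor GT FORMAT fields")
  }
  vcf_samples <- colnames(vcf@gt)[-1]
  missing_samples <- setdiff(pop_map$sample, vcf_samples)
  if (length(missing_samples) > 0) {
    abort_config(sprintf("samples absent from VCF: %s",
                         paste(missing_samples, collapse = ", ")))
  }

  gt <- if (has_gt) vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  ad <- if (has_ad) vcfR::extract.gt(vcf, element = "AD")[keep, , drop = FALSE]
  fixed <- fixed[keep, , drop = FALSE]
  L <- nrow(fixed)

  pops <- unique(pop_map$population)
  freq <- matrix(NA_real_, L, length(pops), dimnames = list(NULL, pops))
  modes <- character(length(pops))
  sizes <- integer(length(pops))
  for (j in seq_along(pops)) {
    rows <- pop_map[pop_map$population == pops[j], ]
    mode <- rows$mode[1]
    modes[j] <- mode
    sizes[j] <- nrow(rows)
    if (mode == "pool") {
      if (!has_ad) abort_format("pool populations require the AD field")
      ref_d <- matrix(0, L, nrow(rows))
      tot_d <- matrix(0, L, nrow(rows))
      for (k in seq_len(nrow(rows))) {
        parts <- strsplit(ad[, rows$sample[k]], ",", fixed = TRUE)
        ref_d[, k] <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
        alt_d <- suppressWarnings(as.numeric(vapply(parts, function(p) {
          if (length(p) >= 2L) p[2L] else NA_character_
        }, "")))
        tot_d[, k] <- ref_d[, k] + alt_d
      }
      tot <- rowSums(tot_d, na.rm = TRUE)
      ref <- rowSums(ref_d * !is.na(tot_d), na.rm = TRUE)
      freq[, j] <- ifelse(tot > 0, ref / tot, NA_real_)
    } else {
      if (!has_gt) abort_format("individual populations require the GT field")
      g <- gt[, rows$sample, drop = FALSE]
      ref_cnt <- matrix(NA_real_, L, ncol(g))
      for (k in seq_len(ncol(g))) {
        alleles <- strsplit(gsub("|", "/", g[, k], fixed = TRUE), "/",
                            fixed = TRUE)
        ref_cnt[, k] <- vapply(alleles, function(a) {
          a <- a[a %in% c("0", "1")]
          if (length(a) == 0L) NA_real_ else sum(a == "0")
        }, numeric(1))
      }
      called <- rowSums(!is.na(ref_cnt))
      freq[, j] <- ifelse(called > 0,
                          rowSums(ref_cnt, na.rm = TRUE) / (2 * called),
                          NA_real_)
    }
  }

  qual <- suppressWarnings(as.numeric(fixed$QUAL))
  loci <- tibble(
    chrom = fixed$CHROM,
    bp = as.integer(fixed$POS),
    cM = NA_real_,
    quality = ifelse(is.na(qual), 0, qual),
    depth = vcf_info_depth(fixed$INFO, L),
    exonic = FALSE,
    ref = fixed$REF,
    alt = fixed$ALT
  )
  ord <- order(loci$chrom, loci$bp)
  pop_meta <- tibble(name = pops, cluster = NA_character_, f = NA_real_,
                     mode = modes, n = sizes, depth = NA_real_,
                     is_seed = FALSE, is_wild = FALSE, is_outgroup = FALSE)
  new_snp_panel(loci[ord, ], freq[ord, , drop = FALSE], pop_meta)
}

vcf_info_depth <- function(info, n) {
  dp <- rep(NA_integer_, n)
  m <- regmatches(info, regexpr("(?:^|;)DP=([0-9]+)", info))
  has <- lengths(regmatches(info, gregexpr("(?:^|;)DP=", info))) > 0
  dp[has] <- as.integer(sub(".*DP=", "", m))
  ifelse(is.na(dp), 0L, dp)
}

#' Drop loci with missing frequencies
#'
#' Loci where any population has a missing frequency estimate are removed
#' panel-wide (with a logged count) so all downstream statistics share one
#' locus set.
#'
#' @param panel A `snp_panel`.
#' @return The filtered panel.
#' @export
drop_missing_freq <- function(panel) {
  stopifnot_panel(panel)
  bad <- rowSums(is.na(panel$freq)) > 0
  if (any(bad)) {
    message(sprintf("dropped %d locus/loci with missing frequencies", sum(bad)))
    panel <- subset_panel(panel, which(!bad))
  }
  panel
}

#' Read exonic intervals from a BED file
#'
#' Three-column BED: chromosome, start, end with 0-based half-open
#' coordinates. Malformed lines raise an error naming the line number.
#'
#' @param path BED file.
#' @return Tibble with columns `chrom`, `start`, `end` (0-based, half-open).
#' @export
read_exonic_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3) {
      abort_format(sprintf("BED line %d: fewer than 3 fields", rows[i]))
    }
    start <- suppressWarnings(as.integer(p[2]))
    end <- suppressWarnings(as.integer(p[3]))
    if (is.na(start) || is.na(end) || start < 0 || end <= start) {
      abort_format(sprintf("BED line %d: invalid interval [%s, %s)",
                           rows[i], p[2], p[3]))
    }
    out[[i]] <- tibble(chrom = p[1], start = start, end = end)
  }
  bind_rows(out)
}

#' Flag exonic loci from an interval set
#'
#' A locus is exonic iff its 0-based position `bp - 1` falls inside
#' `[start, end)` for some interval on its chromosome. Overlapping intervals
#' are merged first, so each locus is flagged once.
#'
#' @param panel A `snp_panel`.
#' @param intervals Tibble from [read_exonic_bed()].
#' @return The panel with its `exonic` column replaced.
#' @export
flag_exonic <- function(panel, intervals) {
  stopifnot_panel(panel)
  exonic <- logical(nrow(panel$loci))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, ]
    iv <- iv[order(iv$start, iv$end), ]
    # merge overlapping/adjacent half-open intervals
    merged <- list()
    cur_s <- iv$start[1]; cur_e <- iv$end[1]
    if (nrow(iv) > 1) {
      for (i in 2:nrow(iv)) {
        if (iv$start[i] <= cur_e) {
          cur_e <- max(cur_e, iv$end[i])
        } else {
          merged[[length(merged) + 1L]] <- c(cur_s, cur_e)
          cur_s <- iv$start[i]; cur_e <- iv$end[i]
        }
      }
    }
    merged[[length(merged) + 1L]] <- c(cur_s, cur_e)
    starts <- vapply(merged, `[`, numeric(1), 1L)
    ends <- vapply(merged, `[`, numeric(1), 2L)
    idx <- which(panel$loci$chrom == ch)
    pos0 <- panel$loci$bp[idx] - 1L
    hit <- findInterval(pos0, starts)
    exonic[idx] <- hit > 0 & pos0 < ends[pmax(hit, 1L)]
  }
  panel$loci$exonic <- exonic
  panel
}
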