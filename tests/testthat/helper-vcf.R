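# writes small VCF fixtures programmatically

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_record <- function(chrom, pos, ref, alt, qual, dp, sample_fields) {
  paste(c(chrom, pos, ".", ref, alt, qual, "PASS",
          paste0("DP=", dp), "GT:AD", sample_fields), collapse = "\t")
}

write_vcf <- function(lines, path = withr::local_tempfile(fileext = ".vcf",
                                                          .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

random_vcf_lines <- function(n_records, samples = c("S1", "S2", "S3", "S4")) {
  gts <- c("0/0", "0/1", "1/1", "./.")
  pos <- sort(sample.int(1e6, n_records))
  recs <- vapply(seq_len(n_records), function(i) {
    fields <- vapply(samples, function(s) {
      ad_ref <- sample(0:30, 1)
      ad_alt <- sample(0:30, 1)
      sprintf("%s:%d,%d", sample(gts, 1), ad_ref, ad_alt)
    }, character(1))
    ref <- sample(c("A", "C", "G", "T"), 1)
    vcf_record(sample(c("1", "2"), 1), pos[i],
               ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1),
               round(runif(1, 30, 100), 1), sample(10:200, 1), fields)
  }, character(1))
  c(vcf_header(samples), recs)
}
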