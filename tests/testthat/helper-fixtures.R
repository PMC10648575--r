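# small in-code fixture builders shared across test files

make_counts <- function(sample_id, alt, ref, chrom = "chr1", pos = 100L,
                        refal = "A", altal = "T") {
  site_count_table(data.frame(
    sample_id = sample_id, chrom = chrom, pos = pos, ref = refal,
    alt = altal, ref_count = ref, alt_count = alt,
    stringsAsFactors = FALSE))
}

write_vcf_fixture <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"))
  writeLines(c(header, lines), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, af, dp = 1000L) {
  paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT:AF:DP",
        sprintf("0/1:%s:%d", af, dp), sep = "\t")
}
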