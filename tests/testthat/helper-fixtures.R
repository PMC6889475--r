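## Small text fixtures built in code at test time.

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

## minimal VCF text from a list of record rows (already tab-joined strings)
vcf_text <- function(records, samples = c("s1", "s2", "s3", "s4")) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

vcf_record <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts), collapse = "\t")
}

## genotype strings from a dosage vector
gt_str <- function(d) {
  out <- c("0/0", "0/1", "1/1")[d + 1L]
  out[is.na(d)] <- "./."
  out
}

gff_fixture_lines <- function() {
  g <- function(chrom, type, start, end, attrs) {
    paste(chrom, "src", type, start, end, ".", "+", ".", attrs, sep = "\t")
  }
  c("##gff-version 3",
    g("1", "gene", 1000, 5000, "ID=g1;Name=G1"),
    g("1", "gene", 8000, 12000, "ID=g2;Name=G2"),
    g("1", "mRNA", 1000, 5000, "ID=g1.t1;Parent=g1"),
    g("1", "mRNA", 1200, 4800, "ID=g1.t2;Parent=g1"),
    g("2", "mRNA", 500, 900, "ID=g3.t1;Parent=g3"),
    g("2", "mRNA", 2000, 2500, "ID=g3.t2;Parent=g3"),
    g("1", "CDS", 1100, 1200, "ID=c1;Parent=g1.t1"),
    g("1", "CDS", 1300, 1400, "ID=c2;Parent=g1.t1"),
    g("1", "CDS", 1500, 1600, "ID=c3;Parent=g1.t1"),
    g("1", "CDS", 8100, 8200, "ID=c4;Parent=g2.t1"),
    g("2", "CDS", 510, 520, "ID=c5;Parent=g3.t1"),
    g("2", "CDS", 530, 540, "ID=c6;Parent=g3.t1"),
    g("2", "CDS", 2010, 2020, "ID=c7;Parent=g3.t2"),
    g("2", "CDS", 2030, 2040, "ID=c8;Parent=g3.t2"))
}

## SNP-array per-individual file content: 12 header lines then data
array_file_lines <- function(rows) {
  c(rep("# header filler", 11), "SNP Name\tAllele1\tAllele2", rows)
}

## a small deterministic pair table for region tests
pairs_table <- function(chrom, pos_a, pos_b, r2, base_threshold = 0.4) {
  out <- data.frame(chrom = as.character(chrom), pos_a = pos_a, pos_b = pos_b,
                    vid_a = paste0(chrom, "_", pos_a),
                    vid_b = paste0(chrom, "_", pos_b),
                    r2 = r2, stringsAsFactors = FALSE)
  attr(out, "base_threshold") <- base_threshold
  out
}

## a regions row in the shape build_regions() returns
region_row <- function(chrom, sid, pos, start, end, alone = FALSE, n_linked = 1L) {
  data.frame(chrom = as.character(chrom), sid = sid, pos = pos, start = start,
             end = end, alone = alone, n_linked = n_linked,
             stringsAsFactors = FALSE)
}

## features data.frame in the shape read_annotations() returns
features_df <- function(chrom, start, end, attributes = NULL, ftype = "gene") {
  data.frame(chrom = as.character(chrom), ftype = ftype, start = start,
             end = end,
             attributes = attributes %||% paste0("ID=f", seq_along(start)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
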