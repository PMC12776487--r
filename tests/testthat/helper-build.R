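# In-code fixture builders shared across test files.

blank_verdicts <- function(n) {
  m <- matrix(NA_character_, n, length(predictor_columns()),
              dimnames = list(NULL, predictor_columns()))
  tibble::as_tibble(m)
}

# a variant table with the full sidecar schema; `support` fills the first
# `support` predictor columns with pathogenic votes and the rest benign
make_variants <- function(n = 1, family_id = "FAM1", consequence = "missense",
                          gene = NULL, chrom = "chr1", pos = NULL,
                          maf_gnomad = NA_real_, maf_kg1000 = NA_real_,
                          maf_esp = NA_real_, support = NA_integer_,
                          cadd = NA_real_, splice = NA_real_) {
  pos <- pos %||% seq(1000L, by = 1000L, length.out = n)
  gene <- gene %||% sprintf("GENE%03d", seq_len(n))
  v <- tibble::tibble(
    family_id = rep_len(family_id, n),
    chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
    ref = "A", alt = "G",
    gene = rep_len(gene, n), hgvs_c = "", hgvs_p = "",
    consequence = rep_len(consequence, n), dbsnp_id = "NOVEL",
    maf_kg1000 = rep_len(maf_kg1000, n), maf_esp = rep_len(maf_esp, n),
    maf_gnomad = rep_len(maf_gnomad, n),
    cadd_phred = rep_len(cadd, n), splice_delta = rep_len(splice, n)
  )
  v$variant_key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  verd <- blank_verdicts(n)
  support <- rep_len(support, n)
  for (i in seq_len(n)) {
    if (!is.na(support[i])) {
      verd[i, ] <- as.list(c(rep("pathogenic", support[i]),
                             rep("benign", 11 - support[i])))
    }
  }
  dplyr::bind_cols(v, verd)
}

make_members <- function(family_id = "FAM1", proband_sex = "XX",
                         mother_present = TRUE, father_present = TRUE,
                         mother_affected = FALSE, father_affected = FALSE) {
  tibble::tibble(
    family_id = family_id,
    sample_id = c(paste0(family_id, "_P"),
                  if (mother_present) paste0(family_id, "_M") else NA_character_,
                  if (father_present) paste0(family_id, "_F") else NA_character_),
    role = c("proband", "mother", "father"),
    sex = c(proband_sex, "XX", "XY"),
    affected = c(TRUE, mother_affected, father_affected),
    present = c(TRUE, mother_present, father_present)
  )
}

make_calls <- function(variants, gt_proband, gt_mother, gt_father) {
  tibble::tibble(family_id = variants$family_id,
                 variant_key = variants$variant_key,
                 gt_proband = rep_len(gt_proband, nrow(variants)),
                 gt_mother = rep_len(gt_mother, nrow(variants)),
                 gt_father = rep_len(gt_father, nrow(variants)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# write a minimal hand-rolled VCF for io tests
write_test_vcf <- function(path, rows, samples) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}

write_test_sidecar <- function(path, variants) {
  readr::write_tsv(variants[, c("chrom", "pos", "ref", "alt", "gene", "hgvs_c",
                                "hgvs_p", "consequence", "dbsnp_id",
                                "maf_kg1000", "maf_esp", "maf_gnomad",
                                predictor_columns(), "cadd_phred",
                                "splice_delta")], path, progress = FALSE)
  path
}
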