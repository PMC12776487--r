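# Family VCFs and their annotation sidecars.
#
# A family's variants travel as a normalized single-ALT VCF plus a
# tab-separated sidecar keyed by chrom:pos:ref:alt that carries the
# annotations the pipeline consumes (consequence class, MAFs from three
# population databases, eleven binarised predictor verdicts, CADD, SpliceAI
# delta). Annotation happens upstream (VEP + dbNSFP style); this module only
# reads and writes.

sidecar_schema <- function() {
  c("chrom", "pos", "ref", "alt", "gene", "hgvs_c", "hgvs_p", "consequence",
    "dbsnp_id", maf_columns(), predictor_columns(), "cadd_phred", "splice_delta")
}

parse_gt <- function(gt) {
  core <- sub(":.*$", "", gt)
  core <- gsub("|", "/", core, fixed = TRUE)
  out <- rep("missing", length(core))
  out[core %in% "0/0"] <- "hom_ref"
  out[core %in% c("0/1", "1/0")] <- "het"
  out[core %in% "1/1"] <- "hom_alt"
  bad <- !is.na(core) & !core %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".", NA)
  if (any(bad)) {
    stop_normalization(sprintf("unsupported genotype call '%s'; input must be normalized to biallelic sites",
                               core[bad][[1]]))
  }
  out
}

format_gt <- function(gt) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")[gt]
}

read_sidecar <- function(path) {
  side <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(sidecar_schema(), names(side))
  if (length(missing_cols) > 0) {
    stop_format(paste0("sidecar is missing columns: ",
                       paste(missing_cols, collapse = ", ")))
  }
  side <- side[sidecar_schema()]
  side %>%
    mutate(across(dplyr::all_of(c(maf_columns(), "cadd_phred", "splice_delta")),
                  as.numeric),
           across(dplyr::all_of(c("hgvs_c", "hgvs_p")),
                  ~ tidyr::replace_na(.x, "")),
           pos = as.integer(.data$pos))
}

#' Read one family's VCF and annotation sidecar
#'
#' Loads a normalized, biallelic VCF for a single family together with its
#' annotation sidecar and a pedigree (from [read_ped()]), producing the
#' annotated-variant table and the per-member genotype calls used by the
#' rest of the pipeline. Records with more than one ALT allele raise a
#' normalization error; a variant without a sidecar row raises a
#' missing-annotation error; a VCF sample that the pedigree does not know
#' raises a pedigree-mismatch error. Members that are absent from the VCF
#' (e.g. the unavailable fathers of dyad families) keep `present = FALSE`
#' and all-missing calls.
#'
#' @param path Path to a VCF (v4.x) for one family.
#' @param sidecar Path to the tab-separated annotation sidecar.
#' @param pedigree Member table from [read_ped()] covering the VCF samples.
#' @return A list with elements `variants` (annotated-variant tibble),
#'   `calls` (one row per variant: `gt_proband`, `gt_mother`, `gt_father`)
#'   and `members` (the family's rows of the pedigree).
#' @export
read_family_vcf <- function(path, sidecar, pedigree) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_mat <- vcfR::getFIX(vcf)
  if (is.null(dim(fix_mat))) {
    # single-record files come back as a bare named vector
    fix_mat <- matrix(fix_mat, nrow = 1, dimnames = list(NULL, names(fix_mat)))
  }
  fix <- as.data.frame(fix_mat, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop_normalization("VCF contains multiallelic records; split them before import")
  }
  samples <- colnames(vcf@gt)[-1]
  unknown <- setdiff(samples, pedigree$sample_id)
  if (length(unknown) > 0) {
    stop_pedigree(paste0("VCF samples absent from pedigree: ",
                         paste(unknown, collapse = ", ")))
  }
  fam_ids <- unique(pedigree$family_id[pedigree$sample_id %in% samples])
  if (length(fam_ids) != 1) {
    stop_pedigree("VCF samples must all belong to one family")
  }
  members <- pedigree %>% filter(.data$family_id == fam_ids)

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gt_raw <- matrix(gt_raw, nrow = nrow(fix),
                   dimnames = list(NULL, samples))
  keys <- variant_key(fix$CHROM, fix$POS, fix$REF, fix$ALT)

  role_gt <- function(role) {
    row <- members[members$role == role, ]
    if (nrow(row) == 0 || !row$present[[1]] || !row$sample_id[[1]] %in% samples) {
      return(rep("missing", length(keys)))
    }
    parse_gt(gt_raw[, row$sample_id[[1]]])
  }
  calls <- tibble(
    family_id = fam_ids,
    variant_key = keys,
    gt_proband = role_gt("proband"),
    gt_mother = role_gt("mother"),
    gt_father = role_gt("father")
  )

  side <- read_sidecar(sidecar)
  side$variant_key <- variant_key(side$chrom, side$pos, side$ref, side$alt)
  missing_keys <- setdiff(keys, side$variant_key)
  if (length(missing_keys) > 0) {
    stop_missing_annotation(paste0("no sidecar annotation for: ",
                                   paste(missing_keys, collapse = ", ")))
  }
  variants <- tibble(variant_key = keys) %>%
    left_join(side, by = "variant_key") %>%
    mutate(family_id = fam_ids,
           dbsnp_id = if_else(is.na(.data$dbsnp_id) | .data$dbsnp_id == ".",
                              "NOVEL", .data$dbsnp_id)) %>%
    select(dplyr::all_of(c("family_id", "variant_key", sidecar_schema())))
  validate_variants(variants)
  list(variants = variants, calls = calls, members = members)
}

#' Write one family's variants back to VCF + sidecar
#'
#' Inverse of [read_family_vcf()]: emits a minimal VCF v4.3 with GT-only
#' genotype columns for the family's present members, and the annotation
#' sidecar in the frozen column schema. Round-tripping through
#' `write_family_vcf()` and [read_family_vcf()] reproduces the same domain
#' objects.
#'
#' @param variants Annotated-variant tibble for one family.
#' @param calls Genotype-call tibble for the same variants.
#' @param members Family member tibble.
#' @param vcf_path,sidecar_path Output paths.
#' @return The paths, invisibly.
#' @export
write_family_vcf <- function(variants, calls, members, vcf_path, sidecar_path) {
  stopifnot(nrow(variants) == nrow(calls))
  present <- members %>% filter(.data$present)
  roles <- intersect(c("proband", "mother", "father"), present$role)
  sample_ids <- vapply(roles, function(r) present$sample_id[present$role == r],
                       character(1))
  gt_cols <- vapply(roles, function(r) {
    format_gt(calls[[paste0("gt_", r)]])
  }, character(nrow(calls)))
  gt_cols <- matrix(gt_cols, nrow = nrow(calls),
                    dimnames = list(NULL, sample_ids))

  header <- c(
    "##fileformat=VCFv4.3",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  body <- apply(cbind(variants$chrom, variants$pos,
                      if_else(variants$dbsnp_id == "NOVEL", ".", variants$dbsnp_id),
                      variants$ref, variants$alt, ".", "PASS", ".", "GT", gt_cols),
                1, paste, collapse = "\t")
  writeLines(c(header, body), vcf_path)
  readr::write_tsv(variants[sidecar_schema()], sidecar_path, progress = FALSE)
  invisible(c(vcf = vcf_path, sidecar = sidecar_path))
}
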