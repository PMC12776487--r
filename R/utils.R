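# Shared vocabularies and small helpers.

#' Controlled vocabularies used across the package
#'
#' `predictor_tools()` returns the fixed panel of eleven in-silico
#' pathogenicity predictors whose binarised verdicts feed the consensus
#' vote; the order is the column order used throughout. `consequence_levels()`
#' returns the recognised transcript-consequence classes and
#' `protein_altering_consequences()` the subset retained by the consequence
#' filter. `genotype_levels()` and `inheritance_modes()` enumerate the
#' zygosity and segregation-mode vocabularies.
#'
#' @return A character vector.
#' @export
predictor_tools <- function() {
  c("ClinPred", "MetaRNN", "BayesDel_addAF", "REVEL", "CADD",
    "AlphaMissense", "MutPred2", "Polyphen2", "MutationAssessor",
    "MutationTaster", "SIFT")
}

#' @rdname predictor_tools
#' @export
predictor_columns <- function() {
  paste0("pred_", tolower(gsub("[^A-Za-z0-9]", "", predictor_tools())))
}

#' @rdname predictor_tools
#' @export
consequence_levels <- function() {
  c("missense", "frameshift", "stop_gained", "stop_lost", "start_gained",
    "start_lost", "splice_region", "inframe_indel", "synonymous", "other")
}

#' @rdname predictor_tools
#' @export
protein_altering_consequences <- function() {
  c("missense", "frameshift", "stop_gained", "stop_lost", "start_gained",
    "start_lost", "splice_region")
}

#' @rdname predictor_tools
#' @export
genotype_levels <- function() {
  c("hom_ref", "het", "hom_alt", "missing")
}

#' @rdname predictor_tools
#' @export
inheritance_modes <- function() {
  c("de_novo", "de_novo_homozygous_flagged", "ad_inherited_affected_parent",
    "ad_incomplete_penetrance", "ar_homozygous", "compound_het", "x_linked",
    "unknown_missing_parent", "mendelian_inconsistent", "unclassified")
}

maf_columns <- function() c("maf_kg1000", "maf_esp", "maf_gnomad")

#' Canonical variant key
#'
#' Builds the `chrom:pos:ref:alt` key that identifies a normalized variant
#' throughout the pipeline.
#'
#' @param chrom,pos,ref,alt Vectors describing the variant.
#' @return A character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Condition helpers -----------------------------------------------------

tf_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("triofunnel_", class), "triofunnel_error"), ...)
}

stop_format <- function(msg) tf_abort(msg, "format_error")
stop_usage <- function(msg) tf_abort(msg, "usage_error")
stop_config <- function(msg) tf_abort(msg, "config_error")
stop_normalization <- function(msg) tf_abort(msg, "normalization_error")
stop_missing_annotation <- function(msg) tf_abort(msg, "missing_annotation_error")
stop_pedigree <- function(msg) tf_abort(msg, "pedigree_mismatch_error")
stop_universe <- function(msg) tf_abort(msg, "universe_error")
stop_evaluation <- function(msg) tf_abort(msg, "evaluation_error")

is_x_chrom <- function(chrom) {
  toupper(sub("^chr", "", chrom, ignore.case = TRUE)) %in% c("X", "23")
}

is_carrier <- function(gt) gt %in% c("het", "hom_alt")

#' Validate a variant table
#'
#' Checks the structural invariants of an annotated-variant tibble: required
#' columns present, positions at least 1, `ref != alt`, a single ALT allele
#' per record (no comma-separated alleles), consequence values drawn from
#' [consequence_levels()], and all present allele frequencies inside
#' \eqn{[0, 1]}.
#'
#' @param variants A tibble of annotated variants.
#' @return The input, invisibly, if valid; otherwise an error is raised.
#' @export
validate_variants <- function(variants) {
  required <- c("family_id", "chrom", "pos", "ref", "alt", "gene",
                "consequence", maf_columns(), predictor_columns(),
                "cadd_phred", "splice_delta")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    stop_format(paste0("variant table is missing columns: ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (any(variants$pos < 1)) stop_format("variant positions must be >= 1")
  if (any(grepl(",", variants$alt, fixed = TRUE))) {
    stop_normalization("multiallelic records (comma-separated ALT) are not allowed; split before import")
  }
  if (any(variants$ref == variants$alt)) stop_format("ref and alt alleles must differ")
  bad_csq <- setdiff(unique(variants$consequence), consequence_levels())
  if (length(bad_csq) > 0) {
    stop_format(paste0("unknown consequence class: ", paste(bad_csq, collapse = ", ")))
  }
  mafs <- unlist(variants[maf_columns()], use.names = FALSE)
  mafs <- mafs[!is.na(mafs)]
  if (any(mafs < 0 | mafs > 1)) stop_format("allele frequencies must lie in [0, 1]")
  verdicts <- unlist(variants[predictor_columns()], use.names = FALSE)
  bad_v <- setdiff(unique(verdicts[!is.na(verdicts)]), c("pathogenic", "benign"))
  if (length(bad_v) > 0) {
    stop_format("predictor verdicts must be 'pathogenic', 'benign' or NA")
  }
  invisible(variants)
}
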