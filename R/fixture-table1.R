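# Packaged worked-example fixture: the published variant table of the nine
# index families (14 variant rows, 13 genes; two dyads with unavailable
# fathers). Printed coordinates, rsIDs, HGVS strings, zygosity, inheritance
# labels and predictor-support counts are transcribed verbatim. Fields the
# publication does not print are synthetic placeholders chosen to be
# consistent with the printed filtering outcome: ref/alt alleles for the
# three indels, and small gnomAD frequencies (1e-5) for rsID sites versus
# all-missing frequencies for the two novel sites.

#' Load the packaged nine-family worked-example fixture
#'
#' Returns the published 14-variant table of the nine syndromic
#' orofacial-cleft/limb-anomaly families as pipeline-ready objects: the
#' annotated-variant table (with an extra `reported_inheritance` column
#' carrying the published segregation label: `de_novo`, `unknown`,
#' `maternal`), the per-family genotype calls implied by the published
#' zygosity, labels and footnote (de novo rows: both parents `hom_ref`;
#' unknown rows: mother `hom_ref`, father absent; the maternally inherited
#' row: affected carrier mother), and the member table. Predictor verdicts
#' are expanded from the printed support count: the first *n* tools of
#' [predictor_tools()] vote pathogenic and the remainder benign; rows
#' printed `N/A` (frameshifts, and the two stop-gains gated by CADD) carry
#' missing verdicts.
#'
#' @return A list with elements `variants`, `calls`, `members`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_variants.tsv", package = "triofunnel")
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)

  verdicts <- matrix(NA_character_, nrow(raw), length(predictor_columns()),
                     dimnames = list(NULL, predictor_columns()))
  for (i in seq_len(nrow(raw))) {
    n <- raw$n_tools_pathogenic[[i]]
    if (!is.na(n)) {
      verdicts[i, ] <- c(rep("pathogenic", n), rep("benign", 11 - n))
    }
  }

  variants <- raw %>%
    mutate(variant_key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt),
           splice_delta = NA_real_,
           pos = as.integer(.data$pos)) %>%
    dplyr::bind_cols(as_tibble(verdicts)) %>%
    select(dplyr::all_of(c("family_id", "variant_key", sidecar_schema())),
           "reported_inheritance", "n_tools_pathogenic")
  validate_variants(variants)

  calls <- raw %>%
    mutate(variant_key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) %>%
    select("family_id", "variant_key") %>%
    mutate(gt_proband = raw$zygosity, gt_mother = raw$gt_mother,
           gt_father = raw$gt_father)

  fams <- raw %>%
    group_by(.data$family_id) %>%
    summarise(proband_sex = .data$proband_sex[[1]],
              mother_affected = any(.data$mother_affected),
              father_present = all(.data$father_present), .groups = "drop")
  members <- purrr::pmap_dfr(fams, function(family_id, proband_sex,
                                            mother_affected, father_present) {
    tibble(
      family_id = family_id,
      sample_id = c(paste0(family_id, "_P"), paste0(family_id, "_M"),
                    if (father_present) paste0(family_id, "_F") else NA_character_),
      role = c("proband", "mother", "father"),
      sex = c(proband_sex, "XX", "XY"),
      affected = c(TRUE, mother_affected, FALSE),
      present = c(TRUE, TRUE, father_present)
    )
  })

  list(variants = variants, calls = calls, members = members)
}

#' Path to the packaged synthetic interaction edge list
#'
#' Five interactions among the fixture's genes in the STRING export dialect
#' (0--1000 integer scores). The edge identities and scores are synthetic
#' stand-ins (a licensed interaction-database export cannot be packaged);
#' what they preserve exactly is the published network geometry over the 13
#' fixture genes: 13 nodes, 5 edges at the 0.150 confidence threshold, mean
#' node degree 0.769, and a single edge surviving the default 0.4 cutoff.
#'
#' @return A file path.
#' @export
synthetic_edge_file <- function() {
  system.file("extdata", "ppi_edges_synthetic.tsv", package = "triofunnel")
}

#' Path to the packaged synthetic demo gene sets (GMT)
#'
#' Small hand-written gene-set collection used in examples and the
#' end-to-end pipeline demo; set memberships are illustrative, not curated
#' ontology exports.
#'
#' @return A file path.
#' @export
demo_gmt_file <- function() {
  system.file("extdata", "gene_sets_demo.gmt", package = "triofunnel")
}
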