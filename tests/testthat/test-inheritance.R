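# Mendelian segregation classification.

classify_one <- function(p, m, f, members, chrom = "chr1") {
  v <- make_variants(1, chrom = chrom)
  calls <- make_calls(v, p, m, f)
  classify_inheritance(v, calls, members)
}

test_that("published family patterns classify as printed", {
  trio <- make_members()
  # de novo missense in a full trio
  expect_equal(classify_one("het", "hom_ref", "hom_ref", trio)$mode, "de_novo")
  # maternally inherited variant with an affected carrier mother
  aff_mother <- make_members(mother_affected = TRUE)
  call <- classify_one("het", "het", "hom_ref", aff_mother)
  expect_equal(call$mode, "ad_inherited_affected_parent")
  expect_equal(call$carrier_parent, "mother")
  # dyad with hom_ref mother: de novo cannot be asserted
  dyad <- make_members(father_present = FALSE)
  expect_equal(classify_one("het", "hom_ref", "missing", dyad)$mode,
               "unknown_missing_parent")
  # homozygous proband with hom_ref parents is flagged, not silently de novo
  flagged <- classify_one("hom_alt", "hom_ref", "hom_ref", trio)
  expect_equal(flagged$mode, "de_novo_homozygous_flagged")
  expect_match(flagged$notes, "artefact")
  # carrier parent without phenotype: incomplete penetrance
  expect_equal(classify_one("het", "hom_ref", "het", trio)$mode,
               "ad_incomplete_penetrance")
})

test_that("X-chromosome calls in XY probands follow hemizygous logic", {
  trio <- make_members(proband_sex = "XY")
  expect_equal(classify_one("het", "hom_ref", "hom_ref", trio, chrom = "chrX")$mode,
               "mendelian_inconsistent")
  xl <- classify_one("hom_alt", "het", "hom_ref", trio, chrom = "chrX")
  expect_equal(xl$mode, "x_linked")
  expect_equal(xl$carrier_parent, "mother")
  expect_equal(classify_one("hom_alt", "hom_ref", "hom_ref", trio, chrom = "chrX")$mode,
               "de_novo")
  # XX probands on X follow the autosomal table
  xx <- make_members(proband_sex = "XX")
  expect_equal(classify_one("het", "hom_ref", "hom_ref", xx, chrom = "chrX")$mode,
               "de_novo")
})

test_that("a non-carrier proband is a usage error", {
  v <- make_variants(1)
  expect_error(classify_inheritance(v, make_calls(v, "hom_ref", "het", "het"),
                                    make_members()),
               class = "triofunnel_usage_error")
})

test_that("classification matches the decision-table oracle exhaustively", {
  gts <- c("hom_ref", "het", "hom_alt")
  affected_patterns <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE),
                            c(TRUE, TRUE))
  presence <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE))
  for (p in c("het", "hom_alt")) for (m in gts) for (f in gts) {
    for (aff in affected_patterns) for (pres in presence) {
      members <- make_members(mother_present = pres[1], father_present = pres[2],
                              mother_affected = aff[1] && pres[1],
                              father_affected = aff[2] && pres[2])
      m_eff <- if (pres[1]) m else "missing"
      f_eff <- if (pres[2]) f else "missing"
      got <- classify_one(p, m, f, members)
      want <- oracle_classify(p, m_eff, f_eff,
                              m_aff = aff[1] && pres[1],
                              f_aff = aff[2] && pres[2])
      expect_equal(got$mode, want,
                   info = sprintf("p=%s m=%s f=%s aff=%s pres=%s", p, m, f,
                                  paste(aff, collapse = ","),
                                  paste(pres, collapse = ",")))
      # exhaustiveness: exactly one recognised mode
      expect_length(got$mode, 1)
      expect_true(got$mode %in% inheritance_modes())
    }
  }
  # X-linked cases against the oracle
  for (p in c("het", "hom_alt")) for (m in c(gts, "missing")) {
    members <- make_members(proband_sex = "XY",
                            mother_present = m != "missing")
    got <- classify_one(p, if (m == "missing") "hom_ref" else m, "hom_ref",
                        members, chrom = "chrX")
    expect_equal(got$mode, oracle_classify(p, m, "hom_ref", x_hemi = TRUE))
  }
})

test_that("missing parental calls demote de novo to unknown", {
  trio <- make_members()
  expect_equal(classify_one("het", "missing", "hom_ref", trio)$mode,
               "unknown_missing_parent")
  expect_equal(classify_one("het", "hom_ref", "missing", trio)$mode,
               "unknown_missing_parent")
  # but a carrier parent still supports dominant calls
  expect_equal(classify_one("het", "het", "missing", trio)$mode,
               "ad_incomplete_penetrance")
})

test_that("a tolerated parental miscall softens inconsistency", {
  trio <- make_members()
  v <- make_variants(1)
  calls <- make_calls(v, "hom_alt", "hom_ref", "het")
  expect_equal(classify_inheritance(v, calls, trio)$mode, "mendelian_inconsistent")
  soft <- classify_inheritance(v, calls, trio, tolerate_miscall = TRUE)
  expect_equal(soft$mode, "ar_homozygous")
  expect_match(soft$notes, "miscall")
})

test_that("compound hets pair trans variants and exclude cis", {
  trio <- make_members()
  v <- make_variants(2, gene = "GENEX", pos = c(100, 200))
  # v1 maternal-only, v2 paternal-only -> one trans pair
  calls <- make_calls(v, "het", c("het", "hom_ref"), c("hom_ref", "het"))
  pairs <- find_compound_hets(v, calls, trio)
  expect_equal(nrow(pairs), 1)
  expect_true(pairs$phased)
  expect_equal(pairs$carrier_parent, "both")
  # both maternal-only -> cis, no pair
  cis <- make_calls(v, "het", c("het", "het"), c("hom_ref", "hom_ref"))
  expect_equal(nrow(find_compound_hets(v, cis, trio)), 0)
  # different genes -> no pairing
  v2 <- make_variants(2, gene = c("G1", "G2"), pos = c(100, 200))
  expect_equal(nrow(find_compound_hets(v2, calls, trio)), 0)
})

test_that("compound hets in dyads are phase-unknown, never asserted", {
  dyad <- make_members(father_present = FALSE)
  v <- make_variants(2, gene = "GENEX", pos = c(100, 200))
  # mother carries one of the two: emitted as phase-unknown
  calls <- make_calls(v, "het", c("het", "hom_ref"), "missing")
  pairs <- find_compound_hets(v, calls, dyad)
  expect_equal(nrow(pairs), 1)
  expect_false(pairs$phased)
  expect_match(pairs$notes, "phase unknown")
  # mother carries both: presumed cis, suppressed
  both <- make_calls(v, "het", c("het", "het"), "missing")
  expect_equal(nrow(find_compound_hets(v, both, dyad)), 0)
})

test_that("cohort classification reproduces the published labels", {
  fx <- load_table1_fixture()
  res <- classify_cohort(fx$variants, fx$calls, fx$members)
  joined <- dplyr::left_join(
    tidy(res),
    dplyr::select(fx$variants, family_id, variant_key, reported_inheritance),
    by = c("family_id", "variant_key"))
  printed_to_mode <- c(de_novo = "de_novo", unknown = "unknown_missing_parent",
                       maternal = "ad_inherited_affected_parent")
  expected <- unname(printed_to_mode[joined$reported_inheritance])
  # the two published homozygous de novo rows carry the flagged mode
  hom <- fx$calls$gt_proband[match(joined$variant_key, fx$calls$variant_key)] == "hom_alt"
  expected[hom] <- "de_novo_homozygous_flagged"
  expect_equal(joined$mode, expected)
  g <- glance(res)
  expect_equal(g$n_de_novo + g$n_de_novo_homozygous_flagged, 11)
  expect_equal(g$n_unknown_missing_parent, 2)
  expect_equal(g$n_ad_inherited_affected_parent, 1)
})

test_that("an empty cohort classifies to empty output", {
  res <- classify_cohort(make_variants(0),
                         make_calls(make_variants(0), character(0),
                                    character(0), character(0)),
                         make_members())
  expect_equal(nrow(res$calls), 0)
  expect_equal(nrow(res$compound_hets), 0)
})
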