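# Mendelian segregation classification within trios and dyads.
#
# The classifier is a closed decision table over the proband/mother/father
# zygosity triple, parent presence, affected status, and chromosome.
# Conservative conventions: a de novo call requires both parents present
# with non-missing hom_ref calls; any unknown parental genotype demotes to
# unknown_missing_parent unless the known genotypes force a dominant or
# inconsistent call; a homozygous proband with hom_ref parents is flagged
# rather than silently accepted (two independent de novo hits at one site
# are implausible, yet the pattern occurs in real call sets).

#' Classify Mendelian inheritance of carrier-proband variants
#'
#' Applies the segregation decision table to every row of `calls`. The
#' proband must be a carrier (`het` or `hom_alt`) in every row; classifying
#' a `hom_ref` or missing proband genotype is a usage error (use
#' [classify_cohort()] for call sets that may contain them).
#'
#' Autosomal rules with both parents present: a het proband with two
#' `hom_ref` parents is `de_novo`; with exactly one carrier parent the call
#' is `ad_inherited_affected_parent` or `ad_incomplete_penetrance`
#' according to that parent's affected status; with two carrier parents the
#' dominant sub-mode is applied with `carrier_parent = "both"`. A
#' `hom_alt` proband with two carrier parents is `ar_homozygous`; with two
#' `hom_ref` parents it is `de_novo_homozygous_flagged` (annotated, not
#' resolved); a `hom_ref` x carrier parental pair is
#' `mendelian_inconsistent`. With an absent parent (or a missing parental
#' call) de novo status cannot be asserted: a `hom_ref` known parent under
#' a het proband gives `unknown_missing_parent`, while a carrier known
#' parent still supports the dominant sub-modes; under a `hom_alt` proband
#' a `hom_ref` known parent is `mendelian_inconsistent` (it cannot have
#' transmitted the allele) and a carrier known parent gives
#' `unknown_missing_parent`. On the X chromosome a het call in an XY
#' proband is `mendelian_inconsistent`; a hemizygous (`hom_alt`) call with
#' a carrier mother is `x_linked`, with a `hom_ref` present mother
#' `de_novo`.
#'
#' With `tolerate_miscall = TRUE` a single parental genotype is allowed to
#' be wrong before declaring inconsistency: the affected autosomal cases
#' are demoted to `ar_homozygous` (one `hom_ref` + one carrier parent under
#' a `hom_alt` proband) or `unknown_missing_parent` instead of
#' `mendelian_inconsistent`, with an explanatory note.
#'
#' @param variants Annotated-variant tibble (supplies `chrom` and `gene`).
#' @param calls Genotype-call tibble (`family_id`, `variant_key`,
#'   `gt_proband`, `gt_mother`, `gt_father`).
#' @param members Family member tibble as from [read_ped()].
#' @param tolerate_miscall Allow one parental miscall before declaring
#'   `mendelian_inconsistent`.
#' @return A tibble with one row per input call: `family_id`,
#'   `variant_key`, `gene`, `mode`, `carrier_parent`, `notes`.
#' @export
classify_inheritance <- function(variants, calls, members,
                                 tolerate_miscall = FALSE) {
  if (nrow(calls) == 0) {
    return(tibble(family_id = character(), variant_key = character(),
                  gene = character(), mode = character(),
                  carrier_parent = character(), notes = character()))
  }
  if (any(!calls$gt_proband %in% c("het", "hom_alt"))) {
    stop_usage("proband must be a carrier (het or hom_alt) in every call; nothing to classify otherwise")
  }

  fam_info <- members %>%
    tidyr::pivot_wider(id_cols = "family_id", names_from = "role",
                       values_from = c("present", "affected", "sex")) %>%
    select("family_id", mother_present = "present_mother",
           father_present = "present_father",
           mother_affected = "affected_mother",
           father_affected = "affected_father",
           proband_sex = "sex_proband")

  d <- calls %>%
    left_join(variants %>% select("family_id", "variant_key", "gene", "chrom") %>%
                distinct(), by = c("family_id", "variant_key")) %>%
    left_join(fam_info, by = "family_id")
  if (any(is.na(d$mother_present))) {
    stop_pedigree("calls reference families absent from the member table")
  }

  # effective parental genotypes: an absent parent is "missing"
  m <- if_else(d$mother_present, d$gt_mother, "missing")
  f <- if_else(d$father_present, d$gt_father, "missing")
  p <- d$gt_proband
  m_known <- m != "missing"; f_known <- f != "missing"
  m_car <- is_carrier(m);    f_car <- is_carrier(f)
  m_ref <- m == "hom_ref";   f_ref <- f == "hom_ref"
  x_hemi <- is_x_chrom(d$chrom) & d$proband_sex == "XY"
  dom_mode <- function(aff) if_else(aff, "ad_inherited_affected_parent",
                                    "ad_incomplete_penetrance")
  inconsistent_demote <- function(mode) {
    if (tolerate_miscall) rep("tolerated", length(p)) else mode
  }

  mode <- case_when(
    # --- X chromosome, XY proband (hemizygous logic) ---
    x_hemi & p == "het" ~ "mendelian_inconsistent",
    x_hemi & m_car ~ "x_linked",
    x_hemi & m_ref ~ "de_novo",
    x_hemi ~ "unknown_missing_parent",
    # --- heterozygous proband, autosomal (or XX proband on X) ---
    p == "het" & m_ref & f_ref ~ "de_novo",
    p == "het" & m_car & f_car ~ dom_mode(d$mother_affected | d$father_affected),
    p == "het" & m_car & (f_ref | !f_known) ~ dom_mode(d$mother_affected),
    p == "het" & f_car & (m_ref | !m_known) ~ dom_mode(d$father_affected),
    p == "het" ~ "unknown_missing_parent",
    # --- homozygous-alternate proband ---
    p == "hom_alt" & m_car & f_car ~ "ar_homozygous",
    p == "hom_alt" & m_ref & f_ref ~ "de_novo_homozygous_flagged",
    p == "hom_alt" & ((m_ref & f_car) | (m_car & f_ref)) ~
      if (tolerate_miscall) "ar_homozygous" else "mendelian_inconsistent",
    p == "hom_alt" & ((m_ref & !f_known) | (f_ref & !m_known)) ~
      if (tolerate_miscall) "unknown_missing_parent" else "mendelian_inconsistent",
    p == "hom_alt" ~ "unknown_missing_parent",
    .default = "unclassified"
  )

  carrier_parent <- case_when(
    x_hemi & mode %in% c("x_linked") ~ "mother",
    mode %in% c("de_novo", "de_novo_homozygous_flagged") ~ "none",
    m_car & f_car ~ "both",
    m_car ~ "mother",
    f_car ~ "father",
    mode == "mendelian_inconsistent" ~ "unknown",
    .default = "unknown"
  )

  notes <- character(nrow(d))
  notes[mode == "de_novo_homozygous_flagged"] <-
    "possible hemizygosity/CNV or genotyping artefact"
  notes[x_hemi & p == "het"] <- "heterozygous X call in XY proband"
  notes[x_hemi & mode == "de_novo"] <- "hemizygous de novo on X"
  both_carrier <- mode %in% c("ad_inherited_affected_parent",
                              "ad_incomplete_penetrance") & m_car & f_car
  notes[both_carrier] <- "both parents carry the allele"
  one_missing <- !x_hemi & (!m_known | !f_known)
  notes[one_missing & mode == "unknown_missing_parent"] <-
    "parental genotype unavailable; de novo status cannot be asserted"
  notes[one_missing & mode %in% c("ad_inherited_affected_parent",
                                  "ad_incomplete_penetrance")] <-
    "other parent genotype unavailable"
  notes[p == "hom_alt" & mode == "unknown_missing_parent" & (m_car | f_car)] <-
    "second parental genotype required to confirm recessive inheritance"
  if (tolerate_miscall) {
    tol <- (p == "hom_alt" & ((m_ref & f_car) | (m_car & f_ref))) |
      (p == "hom_alt" & ((m_ref & !f_known) | (f_ref & !m_known)))
    notes[tol] <- "assuming a single parental genotyping miscall"
  }

  tibble(family_id = d$family_id, variant_key = d$variant_key,
         gene = d$gene, mode = mode, carrier_parent = carrier_parent,
         notes = notes)
}

#' Find compound-heterozygous variant pairs
#'
#' Groups the proband's heterozygous variants by gene and pairs variants in
#' trans by parental origin: in full trios a pair qualifies iff one variant
#' is carried by the mother only and the other by the father only; pairs
#' carried on the same parental haplotype (cis) are excluded. When a parent
#' is absent or a parental call is missing, phase cannot be established:
#' pairs are then emitted with a phase-unknown note -- except pairs whose
#' two variants are both carried by the single available parent, which are
#' suppressed as presumed cis.
#'
#' @inheritParams classify_inheritance
#' @return A tibble with one row per qualifying pair: `family_id`, `gene`,
#'   `variant_key_1`, `variant_key_2`, `mode` (always `"compound_het"`),
#'   `phased`, `carrier_parent`, `notes`.
#' @export
find_compound_hets <- function(variants, calls, members) {
  empty <- tibble(family_id = character(), gene = character(),
                  variant_key_1 = character(), variant_key_2 = character(),
                  mode = character(), phased = logical(),
                  carrier_parent = character(), notes = character())
  if (nrow(calls) == 0) return(empty)

  d <- calls %>%
    filter(.data$gt_proband == "het") %>%
    left_join(variants %>% select("family_id", "variant_key", "gene") %>% distinct(),
              by = c("family_id", "variant_key")) %>%
    left_join(members %>%
                tidyr::pivot_wider(id_cols = "family_id", names_from = "role",
                                   values_from = "present") %>%
                select("family_id", mother_present = "mother",
                       father_present = "father"),
              by = "family_id") %>%
    mutate(gt_mother = if_else(.data$mother_present, .data$gt_mother, "missing"),
           gt_father = if_else(.data$father_present, .data$gt_father, "missing"))

  groups <- d %>% group_by(.data$family_id, .data$gene) %>% filter(n() >= 2)
  if (nrow(groups) == 0) return(empty)

  purrr::map_dfr(dplyr::group_split(groups), function(g) {
    phase_known <- all(g$gt_mother != "missing") && all(g$gt_father != "missing")
    m_car <- is_carrier(g$gt_mother)
    f_car <- is_carrier(g$gt_father)
    pairs <- utils::combn(seq_len(nrow(g)), 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(ij) {
      i <- ij[[1]]; j <- ij[[2]]
      if (phase_known) {
        trans <- (m_car[i] & !f_car[i] & f_car[j] & !m_car[j]) ||
                 (f_car[i] & !m_car[i] & m_car[j] & !f_car[j])
        if (!trans) return(NULL)
        tibble(family_id = g$family_id[[1]], gene = g$gene[[1]],
               variant_key_1 = g$variant_key[[i]],
               variant_key_2 = g$variant_key[[j]],
               mode = "compound_het", phased = TRUE, carrier_parent = "both",
               notes = "")
      } else {
        # single informative parent: suppress pairs it carries in cis
        known_m <- g$gt_mother != "missing"
        known_f <- g$gt_father != "missing"
        cis_via_mother <- all(known_m[c(i, j)]) && m_car[i] && m_car[j]
        cis_via_father <- all(known_f[c(i, j)]) && f_car[i] && f_car[j]
        if (cis_via_mother || cis_via_father) return(NULL)
        tibble(family_id = g$family_id[[1]], gene = g$gene[[1]],
               variant_key_1 = g$variant_key[[i]],
               variant_key_2 = g$variant_key[[j]],
               mode = "compound_het", phased = FALSE,
               carrier_parent = "unknown",
               notes = "phase unknown: parental genotypes incomplete")
      }
    })
  })
}

#' Classify a whole cohort and summarise by mode
#'
#' Runs [classify_inheritance()] on every carrier-proband call and
#' [find_compound_hets()] on every family/gene group. Variants where the
#' proband is not a carrier (possible under genotyping error) are excluded
#' from classification and counted.
#'
#' @inheritParams classify_inheritance
#' @return An object of class `cohort_inheritance`: list with `calls`,
#'   `compound_hets`, `summary` (counts by mode) and `n_noncarrier`. Has
#'   [tidy()] and [glance()] methods.
#' @export
classify_cohort <- function(variants, calls, members, tolerate_miscall = FALSE) {
  carrier <- calls$gt_proband %in% c("het", "hom_alt")
  cls <- classify_inheritance(variants, calls[carrier, , drop = FALSE], members,
                              tolerate_miscall = tolerate_miscall)
  ch <- find_compound_hets(variants, calls[carrier, , drop = FALSE], members)
  summary <- cls %>% count(.data$mode, name = "n") %>% arrange(.data$mode)
  structure(list(calls = cls, compound_hets = ch, summary = summary,
                 n_noncarrier = sum(!carrier)),
            class = "cohort_inheritance")
}

#' @export
print.cohort_inheritance <- function(x, ...) {
  cat(sprintf("<cohort_inheritance> %d calls, %d compound-het pairs\n",
              nrow(x$calls), nrow(x$compound_hets)))
  print(x$summary)
  invisible(x)
}

#' Tidiers for cohort inheritance results
#'
#' `tidy()` returns the per-variant inheritance calls; `glance()` a one-row
#' summary of counts by mode.
#'
#' @param x A `cohort_inheritance` object.
#' @param ... Unused.
#' @method tidy cohort_inheritance
#' @export
tidy.cohort_inheritance <- function(x, ...) x$calls

#' @rdname tidy.cohort_inheritance
#' @method glance cohort_inheritance
#' @export
glance.cohort_inheritance <- function(x, ...) {
  wide <- setNames(as.list(x$summary$n), paste0("n_", x$summary$mode))
  as_tibble(c(wide, list(n_compound_het_pairs = nrow(x$compound_hets),
                         n_noncarrier = x$n_noncarrier)))
}
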