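# The staged prioritisation funnel: consequence class -> rarity ->
# class-specific pathogenicity gate -> gene-panel tier annotation.

#' Configuration of the filtering funnel
#'
#' Thresholds for the staged variant filter. Defaults follow the published
#' analysis where stated (rarity below 0.01 against the maximum of the
#' present population frequencies, pathogenic votes from at least 6 of the
#' 11-predictor panel); the CADD gate (phred 20) and SpliceAI gate (delta
#' 0.5) use the conventional community cutoffs and are fully configurable.
#' `panel_genes`, when given, only annotates survivors with a
#' `known_phenotype_gene`/`other` tier -- it never discards a variant.
#'
#' @param maf_threshold Strict upper bound on the aggregated minor allele
#'   frequency (a variant at exactly the threshold fails).
#' @param consensus_min Minimum number of pathogenic predictor votes for a
#'   missense variant to survive.
#' @param consensus_total Size of the predictor panel (fixed at 11 tools).
#' @param cadd_min Minimum CADD phred score for stop/start gain-loss
#'   variants.
#' @param splice_min Minimum SpliceAI delta for splice-region variants.
#' @param panel_genes Optional character vector of phenotype-associated
#'   genes used for tier annotation.
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(maf_threshold = 0.01, consensus_min = 6L,
                           consensus_total = 11L, cadd_min = 20,
                           splice_min = 0.5, panel_genes = NULL) {
  if (!(maf_threshold > 0 && maf_threshold <= 1)) {
    stop_config("maf_threshold must lie in (0, 1]")
  }
  if (consensus_min < 0 || consensus_min > consensus_total + 1) {
    # consensus_min one above the panel size is allowed: it expresses
    # "no missense can pass", exercised by threshold property tests
    stop_config("consensus_min must lie in [0, consensus_total + 1]")
  }
  if (cadd_min < 0) stop_config("cadd_min must be nonnegative")
  if (splice_min < 0 || splice_min > 1) stop_config("splice_min must lie in [0, 1]")
  structure(list(maf_threshold = maf_threshold,
                 consensus_min = as.integer(consensus_min),
                 consensus_total = as.integer(consensus_total),
                 cadd_min = cadd_min, splice_min = splice_min,
                 panel_genes = panel_genes),
            class = "cascade_config")
}

#' Stage filters of the prioritisation funnel
#'
#' Vectorised pass/fail tests for the individual funnel stages.
#' `consequence_filter()` keeps protein-altering classes (missense,
#' frameshift, stop/start gain-loss, splice region). `rarity_filter()`
#' keeps variants whose maximum present population frequency is strictly
#' below the threshold; variants missing from every database (novel) pass.
#' `consensus_vote()` applies the majority vote over the 11-predictor panel
#' to missense variants (missing verdicts count toward the denominator but
#' never the numerator) and returns the support count alongside the
#' verdict. `lof_gate()` gates stop/start gain-loss variants on CADD and
#' `splice_gate()` gates splice-region variants on the SpliceAI delta; a
#' missing score fails the gate. Applying a class-specific gate to a
#' variant of the wrong class is a usage error.
#'
#' @param variants An annotated-variant tibble.
#' @param config A [cascade_config()].
#' @return `consequence_filter`, `rarity_filter`, `lof_gate` and
#'   `splice_gate` return a logical vector; `consensus_vote` returns a
#'   tibble with columns `variant_key`, `support`, `pass`.
#' @export
consequence_filter <- function(variants) {
  variants$consequence %in% protein_altering_consequences()
}

#' @rdname consequence_filter
#' @export
rarity_filter <- function(variants, config = cascade_config()) {
  maf <- as.matrix(variants[maf_columns()])
  max_maf <- apply(maf, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  is.na(max_maf) | max_maf < config$maf_threshold
}

#' @rdname consequence_filter
#' @export
consensus_vote <- function(variants, config = cascade_config()) {
  if (!all(variants$consequence == "missense")) {
    stop_usage("consensus_vote applies to missense variants only")
  }
  support <- rowSums(as.matrix(variants[predictor_columns()]) == "pathogenic",
                     na.rm = TRUE)
  tibble(variant_key = variants$variant_key,
         support = as.integer(support),
         pass = support >= config$consensus_min)
}

#' @rdname consequence_filter
#' @export
lof_gate <- function(variants, config = cascade_config()) {
  ok <- c("stop_gained", "stop_lost", "start_gained", "start_lost")
  if (!all(variants$consequence %in% ok)) {
    stop_usage("lof_gate applies to stop/start gain-loss variants only")
  }
  !is.na(variants$cadd_phred) & variants$cadd_phred >= config$cadd_min
}

#' @rdname consequence_filter
#' @export
splice_gate <- function(variants, config = cascade_config()) {
  if (!all(variants$consequence == "splice_region")) {
    stop_usage("splice_gate applies to splice-region variants only")
  }
  !is.na(variants$splice_delta) & variants$splice_delta >= config$splice_min
}

#' Run the full prioritisation funnel
#'
#' Applies the filter stages in fixed order -- consequence class, rarity,
#' class-specific pathogenicity gate (consensus vote for missense, CADD for
#' stop/start gain-loss, SpliceAI for splice region; frameshifts and
#' in-frame indels bypass the gate), then gene-panel tier annotation, which
#' never discards -- and returns the complete per-variant decision trace
#' together with per-stage survivor counts.
#'
#' @param variants An annotated-variant tibble (one or more families).
#' @param config A [cascade_config()].
#' @return A `funnel_report`: list with `decisions` (one row per input
#'   variant: stage outcomes `pass`/`fail`/`not_applicable`, the missense
#'   `support` count, the panel `tier`, the `final` verdict and `reasons`),
#'   `stage_counts` (survivors after each stage), `by_family`, and the
#'   `config` used. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
run_cascade <- function(variants, config = cascade_config()) {
  stages <- c("consequence", "rarity", "class_gate")
  if (nrow(variants) == 0) {
    report <- list(
      decisions = tibble(variant_key = character(), family_id = character(),
                         gene = character(), consequence = character(),
                         stage_consequence = character(), stage_rarity = character(),
                         stage_class_gate = character(), support = integer(),
                         tier = character(), final = logical(), reasons = character()),
      stage_counts = tibble(stage = c("input", stages), survivors = 0L),
      by_family = tibble(family_id = character(), n_input = integer(),
                         n_final = integer()),
      config = config)
    return(structure(report, class = "funnel_report"))
  }
  validate_variants(variants)

  csq <- variants$consequence
  p_consequence <- consequence_filter(variants)
  p_rarity <- rarity_filter(variants, config)

  support <- rep(NA_integer_, nrow(variants))
  gate <- rep("not_applicable", nrow(variants))
  is_mis <- csq == "missense"
  if (any(is_mis)) {
    vote <- consensus_vote(variants[is_mis, ], config)
    support[is_mis] <- vote$support
    gate[is_mis] <- if_else(vote$pass, "pass", "fail")
  }
  is_lof <- csq %in% c("stop_gained", "stop_lost", "start_gained", "start_lost")
  if (any(is_lof)) {
    gate[is_lof] <- if_else(lof_gate(variants[is_lof, ], config), "pass", "fail")
  }
  is_spl <- csq == "splice_region"
  if (any(is_spl)) {
    gate[is_spl] <- if_else(splice_gate(variants[is_spl, ], config), "pass", "fail")
  }
  # frameshift / inframe_indel / non-protein-altering classes carry no
  # class-specific score gate

  tier <- if (is.null(config$panel_genes)) {
    rep(NA_character_, nrow(variants))
  } else {
    if_else(variants$gene %in% config$panel_genes, "known_phenotype_gene", "other")
  }

  decisions <- tibble(
    variant_key = variants$variant_key,
    family_id = variants$family_id,
    gene = variants$gene,
    consequence = csq,
    stage_consequence = if_else(p_consequence, "pass", "fail"),
    stage_rarity = if_else(p_rarity, "pass", "fail"),
    stage_class_gate = gate,
    support = support,
    tier = tier
  )
  failed <- cbind(!p_consequence, !p_rarity, gate == "fail")
  decisions$final <- rowSums(failed) == 0
  reason_of <- function(i) {
    r <- stages[failed[i, ]]
    if (length(r) == 0) "retained" else paste0("failed: ", paste(r, collapse = ", "))
  }
  decisions$reasons <- vapply(seq_len(nrow(decisions)), reason_of, character(1))

  alive <- rep(TRUE, nrow(variants))
  survivors <- integer(length(stages))
  fails <- list(!p_consequence, !p_rarity, gate == "fail")
  for (i in seq_along(stages)) {
    alive <- alive & !fails[[i]]
    survivors[i] <- sum(alive)
  }
  stage_counts <- tibble(stage = c("input", stages),
                         survivors = c(nrow(variants), survivors))

  by_family <- decisions %>%
    group_by(.data$family_id) %>%
    summarise(n_input = n(), n_final = sum(.data$final), .groups = "drop")

  structure(list(decisions = decisions, stage_counts = stage_counts,
                 by_family = by_family, config = config),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  for (i in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  %-12s %d\n", x$stage_counts$stage[[i]],
                x$stage_counts$survivors[[i]]))
  }
  invisible(x)
}

#' Tidiers for funnel reports
#'
#' `tidy()` returns the per-variant decision trace; `glance()` the one-row
#' stage survivor summary.
#'
#' @param x A `funnel_report`.
#' @param ... Unused.
#' @method tidy funnel_report
#' @export
tidy.funnel_report <- function(x, ...) x$decisions

#' @rdname tidy.funnel_report
#' @method glance funnel_report
#' @export
glance.funnel_report <- function(x, ...) {
  wide <- setNames(as.list(x$stage_counts$survivors),
                   paste0("n_", x$stage_counts$stage))
  as_tibble(c(wide, list(n_families = nrow(x$by_family))))
}

#' Funnel plot of per-stage survivor counts
#'
#' @param object A `funnel_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot funnel_report
#' @export
autoplot.funnel_report <- function(object, ...) {
  counts <- object$stage_counts
  counts$stage <- factor(counts$stage, levels = counts$stage)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$stage, y = .data$survivors)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$survivors), vjust = -0.4) +
    ggplot2::labs(x = "funnel stage", y = "surviving variants",
                  title = "Variant prioritisation funnel") +
    ggplot2::theme_minimal()
}

#' Retained variants of a funnel run
#'
#' Convenience accessor: the rows of the input variant table whose funnel
#' decision was positive.
#'
#' @param variants The variant table passed to [run_cascade()].
#' @param report The resulting `funnel_report`.
#' @return A filtered variant tibble.
#' @export
surviving_variants <- function(variants, report) {
  keep <- report$decisions$final[match(
    paste(variants$family_id, variants$variant_key),
    paste(report$decisions$family_id, report$decisions$variant_key))]
  variants[keep %in% TRUE, ]
}
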