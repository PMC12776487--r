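# Scoring pipeline output against simulated ground truth.

#' Evaluate recovery of planted inheritance patterns
#'
#' Scores a cohort classification against the simulator's truth table. For
#' every planted variant the *expected* call is computed by running the
#' classifier on the true (pre-error) genotypes under the observed parent
#' availability -- so a de novo variant planted in a dyad family is
#' expected to be demoted to `unknown_missing_parent`, and recovering that
#' demotion counts as correct. Per-mode sensitivity is the fraction of
#' planted variants of that true mode whose call equals the expected call;
#' specificity is the fraction of variants with a different expected call
#' that were not called as that mode. Compound-heterozygous patterns are
#' scored at the pair level: recovered when the pair is reported
#' (trans-phased in trios, phase-unknown in dyads).
#'
#' @param result A `cohort_inheritance` from [classify_cohort()].
#' @param truth Truth tibble from [simulate_cohort()].
#' @param members Member table of the same cohort.
#' @param funnel Optional `funnel_report` over the same variants; adds a
#'   planted-survival concordance metric.
#' @return A list of class `recovery_metrics`: `metrics` (per-mode tibble
#'   with `n_true`, `n_recovered`, `sensitivity`, `specificity`),
#'   `confusion` (expected vs called counts), and scalar
#'   `funnel_planted_survival` when `funnel` is given.
#' @export
evaluate_recovery <- function(result, truth, members, funnel = NULL) {
  stopifnot(inherits(result, "cohort_inheritance"))
  calls <- result$calls
  bad_fams <- setdiff(calls$family_id, truth$family_id)
  if (length(bad_fams) > 0) {
    stop_evaluation(paste0("calls reference families absent from the truth table: ",
                           paste(bad_fams, collapse = ", ")))
  }

  # expected call: classifier on clean genotypes under observed availability
  planted <- truth %>% filter(.data$planted, .data$true_mode != "compound_het")
  expected <- if (nrow(planted) > 0) {
    clean_calls <- planted %>%
      mutate(gt_proband = .data$true_gt_proband,
             gt_mother = .data$true_gt_mother,
             gt_father = if_else(.data$is_dyad, "missing", .data$true_gt_father)) %>%
      select("family_id", "variant_key", "gt_proband", "gt_mother", "gt_father")
    clean_variants <- planted %>%
      mutate(chrom = "chr1") %>%
      select("family_id", "variant_key", "gene", "chrom")
    classify_inheritance(clean_variants, clean_calls, members) %>%
      select("family_id", "variant_key", expected_mode = "mode")
  } else {
    tibble(family_id = character(), variant_key = character(),
           expected_mode = character())
  }

  scored <- planted %>%
    left_join(expected, by = c("family_id", "variant_key")) %>%
    left_join(calls %>% select("family_id", "variant_key", called_mode = "mode"),
              by = c("family_id", "variant_key")) %>%
    mutate(recovered = !is.na(.data$called_mode) &
             .data$called_mode == .data$expected_mode)

  per_mode <- scored %>%
    group_by(.data$true_mode) %>%
    summarise(n_true = n(), n_recovered = sum(.data$recovered),
              sensitivity = if_else(n() > 0, sum(.data$recovered) / n(), NA_real_),
              .groups = "drop")

  # specificity per expected mode over all scored variants
  spec <- purrr::map_dfr(unique(scored$expected_mode), function(m) {
    neg <- scored %>% filter(.data$expected_mode != m)
    tibble(expected_mode = m,
           specificity = if (nrow(neg) == 0) NA_real_ else
             mean(is.na(neg$called_mode) | neg$called_mode != m))
  })
  per_mode <- per_mode %>%
    left_join(scored %>% distinct(.data$true_mode, .data$expected_mode) %>%
                group_by(.data$true_mode) %>% slice_head(n = 1) %>% ungroup(),
              by = "true_mode") %>%
    left_join(spec, by = "expected_mode")

  # compound-het pairs
  ch_truth <- truth %>% filter(.data$true_mode == "compound_het")
  if (nrow(ch_truth) > 0) {
    pairs <- ch_truth %>%
      group_by(.data$family_id, .data$pair_id) %>%
      summarise(key_a = min(.data$variant_key), key_b = max(.data$variant_key),
                .groups = "drop")
    found <- result$compound_hets %>%
      mutate(key_a = pmin(.data$variant_key_1, .data$variant_key_2),
             key_b = pmax(.data$variant_key_1, .data$variant_key_2))
    pairs$recovered <- paste(pairs$family_id, pairs$key_a, pairs$key_b) %in%
      paste(found$family_id, found$key_a, found$key_b)
    per_mode <- bind_rows(per_mode, tibble(
      true_mode = "compound_het", n_true = nrow(pairs),
      n_recovered = sum(pairs$recovered),
      sensitivity = mean(pairs$recovered),
      expected_mode = "compound_het",
      specificity = NA_real_))
  }

  confusion <- scored %>%
    count(.data$expected_mode, .data$called_mode, name = "n")

  out <- list(metrics = per_mode, confusion = confusion)
  if (!is.null(funnel)) {
    planted_keys <- paste(truth$family_id[truth$planted],
                          truth$variant_key[truth$planted])
    dec <- funnel$decisions
    surv <- dec$final[match(planted_keys, paste(dec$family_id, dec$variant_key))]
    out$funnel_planted_survival <- mean(surv, na.rm = TRUE)
  }
  structure(out, class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat("<recovery_metrics>\n")
  print(x$metrics)
  invisible(x)
}

#' @rdname evaluate_recovery
#' @param x A `recovery_metrics` object.
#' @param ... Unused.
#' @method tidy recovery_metrics
#' @export
tidy.recovery_metrics <- function(x, ...) x$metrics
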