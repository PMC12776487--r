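# The staged prioritisation funnel.

test_that("consequence filter keeps protein-altering classes only", {
  v <- make_variants(4, consequence = c("missense", "synonymous", "frameshift",
                                        "other"))
  expect_equal(consequence_filter(v), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("rarity filter takes the max over present sources, strict at the threshold", {
  cfg <- cascade_config()
  v <- make_variants(4,
                     maf_kg1000 = c(0.004, 0.009, NA, 0.01),
                     maf_esp    = c(0,     0.02,  NA, NA),
                     maf_gnomad = c(NA,    0.001, NA, 0.0099))
  # max per row: 0.004 -> pass; 0.02 -> fail; all missing (novel) -> pass;
  # 0.01 -> fail under strict inequality
  expect_equal(rarity_filter(v, cfg), c(TRUE, FALSE, TRUE, FALSE))
  expect_true(rarity_filter(make_variants(1, maf_gnomad = 0.0099999), cfg))
})

test_that("consensus vote counts pathogenic verdicts against the 11-tool panel", {
  cfg <- cascade_config()
  v <- make_variants(3, support = c(11L, 6L, 5L))
  vote <- consensus_vote(v, cfg)
  expect_equal(vote$support, c(11L, 6L, 5L))
  expect_equal(vote$pass, c(TRUE, TRUE, FALSE))
  # missing verdicts count toward the denominator but not the numerator
  v_missing <- make_variants(1)  # all verdicts NA
  expect_equal(consensus_vote(v_missing, cfg)$support, 0L)
  expect_false(consensus_vote(v_missing, cfg)$pass)
  expect_error(consensus_vote(make_variants(1, consequence = "frameshift"), cfg),
               class = "triofunnel_usage_error")
})

test_that("consensus vote equals a brute-force count on random panels", {
  set.seed(42)
  for (i in 1:50) {
    v <- make_variants(1)
    verdicts <- sample(c("pathogenic", "benign", NA), 11, replace = TRUE)
    v[predictor_columns()] <- as.list(verdicts)
    vote <- consensus_vote(v, cascade_config())
    expect_equal(vote$support, sum(verdicts == "pathogenic", na.rm = TRUE))
    expect_equal(vote$pass, sum(verdicts == "pathogenic", na.rm = TRUE) >= 6)
  }
})

test_that("CADD and splice gates respect thresholds and missing scores fail", {
  cfg <- cascade_config()
  lof <- make_variants(3, consequence = "stop_gained", cadd = c(35, 12, NA))
  expect_equal(lof_gate(lof, cfg), c(TRUE, FALSE, FALSE))
  spl <- make_variants(3, consequence = "splice_region", splice = c(0.8, 0.1, NA))
  expect_equal(splice_gate(spl, cfg), c(TRUE, FALSE, FALSE))
  expect_error(lof_gate(make_variants(1), cfg), class = "triofunnel_usage_error")
  expect_error(splice_gate(make_variants(1), cfg), class = "triofunnel_usage_error")
})

test_that("a hand-enumerated six-variant fixture leaves three survivors", {
  v <- dplyr::bind_rows(
    make_variants(1, consequence = "synonymous", pos = 1),
    make_variants(1, consequence = "missense", maf_gnomad = 0.05, support = 9,
                  pos = 2),
    make_variants(1, consequence = "missense", maf_gnomad = 0.001, support = 7,
                  pos = 3),
    make_variants(1, consequence = "missense", maf_gnomad = 0.001, support = 4,
                  pos = 4),
    make_variants(1, consequence = "frameshift", pos = 5),
    make_variants(1, consequence = "stop_gained", maf_gnomad = 0.002, cadd = 35,
                  pos = 6)
  )
  rep <- run_cascade(v)
  expect_equal(sum(rep$decisions$final), 3)
  expect_equal(rep$stage_counts$survivors, c(6L, 5L, 4L, 3L))
})

test_that("the packaged fixture survives the funnel in full", {
  fx <- load_table1_fixture()
  rep <- run_cascade(fx$variants)
  expect_true(all(rep$decisions$final))
  # an unreachable consensus threshold fails every missense variant
  strict <- run_cascade(fx$variants, cascade_config(consensus_min = 12))
  mis <- rep$decisions$consequence == "missense"
  expect_false(any(strict$decisions$final[mis]))
  expect_true(all(strict$decisions$final[!mis]))
})

test_that("funnel trace is complete and counts match the decisions", {
  co <- simulate_cohort(sim_config(n_families = 4, variants_per_family = 25,
                                   seed = 3))
  rep <- run_cascade(co$variants)
  expect_equal(nrow(rep$decisions), nrow(co$variants))
  expect_equal(anyDuplicated(paste(rep$decisions$family_id,
                                   rep$decisions$variant_key)), 0L)
  # survivor counts recomputed from the trace
  d <- rep$decisions
  alive1 <- d$stage_consequence == "pass"
  alive2 <- alive1 & d$stage_rarity == "pass"
  alive3 <- alive2 & d$stage_class_gate != "fail"
  expect_equal(rep$stage_counts$survivors,
               c(nrow(d), sum(alive1), sum(alive2), sum(alive3)))
  expect_equal(sum(d$final), sum(alive3))
  # counts are non-increasing along the funnel
  expect_true(all(diff(rep$stage_counts$survivors) <= 0))
})

test_that("relaxing thresholds is monotone in survivor counts", {
  co <- simulate_cohort(sim_config(n_families = 5, variants_per_family = 30,
                                   seed = 9))
  surv <- function(cfg) sum(run_cascade(co$variants, cfg)$decisions$final)
  maf_grid <- c(0.0001, 0.001, 0.01, 0.1, 1)
  s_maf <- vapply(maf_grid, function(t) surv(cascade_config(maf_threshold = t)),
                  numeric(1))
  expect_true(all(diff(s_maf) >= 0))
  cons_grid <- c(0, 3, 6, 9, 12)
  s_cons <- vapply(cons_grid, function(k) surv(cascade_config(consensus_min = k)),
                   numeric(1))
  expect_true(all(diff(s_cons) <= 0))
})

test_that("panel tier annotates without excluding, and empty input is allowed", {
  v <- make_variants(2, consequence = "missense", maf_gnomad = 0.001,
                     support = c(8L, 8L), gene = c("TP63", "NOVELGENE"))
  rep <- run_cascade(v, cascade_config(panel_genes = "TP63"))
  expect_equal(rep$decisions$tier, c("known_phenotype_gene", "other"))
  expect_true(all(rep$decisions$final))

  empty <- run_cascade(make_variants(0))
  expect_equal(nrow(empty$decisions), 0)
  expect_equal(empty$stage_counts$survivors, rep(0L, 4))
})

test_that("funnel report tidiers and plot work", {
  fx <- load_table1_fixture()
  rep <- run_cascade(fx$variants)
  expect_equal(nrow(tidy(rep)), 14)
  expect_equal(glance(rep)$n_input, 14)
  expect_s3_class(autoplot(rep), "ggplot")
})
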