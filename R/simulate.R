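# Synthetic annotated family cohorts with known ground truth.
#
# The generator emulates the structure of a small trio/dyad exome study:
# per-family variant tables with consequence classes, a three-database MAF
# panel, binarised predictor verdicts, and trio genotypes drawn under
# Mendelian transmission, with inheritance patterns planted at known truth.
# Dyads are produced by dropping the father after generation, so the truth
# table still records the full trio.

#' Simulation configuration
#'
#' @param n_families Number of families.
#' @param dyad_fraction Fraction of families whose father is dropped after
#'   generation (case-mother dyads). Default 2/9, the study design the
#'   generator emulates (seven trios, two dyads).
#' @param variants_per_family Total variant rows generated per family,
#'   planted rows included.
#' @param planted Named integer vector of patterns planted per family:
#'   `de_novo`, `ad_inherited`, `ad_incomplete`, `ar_homozygous`,
#'   `compound_het` (each compound-het pattern plants two variants).
#' @param maf_zero_weight Weight of the point mass at frequency 0 in the
#'   background MAF mixture; the remainder is log-uniform on
#'   `maf_log_range`.
#' @param maf_log_range Two-element range of the log-uniform background
#'   MAF component.
#' @param genotype_error_rate Per-call probability that a written genotype
#'   is replaced by one of the other two states (uniformly).
#' @param inbreeding_f Inbreeding coefficient applied to parental genotype
#'   draws (elevated homozygosity for consanguineous families); default 0.
#' @param seed Integer seed governing all randomness of the simulation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_families = 9, dyad_fraction = 2 / 9,
                       variants_per_family = 20,
                       planted = c(de_novo = 1, ad_inherited = 0,
                                   ad_incomplete = 0, ar_homozygous = 0,
                                   compound_het = 0),
                       maf_zero_weight = 0.2,
                       maf_log_range = c(1e-5, 0.5),
                       genotype_error_rate = 0,
                       inbreeding_f = 0,
                       seed = 1L) {
  modes <- c("de_novo", "ad_inherited", "ad_incomplete", "ar_homozygous",
             "compound_het")
  full <- setNames(integer(length(modes)), modes)
  full[names(planted)] <- as.integer(planted)
  if (any(is.na(full)) || any(full < 0)) stop_config("planted counts must be nonnegative")
  n_planted_rows <- sum(full) + full[["compound_het"]]
  if (n_planted_rows > variants_per_family) {
    stop_config("planted patterns exceed variants_per_family capacity")
  }
  if (dyad_fraction < 0 || dyad_fraction > 1) stop_config("dyad_fraction must lie in [0, 1]")
  if (maf_zero_weight < 0 || maf_zero_weight > 1) stop_config("maf_zero_weight must lie in [0, 1]")
  if (genotype_error_rate < 0 || genotype_error_rate > 1) stop_config("genotype_error_rate must lie in [0, 1]")
  if (inbreeding_f < 0 || inbreeding_f > 1) stop_config("inbreeding_f must lie in [0, 1]")
  structure(list(n_families = as.integer(n_families),
                 dyad_fraction = dyad_fraction,
                 variants_per_family = as.integer(variants_per_family),
                 planted = full, maf_zero_weight = maf_zero_weight,
                 maf_log_range = maf_log_range,
                 genotype_error_rate = genotype_error_rate,
                 inbreeding_f = inbreeding_f, seed = as.integer(seed)),
            class = "sim_config")
}

# parental genotype under HWE with inbreeding coefficient f
draw_parent_gt <- function(q, f) {
  p_hom_alt <- q^2 + f * q * (1 - q)
  p_het <- 2 * q * (1 - q) * (1 - f)
  u <- runif(length(q))
  if_else(u < p_hom_alt, "hom_alt", if_else(u < p_hom_alt + p_het, "het", "hom_ref"))
}

transmit <- function(gt) {
  # one allele drawn from a parent's genotype: probability of passing alt
  p_alt <- c(hom_ref = 0, het = 0.5, hom_alt = 1)[gt]
  if_else(runif(length(gt)) < p_alt, 1L, 0L)
}

child_gt <- function(gm, gf) {
  alt <- transmit(gm) + transmit(gf)
  c("hom_ref", "het", "hom_alt")[alt + 1L]
}

rand_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

verdict_row <- function(n_path) {
  # which tools vote pathogenic is a random draw of n_path of the panel
  v <- rep("benign", 11)
  if (n_path > 0) v[sample(11, n_path)] <- "pathogenic"
  v
}

#' Simulate an annotated cohort with planted inheritance patterns
#'
#' Generates `cfg$n_families` families. Background variants draw a
#' population MAF from the configured point-mass/log-uniform mixture,
#' predictor support concentrated below the consensus threshold (0--5
#' pathogenic votes for missense), and trio genotypes under Mendelian
#' transmission at a within-cohort sampling frequency clamped to
#' \eqn{[0.01, 0.5]} (sites are resampled until at least one family member
#' carries the allele, as in a real per-family call set). Planted variants
#' are protein-altering, rare or novel, carry 6--11 pathogenic votes, and
#' receive the genotype configuration of their pattern. Dyad families are
#' generated as full trios and the father dropped afterwards; genotype
#' errors are applied last, to the observed calls of present members.
#'
#' Given the same configuration (including seed) the result is identical,
#' and files written by [write_cohort()] are byte-identical.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_cohort`: list with `variants`, `calls`
#'   (observed, post dropping/error), `members`, `truth` (per-variant true
#'   mode, pre-error trio genotypes, dyad flag, compound-het pair id) and
#'   `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_dyads <- round(cfg$n_families * cfg$dyad_fraction)
  dyad_ids <- sample(cfg$n_families, n_dyads)

  all_variants <- list(); all_calls <- list(); all_truth <- list()
  all_members <- list()
  pair_counter <- 0L

  for (i in seq_len(cfg$n_families)) {
    fid <- sprintf("SIM%03d", i)
    is_dyad <- i %in% dyad_ids
    proband_sex <- sample(c("XX", "XY"), 1)

    plant_rows <- unlist(lapply(names(cfg$planted), function(m) {
      reps <- cfg$planted[[m]]
      if (m == "compound_het") rep(m, 2 * reps) else rep(m, reps)
    }))
    n_bg <- cfg$variants_per_family - length(plant_rows)
    n_var <- cfg$variants_per_family

    genes <- sample(sprintf("GENE%04d", seq_len(2000)), n_var)
    # compound-het pairs share a gene
    pair_id <- rep(NA_integer_, n_var)
    if (cfg$planted[["compound_het"]] > 0) {
      ch_idx <- which(plant_rows == "compound_het")
      for (p in seq_len(cfg$planted[["compound_het"]])) {
        idx <- ch_idx[c(2 * p - 1, 2 * p)]
        genes[idx[2]] <- genes[idx[1]]
        pair_counter <- pair_counter + 1L
        pair_id[idx] <- pair_counter
      }
    }
    chrom <- paste0("chr", sample(1:22, n_var, replace = TRUE))
    pos <- sample(1e6:2e8, n_var)
    al <- rand_alleles(n_var)
    keys <- variant_key(chrom, pos, al$ref, al$alt)

    is_planted <- c(rep(TRUE, length(plant_rows)), rep(FALSE, n_bg))
    true_mode <- c(plant_rows, rep("background", n_bg))

    # --- annotations ---
    consequence <- character(n_var)
    maf <- rep(NA_real_, n_var)
    support <- rep(NA_integer_, n_var)
    cadd <- rep(NA_real_, n_var)
    splice <- rep(NA_real_, n_var)
    for (v in seq_len(n_var)) {
      if (is_planted[v]) {
        consequence[v] <- "missense"
        support[v] <- sample(6:11, 1)
        maf[v] <- if (runif(1) < 0.5) NA_real_ else 10^runif(1, -6, -3.1)
      } else {
        consequence[v] <- sample(
          c("missense", "synonymous", "frameshift", "stop_gained",
            "splice_region", "inframe_indel", "other"),
          1, prob = c(0.45, 0.25, 0.05, 0.05, 0.05, 0.05, 0.10))
        maf[v] <- if (runif(1) < cfg$maf_zero_weight) 0 else
          10^runif(1, log10(cfg$maf_log_range[[1]]), log10(cfg$maf_log_range[[2]]))
        if (consequence[v] == "missense") support[v] <- sample(0:5, 1)
        if (consequence[v] == "stop_gained") cadd[v] <- runif(1, 0, 40)
        if (consequence[v] == "splice_region") splice[v] <- runif(1)
      }
    }
    verdicts <- matrix(NA_character_, n_var, 11,
                       dimnames = list(NULL, predictor_columns()))
    for (v in which(!is.na(support))) verdicts[v, ] <- verdict_row(support[v])

    # --- true genotypes ---
    gt_p <- gt_m <- gt_f <- character(n_var)
    ad_carrier <- sample(c("mother", "father"), n_var, replace = TRUE)
    for (v in seq_len(n_var)) {
      mode_v <- true_mode[v]
      if (mode_v == "de_novo") {
        gt_p[v] <- "het"; gt_m[v] <- "hom_ref"; gt_f[v] <- "hom_ref"
      } else if (mode_v %in% c("ad_inherited", "ad_incomplete")) {
        gt_p[v] <- "het"
        if (ad_carrier[v] == "mother") { gt_m[v] <- "het"; gt_f[v] <- "hom_ref" }
        else { gt_f[v] <- "het"; gt_m[v] <- "hom_ref" }
      } else if (mode_v == "ar_homozygous") {
        gt_p[v] <- "hom_alt"; gt_m[v] <- "het"; gt_f[v] <- "het"
      } else if (mode_v == "compound_het") {
        gt_p[v] <- "het"
        first_of_pair <- v == min(which(pair_id == pair_id[v]))
        if (first_of_pair) { gt_m[v] <- "het"; gt_f[v] <- "hom_ref" }
        else { gt_m[v] <- "hom_ref"; gt_f[v] <- "het" }
      } else {
        q <- min(max(maf[v], 0.01), 0.5)
        repeat {
          gm <- draw_parent_gt(q, cfg$inbreeding_f)
          gf <- draw_parent_gt(q, cfg$inbreeding_f)
          gp <- child_gt(gm, gf)
          if (gp != "hom_ref" || gm != "hom_ref" || gf != "hom_ref") break
        }
        gt_p[v] <- gp; gt_m[v] <- gm; gt_f[v] <- gf
      }
    }

    mother_affected <- cfg$planted[["ad_inherited"]] > 0 &&
      any(true_mode == "ad_inherited" & ad_carrier == "mother")
    father_affected <- cfg$planted[["ad_inherited"]] > 0 &&
      any(true_mode == "ad_inherited" & ad_carrier == "father")

    members <- tibble(
      family_id = fid,
      sample_id = c(paste0(fid, "_P"), paste0(fid, "_M"),
                    if (is_dyad) NA_character_ else paste0(fid, "_F")),
      role = c("proband", "mother", "father"),
      sex = c(proband_sex, "XX", "XY"),
      affected = c(TRUE, mother_affected, father_affected && !is_dyad),
      present = c(TRUE, TRUE, !is_dyad)
    )

    # --- observed calls: drop father for dyads, then apply error ---
    obs_p <- gt_p; obs_m <- gt_m
    obs_f <- if (is_dyad) rep("missing", n_var) else gt_f
    e <- cfg$genotype_error_rate
    if (e > 0) {
      flip <- function(gt) {
        states <- c("hom_ref", "het", "hom_alt")
        hit <- gt != "missing" & runif(length(gt)) < e
        gt[hit] <- vapply(gt[hit], function(g) sample(setdiff(states, g), 1),
                          character(1))
        gt
      }
      obs_p <- flip(obs_p); obs_m <- flip(obs_m); obs_f <- flip(obs_f)
    }

    variants <- tibble(
      family_id = fid, variant_key = keys, chrom = chrom,
      pos = as.integer(pos), ref = al$ref, alt = al$alt, gene = genes,
      hgvs_c = "", hgvs_p = "", consequence = consequence,
      dbsnp_id = if_else(is.na(maf), "NOVEL",
                         sprintf("rs9%07d", sample(1e7, n_var) - 1L)),
      maf_kg1000 = NA_real_, maf_esp = NA_real_, maf_gnomad = maf
    ) %>%
      dplyr::bind_cols(as_tibble(verdicts)) %>%
      mutate(cadd_phred = cadd, splice_delta = splice)

    all_variants[[i]] <- variants
    all_calls[[i]] <- tibble(family_id = fid, variant_key = keys,
                             gt_proband = obs_p, gt_mother = obs_m,
                             gt_father = obs_f)
    all_truth[[i]] <- tibble(family_id = fid, variant_key = keys,
                             gene = genes, true_mode = true_mode,
                             planted = is_planted, pair_id = pair_id,
                             true_gt_proband = gt_p, true_gt_mother = gt_m,
                             true_gt_father = gt_f, is_dyad = is_dyad)
    all_members[[i]] <- members
  }

  out <- list(variants = bind_rows(all_variants),
              calls = bind_rows(all_calls),
              members = bind_rows(all_members),
              truth = bind_rows(all_truth),
              config = cfg)
  structure(out, class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d families (%d dyads), %d variants (%d planted)\n",
              x$config$n_families, sum(!x$members$present),
              nrow(x$variants), sum(x$truth$planted)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits one VCF + sidecar per family, a single cohort PED and the truth
#' table, all as plain text. Re-running the same simulation and writer
#' yields byte-identical files.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return A named list of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fam_ids <- unique(cohort$members$family_id)
  vcfs <- character(0); sidecars <- character(0)
  for (fid in fam_ids) {
    v <- cohort$variants %>% filter(.data$family_id == fid)
    cl <- cohort$calls %>% filter(.data$family_id == fid)
    mm <- cohort$members %>% filter(.data$family_id == fid)
    vcf_path <- file.path(dir, paste0(fid, ".vcf"))
    side_path <- file.path(dir, paste0(fid, "_sidecar.tsv"))
    write_family_vcf(v, cl, mm, vcf_path, side_path)
    vcfs <- c(vcfs, vcf_path); sidecars <- c(sidecars, side_path)
  }
  ped_path <- file.path(dir, "cohort.ped")
  ped_lines <- cohort$members %>%
    filter(.data$present) %>%
    group_by(.data$family_id) %>%
    dplyr::group_map(function(fam, key) {
      fid <- key$family_id[[1]]
      by_role <- setNames(fam$sample_id, fam$role)
      vapply(seq_len(nrow(fam)), function(j) {
        r <- fam[j, ]
        father <- if (r$role == "proband") unname(by_role["father"]) else "0"
        mother <- if (r$role == "proband") unname(by_role["mother"]) else "0"
        if (is.na(father)) father <- "0"
        if (is.na(mother)) mother <- "0"
        paste(fid, r$sample_id, father, mother,
              if (r$sex == "XY") "1" else "2",
              if (r$affected) "2" else "1", sep = "\t")
      }, character(1))
    }) %>% unlist()
  writeLines(ped_lines, ped_path)
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(cohort$truth, truth_path, progress = FALSE)
  invisible(list(vcf = vcfs, sidecar = sidecars, ped = ped_path,
                 truth = truth_path))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `*.vcf`, `*_sidecar.tsv` and
#'   `cohort.ped`.
#' @return A list with `variants`, `calls`, `members` tibbles (and `truth`
#'   when a `truth.tsv` is present).
#' @export
read_cohort_dir <- function(dir) {
  ped <- file.path(dir, "cohort.ped")
  if (!file.exists(ped)) stop_format("cohort.ped not found in directory")
  members <- read_ped(ped)
  vcfs <- sort(list.files(dir, pattern = "\\.vcf$", full.names = TRUE))
  parts <- lapply(vcfs, function(v) {
    side <- sub("\\.vcf$", "_sidecar.tsv", v)
    if (!file.exists(side)) stop_missing_annotation(paste0("no sidecar for ", v))
    read_family_vcf(v, side, members)
  })
  out <- list(variants = bind_rows(lapply(parts, `[[`, "variants")),
              calls = bind_rows(lapply(parts, `[[`, "calls")),
              members = members)
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) {
    out$truth <- readr::read_tsv(truth_path, show_col_types = FALSE,
                                 progress = FALSE)
  }
  out
}
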