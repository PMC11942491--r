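# helper: a synthetic allele_call with chosen properties
mk_allele <- function(point, min_ = point, max_ = point,
                      lower_bound_only = FALSE, composition = numeric(0),
                      has_interruptions = FALSE, methylated_fraction = NA_real_) {
  structure(list(unit_count_min = min_, unit_count_max = max_,
                 point_estimate = point, lower_bound_only = lower_bound_only,
                 supporting_reads = character(0),
                 mosaic_span = max_ - min_, composition = composition,
                 has_interruptions = has_interruptions,
                 methylated_fraction = methylated_fraction),
            class = "allele_call")
}

mk_genotype <- function(locus_id, alleles, ploidy = 2,
                        homozygous_or_dropout = length(alleles) == 1 && ploidy == 2) {
  structure(list(locus_id = locus_id, alleles = alleles, ploidy = ploidy,
                 homozygous_or_dropout = homozygous_or_dropout,
                 n_spanning = NA, n_bounded = NA),
            class = "str_genotype")
}

test_that("per-allele categories follow the printed ranges", {
  cat_ <- test_catalog()
  expect_equal(classify_allele(mk_allele(66, composition = c(GAA = 1)),
                               cat_$FXN)$category, "full_penetrance")
  expect_equal(classify_allele(mk_allele(130, composition = c(CGG = 1)),
                               cat_$FMR1)$category, "premutation")
  expect_equal(classify_allele(mk_allele(36, composition = c(CAG = 1)),
                               cat_$HTT)$category, "reduced_penetrance")
  expect_equal(classify_allele(mk_allele(30, composition = c(GAA = 1)),
                               cat_$FXN)$category, "normal")
})

test_that("the composition gate demotes expansions of non-pathogenic units", {
  fgf14 <- test_catalog()$FGF14
  a <- mk_allele(330, composition = c(GAAGGA = 0.95, GAA = 0.05))
  res <- classify_allele(a, fgf14)
  expect_equal(res$category, "uncertain_composition")
  expect_match(res$rationale, "uncertain composition")
  # a GAA-dominant expansion of the same length is pathogenic by length
  b <- mk_allele(330, composition = c(GAA = 0.9, GAAGGA = 0.1))
  expect_equal(classify_allele(b, fgf14)$category, "full_penetrance")
})

test_that("interrupted ranges override the uninterrupted thresholds", {
  atxn1 <- test_catalog()$ATXN1
  # 42 units: full penetrance without interruptions, normal with them
  expect_equal(classify_allele(mk_allele(42, composition = c(CAG = 1)),
                               atxn1)$category, "full_penetrance")
  expect_equal(classify_allele(mk_allele(42, composition = c(CAG = 0.9, CAT = 0.1),
                                         has_interruptions = TRUE),
                               atxn1)$category, "normal")
  expect_equal(classify_allele(mk_allele(45, has_interruptions = TRUE),
                               atxn1)$category, "intermediate_uncertain")
  expect_equal(classify_allele(mk_allele(46, has_interruptions = TRUE),
                               atxn1)$category, "full_penetrance")
})

test_that("boundary straddles are flagged on mosaic ranges and bounds", {
  htt <- test_catalog()$HTT
  a <- mk_allele(38, min_ = 36, max_ = 41)   # straddles 39/40
  expect_true(classify_allele(a, htt)$boundary_straddle)
  b <- mk_allele(37, min_ = 36, max_ = 39)
  expect_false(classify_allele(b, htt)$boundary_straddle)
  rfc1 <- test_catalog()$RFC1
  lb <- mk_allele(200, min_ = 200, max_ = 200, lower_bound_only = TRUE,
                  composition = c(AAGGG = 0.9, AAAAG = 0.1))
  res <- classify_allele(lb, rfc1)
  expect_true(res$boundary_straddle)
  expect_equal(res$category, "reduced_penetrance")
})

test_that("recessive case logic distinguishes pathogenic from carrier", {
  fxn <- test_catalog()$FXN
  gaa <- c(GAA = 1)
  gt <- mk_genotype("FXN", list(mk_allele(100, composition = gaa),
                                mk_allele(700, composition = gaa)))
  expect_equal(classify_case(gt, fxn)$case_significance, "pathogenic")
  gt2 <- mk_genotype("FXN", list(mk_allele(30, composition = gaa),
                                 mk_allele(700, composition = gaa)))
  expect_equal(classify_case(gt2, fxn)$case_significance, "carrier")
  gt3 <- mk_genotype("FXN", list(mk_allele(20, composition = gaa),
                                 mk_allele(30, composition = gaa)))
  expect_equal(classify_case(gt3, fxn)$case_significance, "benign")
})

test_that("biallelic lower bounds with pathogenic-unit dominance are pathogenic", {
  rfc1 <- test_catalog()$RFC1
  comp <- c(AAGGG = 0.9, AAAAG = 0.1)
  gt <- mk_genotype("RFC1", list(
    mk_allele(200, lower_bound_only = TRUE, composition = comp),
    mk_allele(830, lower_bound_only = TRUE, composition = comp)))
  res <- classify_case(gt, rfc1)
  expect_equal(res$case_significance, "pathogenic")
  expect_true(res$per_allele[[1]]$boundary_straddle)
})

test_that("recessive soundness: fewer than two affected alleles is never pathogenic", {
  cat_ <- test_catalog()
  for (locus_id in c("FXN", "RFC1", "GLS", "CSTB")) {
    locus <- cat_[[locus_id]]
    comp <- setNames(1, locus$pathogenic_motifs[1])
    set.seed(21)
    for (i in 1:25) {
      low <- sample(0:(min(locus$pathogenic_min %||% 100,
                           if (!is.null(locus$normal)) locus$normal$hi + 1
                           else 10)), 1)
      high <- sample(0:2000, 1)
      gt <- mk_genotype(locus_id, list(mk_allele(low, composition = comp),
                                       mk_allele(high, composition = comp)))
      res <- classify_case(gt, locus)
      cats <- vapply(res$per_allele, `[[`, "", "category")
      if (sum(cats %in% c("reduced_penetrance", "full_penetrance")) < 2)
        expect_false(res$case_significance == "pathogenic",
                     info = sprintf("%s %d/%d", locus_id, low, high))
    }
  }
})

test_that("dominant cases take the most severe allele", {
  htt <- test_catalog()$HTT
  cag <- c(CAG = 1)
  gt <- mk_genotype("HTT", list(mk_allele(26, composition = cag),
                                mk_allele(44, composition = cag)))
  expect_equal(classify_case(gt, htt)$case_significance, "pathogenic")
  gt2 <- mk_genotype("HTT", list(mk_allele(26, composition = cag),
                                 mk_allele(37, composition = cag)))
  expect_equal(classify_case(gt2, htt)$case_significance,
               "reduced_penetrance")
  gt3 <- mk_genotype("HTT", list(mk_allele(26, composition = cag),
                                 mk_allele(30, composition = cag)))
  expect_equal(classify_case(gt3, htt)$case_significance, "benign")
})

test_that("FMR1 full mutations in males need methylation corroboration", {
  fmr1 <- test_catalog()$FMR1
  cgg <- c(CGG = 1)
  meth <- mk_genotype("FMR1", list(mk_allele(250, composition = cgg,
                                             methylated_fraction = 0.8)),
                      ploidy = 1, homozygous_or_dropout = FALSE)
  expect_equal(classify_case(meth, fmr1)$case_significance, "pathogenic")
  unmeth <- mk_genotype("FMR1", list(mk_allele(250, composition = cgg,
                                               methylated_fraction = 0.05)),
                        ploidy = 1, homozygous_or_dropout = FALSE)
  res <- classify_case(unmeth, fmr1)
  expect_equal(res$case_significance, "uncertain")
  expect_match(res$rationale, "methylation")
  # premutation lengths do not require methylation support
  prem <- mk_genotype("FMR1", list(mk_allele(130, composition = cgg)),
                      ploidy = 1, homozygous_or_dropout = FALSE)
  expect_equal(classify_case(prem, fmr1)$case_significance,
               "reduced_penetrance")
})

test_that("the PABPN1 homozygosity rule fires on 11/11 genotypes", {
  pab <- test_catalog()$PABPN1
  gcg <- c(GCG = 1)
  gt <- mk_genotype("PABPN1", list(mk_allele(11, composition = gcg),
                                   mk_allele(11, composition = gcg)))
  expect_equal(classify_case(gt, pab)$case_significance, "pathogenic")
  het <- mk_genotype("PABPN1", list(mk_allele(10, composition = gcg),
                                    mk_allele(11, composition = gcg)))
  expect_false(classify_case(het, pab)$case_significance == "pathogenic")
})

test_that("short-read estimates are exact for spanning alleles, statistical otherwise", {
  cat_ <- test_catalog()
  spec <- sample_spec("FXN",
                      list(allele_spec("GAA", 30), allele_spec("GAA", 30)),
                      coverage = 25,
                      read_length_model = list(type = "short",
                                               read_length = 150),
                      seed = 5)
  sim <- simulate_reads(spec)
  reads <- data.frame(read_id = names(sim$reads), sequence = unname(sim$reads),
                      stringsAsFactors = FALSE)
  est <- estimate_from_short_reads(reads, cat_$FXN)
  expect_equal(est$allele_unit_estimates, c(30, 30))
  expect_false(any(est$statistical))
  expect_gt(est$spanning_read_count, 0)

  # biallelic large expansion: statistical estimates flagged unreliable
  spec2 <- sample_spec("RFC1", list(allele_spec("AAGGG", 450),
                                    allele_spec("AAGGG", 500)),
                       coverage = 25,
                       read_length_model = list(type = "short",
                                                read_length = 150),
                       seed = 11)
  sim2 <- simulate_reads(spec2)
  reads2 <- data.frame(read_id = names(sim2$reads),
                       sequence = unname(sim2$reads), stringsAsFactors = FALSE)
  est2 <- estimate_from_short_reads(reads2, cat_$RFC1)
  expect_true(all(est2$statistical))
  expect_equal(est2$spanning_read_count, 0)
  expect_equal(est2$reliability_ceiling, 27)  # floor(135/5)
  expect_true(any(est2$unreliable))
  expect_error(estimate_from_short_reads(reads2[0, ], cat_$RFC1), "no-call")
})

test_that("the 135 bp rule separates HTT estimates of 47 and 40 units", {
  htt <- test_catalog()$HTT
  hot <- triage(short_read_estimate(htt, c(47, 18)), htt)
  expect_true(hot$needs_long_read)
  expect_true("R1" %in% names(hot$reasons))
  cold <- triage(short_read_estimate(htt, c(40, 18)), htt)
  expect_false(cold$needs_long_read)
  expect_length(cold$reasons, 0)
})

test_that("statistical estimates at high-threshold loci trigger rule R2", {
  fgf14 <- test_catalog()$FGF14
  est <- short_read_estimate(fgf14, c(36, 105), statistical = c(FALSE, TRUE))
  dec <- triage(est, fgf14)
  expect_true(dec$needs_long_read)
  expect_true("R2" %in% names(dec$reasons))
})

test_that("composition, recessive and methylation rules escalate", {
  cat_ <- test_catalog()
  # RFC1: ambiguous composition (R3) and biallelic signal (R4)
  dec <- triage(short_read_estimate(cat_$RFC1, c(40, 60),
                                    statistical = c(TRUE, TRUE)), cat_$RFC1)
  expect_true(all(c("R3", "R4") %in% names(dec$reasons)))
  # FMR1 premutation-range estimate needs methylation (R5)
  dec2 <- triage(short_read_estimate(cat_$FMR1, c(30, 60)), cat_$FMR1)
  expect_true("R5" %in% names(dec2$reasons))
  dec3 <- triage(short_read_estimate(cat_$FMR1, c(20, 30)), cat_$FMR1)
  expect_false("R5" %in% names(dec3$reasons))
})

test_that("severity is monotone in count over the printed ranges", {
  cat_ <- test_catalog()
  for (locus in cat_) {
    counts <- 0:2000
    cats <- classify_count(locus, counts)
    # gap-filled uncertain stretches (no printed range) sit outside the
    # severity scale; monotonicity is asserted across printed categories
    printed <- cats != "intermediate_uncertain" |
      vapply(counts, function(n) in_range(locus$intermediate, n), logical(1))
    ranks <- severity_rank(cats[printed])
    expect_true(all(diff(ranks) >= 0), info = locus$locus_id)
  }
})

test_that("raising an estimate never cancels a long-read requirement", {
  cat_ <- test_catalog()
  for (locus in cat_) {
    for (stat_flag in c(FALSE, TRUE)) {
      needs <- vapply(seq(0, 2000, by = 7), function(e)
        triage(short_read_estimate(locus, c(10, e),
                                   statistical = c(FALSE, stat_flag)),
               locus)$needs_long_read, logical(1))
      expect_true(all(diff(needs) >= 0),
                  info = sprintf("%s stat=%s", locus$locus_id, stat_flag))
    }
  }
})
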