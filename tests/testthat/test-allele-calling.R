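test_that("flank-anchored extraction sets spanning flags on exact constructs", {
  fxn <- test_catalog()$FXN
  read <- paste0(fxn$left_flank, strrep("GAA", 10), fxn$right_flank)
  r <- extract_region(read, fxn)
  expect_true(r$spans_left)
  expect_true(r$spans_right)
  expect_equal(r$sequence, strrep("GAA", 10))
  expect_equal(nchar(r$sequence), 30)
})

test_that("truncated reads yield one-sided extractions (lower bounds)", {
  fxn <- test_catalog()$FXN
  read <- paste0(fxn$left_flank, strrep("GAA", 500))
  r <- extract_region(read, fxn)
  expect_true(r$spans_left)
  expect_false(r$spans_right)
  expect_equal(nchar(r$sequence), 1500)
  # flankless repeat-only read is kept as a bound, not discarded
  r2 <- extract_region(strrep("GAA", 100), fxn)
  expect_false(r2$spans_left || r2$spans_right)
  # flankless non-repeat read is discarded
  set.seed(1)
  expect_null(extract_region(random_dna_str(200), fxn))
})

test_that("mismatched flanks are located where the Hamming-scan oracle puts them", {
  fxn <- test_catalog()$FXN
  set.seed(33)
  for (i in 1:20) {
    lf <- fxn$left_flank
    # plant 2 substitutions at random flank positions
    pos <- sample(30, 2)
    fl_chars <- strsplit(lf, "")[[1]]
    for (p in pos)
      fl_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), fl_chars[p]), 1)
    mutated <- paste(fl_chars, collapse = "")
    read <- paste0(random_dna_str(40), mutated, strrep("GAA", 20),
                   fxn$right_flank)
    r <- extract_region(read, fxn, max_flank_mismatch_frac = 0.2)
    expect_true(r$spans_left)
    oracle <- hamming_scan(read, lf)
    expect_equal(oracle$mismatches, 2)
    expect_equal(oracle$start, 40)
    expect_equal(r$sequence, strrep("GAA", 20))
  }
})

test_that("reverse-complement reads are recognized", {
  fxn <- test_catalog()$FXN
  read <- paste0(fxn$left_flank, strrep("GAA", 12), fxn$right_flank)
  rc <- strcaller:::revcomp(read)
  r <- extract_region(rc, fxn)
  expect_true(r$spans_left && r$spans_right)
  expect_equal(r$sequence, strrep("GAA", 12))
  expect_equal(r$strand, "-")
})

test_that("a wide count gap splits spanning reads into two mosaic alleles", {
  fxn <- test_catalog()$FXN
  counts <- c(92, 95, 100, 104, 649, 700, 830, 901)
  decomps <- lapply(seq_along(counts), function(i)
    make_decomp(counts[i], "GAA", paste0("r", i)))
  gt <- call_alleles(decomps, fxn, ploidy = 2)
  expect_length(gt$alleles, 2)
  expect_equal(c(gt$alleles[[1]]$unit_count_min,
                 gt$alleles[[1]]$unit_count_max), c(92, 104))
  expect_equal(c(gt$alleles[[2]]$unit_count_min,
                 gt$alleles[[2]]$unit_count_max), c(649, 901))
  expect_equal(gt$alleles[[1]]$mosaic_span, 12)
  expect_false(gt$homozygous_or_dropout)
  # ranges of a 2-way split never overlap
  expect_lt(gt$alleles[[1]]$unit_count_max, gt$alleles[[2]]$unit_count_min)
})

test_that("identical counts at ploidy 2 give one allele flagged homozygous-or-dropout", {
  fxn <- test_catalog()$FXN
  decomps <- lapply(1:6, function(i) make_decomp(10, "GAA", paste0("r", i)))
  gt <- call_alleles(decomps, fxn, ploidy = 2)
  expect_length(gt$alleles, 1)
  expect_equal(gt$alleles[[1]]$point_estimate, 10)
  expect_true(gt$homozygous_or_dropout)
})

test_that("when the gap rule fires, the split minimizes within-cluster variance", {
  fxn <- test_catalog()$FXN
  set.seed(99)
  fired <- 0
  for (i in 1:60) {
    n <- sample(4:12, 1)
    counts <- sort(sample(5:400, n, replace = TRUE))
    decomps <- lapply(seq_along(counts), function(j)
      make_decomp(counts[j], "GAA", paste0("r", j)))
    gt <- call_alleles(decomps, fxn, ploidy = 2)
    thr <- max(5, 0.2 * median(counts))
    if (max(diff(counts)) > thr && length(gt$alleles) == 2) {
      fired <- fired + 1
      k <- sse_split_oracle(counts)
      expect_equal(length(gt$alleles[[1]]$supporting_reads), k)
      expect_equal(gt$alleles[[1]]$unit_count_max, counts[k])
      expect_equal(gt$alleles[[2]]$unit_count_min, counts[k + 1])
      # allele ranges never overlap after a 2-way split
      expect_lt(gt$alleles[[1]]$unit_count_max,
                gt$alleles[[2]]$unit_count_min)
    }
  }
  expect_gt(fired, 10)
})

test_that("bounds exceeding all spanning clusters found a lower-bound-only allele", {
  fxn <- test_catalog()$FXN
  decomps <- c(
    lapply(1:5, function(i) make_decomp(30, "GAA", paste0("s", i))),
    lapply(1:3, function(i) make_decomp(400 + 50 * i, "GAA", paste0("b", i),
                                        spans = c(TRUE, FALSE))))
  gt <- call_alleles(decomps, fxn, ploidy = 2)
  expect_length(gt$alleles, 2)
  a2 <- gt$alleles[[2]]
  expect_true(a2$lower_bound_only)
  expect_equal(a2$point_estimate, 550)  # maximum lower bound
  expect_false(gt$alleles[[1]]$lower_bound_only)
})

test_that("with no spanning reads all alleles are lower bounds", {
  rfc1 <- test_catalog()$RFC1
  counts <- c(180, 200, 190, 750, 830, 800)
  decomps <- lapply(seq_along(counts), function(i)
    make_decomp(counts[i], "AAGGG", paste0("r", i), spans = c(TRUE, FALSE)))
  gt <- call_alleles(decomps, rfc1, ploidy = 2)
  expect_length(gt$alleles, 2)
  expect_true(all(vapply(gt$alleles, `[[`, TRUE, "lower_bound_only")))
  expect_equal(gt$alleles[[1]]$point_estimate, 200)
  expect_equal(gt$alleles[[2]]$point_estimate, 830)
})

test_that("zero usable reads is a no-call error", {
  fxn <- test_catalog()$FXN
  expect_error(call_alleles(list(), fxn), "no-call")
})

test_that("an error-free simulated sample is genotyped exactly", {
  cat_ <- test_catalog()
  spec <- sample_spec("FXN",
                      list(allele_spec("GAA", 100), allele_spec("GAA", 700)),
                      coverage = 20, seed = 7)
  sim <- simulate_reads(spec)
  gt <- genotype_sample(sim$reads, cat_$FXN, ploidy = 2)
  pts <- vapply(gt$alleles, `[[`, 0, "point_estimate")
  expect_equal(pts, c(100, 700))
  expect_equal(unname(gt$alleles[[1]]$composition["GAA"]), 1)
})

test_that("a hemizygous male sample yields a single allele at ploidy 1", {
  cat_ <- test_catalog()
  spec <- sample_spec("FMR1", list(allele_spec("CGG", 130)),
                      coverage = 15, seed = 3)
  sim <- simulate_reads(spec)
  gt <- genotype_sample(sim$reads, cat_$FMR1, ploidy = 1)
  expect_length(gt$alleles, 1)
  expect_equal(gt$alleles[[1]]$point_estimate, 130)
  expect_false(gt$homozygous_or_dropout)
})

test_that("truncating reads never raises the called category's severity", {
  fxn <- test_catalog()$FXN
  full <- lapply(1:8, function(i) make_decomp(700, "GAA", paste0("r", i)))
  gt_full <- call_alleles(full, fxn, ploidy = 1)
  cat_full <- classify_allele(gt_full$alleles[[1]], fxn)$category
  for (trunc_units in c(600, 300, 60, 20)) {
    truncated <- lapply(1:8, function(i)
      make_decomp(trunc_units, "GAA", paste0("r", i), spans = c(TRUE, FALSE)))
    gt_t <- call_alleles(truncated, fxn, ploidy = 1)
    a <- gt_t$alleles[[1]]
    expect_true(a$lower_bound_only)
    cat_t <- classify_allele(a, fxn)$category
    expect_lte(strcaller:::severity_rank(cat_t),
               strcaller:::severity_rank(cat_full))
  }
})
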