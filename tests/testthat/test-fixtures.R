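test_that("the simulator is byte-deterministic for a fixed seed", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  s1 <- simulate_cohort(d1, n_samples = 5, n_sites = 40, chrom_length = 1e5,
                        seed = 99)
  s2 <- simulate_cohort(d2, n_samples = 5, n_sites = 40, chrom_length = 1e5,
                        seed = 99)
  for (f in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[f]]), readLines(s2$paths[[f]]),
                     label = paste("file", f))
  }
  # the seed is recorded in the emitted headers
  expect_true(any(grepl("seed=99", readLines(s1$paths$vcf))))
  expect_true(grepl("seed=99", readLines(s1$paths$fasta)[1L]))
})

test_that("planted confidence classes have exact counts in the truth table", {
  sim <- simulate_cohort(file.path(tempdir(), "cnt"), n_samples = 5,
                         n_sites = 100, chrom_length = 5e5,
                         frac_unknown = 0.1, frac_low_conf = 0.06,
                         frac_mismatch = 0.04, seed = 3)
  expect_equal(sum(sim$truth$expected_reason %in% "no_ancestral_call"), 10L)
  expect_equal(sum(sim$truth$expected_reason %in% "low_confidence"), 6L)
  expect_equal(sum(sim$truth$expected_reason %in% "mismatch"), 4L)
})

test_that("emitted files re-ingest cleanly and every drop matches the truth", {
  sim <- simulate_cohort(file.path(tempdir(), "ingest"), n_samples = 10,
                         n_sites = 120, chrom_length = 1e6, seed = 17)
  ch <- read_phased_vcf(sim$paths$vcf)
  expect_equal(sum(ch$skipped), 0L)
  ch <- assign_missing_ids(ch)
  expect_equal(ch$sites$vid, sim$truth$expected_vid)

  anc <- load_ancestral_fasta(sim$paths$fasta, sim$chrom)
  pol <- polarize(ch, anc)
  truth <- sim$truth
  expect_equal(pol$sites$vid,
               truth$expected_vid[is.na(truth$expected_reason)])
  drop <- pol$drop_log$dropped
  expect_equal(drop$reason,
               truth$expected_reason[!is.na(truth$expected_reason)])

  # polarization recovers the true ancestral/derived assignment exactly
  kept <- truth[is.na(truth$expected_reason), ]
  expect_equal(pol$sites$anc, kept$anc)
  expect_equal(pol$sites$der, kept$der)
  expect_equal(pol$sites$flipped, kept$flipped)
  expect_equal(unname(colMeans(pol$P)), kept$derived_freq)

  gm <- read_plink_map(sim$paths$map)
  sm <- build_site_map(pol, gm)
  expect_true(all(diff(sm$cM) >= 0))
})

test_that("infeasible sweep segments are rejected", {
  expect_error(simulate_cohort(tempdir(), n_sites = 10, chrom_length = 1e5,
                               sweep = sweep_spec(segment_cM = 10), seed = 1),
               "infeasible")
  expect_error(sweep_spec(freq = 1.2), "frequency")
})

test_that("the unpolarized twin matches the polarized arm except flipped columns", {
  sim <- simulate_cohort(file.path(tempdir(), "twin"), n_samples = 8,
                         n_sites = 60, chrom_length = 5e5,
                         frac_low_conf = 0, frac_unknown = 0,
                         frac_mismatch = 0, seed = 29)
  twin <- make_unpolarized_twin(sim, file.path(tempdir(), "twin-out"))
  ch <- assign_missing_ids(read_phased_vcf(sim$paths$vcf))
  pol <- polarize(ch, load_ancestral_fasta(sim$paths$fasta, sim$chrom))
  # with no curation drops the two arms share the full site set
  expect_equal(ncol(twin$P), ncol(pol$P))
  flipped <- pol$sites$flipped
  expect_equal(twin$P[, !flipped], pol$P[, !flipped, drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(twin$P[, flipped], 1L - pol$P[, flipped, drop = FALSE],
               ignore_attr = TRUE)
  # a cohort with zero flipped sites would make the twin identical; here the
  # flipped truth drives exactly the differing columns
  differs <- vapply(seq_len(ncol(twin$P)),
                    function(j) any(twin$P[, j] != pol$P[, j]), logical(1))
  expect_equal(differs, flipped)
})

test_that("a zero-flip cohort's twin is identical to the polarized output", {
  sim <- simulate_cohort(file.path(tempdir(), "noflip"), n_samples = 6,
                         n_sites = 30, chrom_length = 2e5,
                         frac_low_conf = 0, frac_unknown = 0,
                         frac_mismatch = 0, seed = 41)
  # rewrite the VCF with REF = ancestral everywhere (no flipped sites)
  ch <- assign_missing_ids(read_phased_vcf(sim$paths$vcf))
  fl <- sim$truth$flipped
  ch$H[, fl] <- 1L - ch$H[, fl]
  tmp <- ch$sites$ref[fl]
  ch$sites$ref[fl] <- ch$sites$alt[fl]
  ch$sites$alt[fl] <- tmp
  write_phased_vcf(ch, sim$paths$vcf)
  sim$truth$flipped <- FALSE

  twin <- make_unpolarized_twin(sim, file.path(tempdir(), "noflip-out"))
  pol <- polarize(assign_missing_ids(read_phased_vcf(sim$paths$vcf)),
                  load_ancestral_fasta(sim$paths$fasta, sim$chrom))
  expect_equal(twin$P, unname(pol$P), ignore_attr = TRUE)
})

test_that("sign agreement between arms holds only at non-flipped sites", {
  sim <- simulate_cohort(file.path(tempdir(), "signs"), n_samples = 30,
                         n_sites = 150, chrom_length = 3e6,
                         sweep = sweep_spec(), frac_low_conf = 0,
                         frac_unknown = 0, frac_mismatch = 0, seed = 61)
  twin <- make_unpolarized_twin(sim, file.path(tempdir(), "signs-out"))
  ch <- assign_missing_ids(read_phased_vcf(sim$paths$vcf))
  pol <- polarize(ch, load_ancestral_fasta(sim$paths$fasta, sim$chrom))
  sm <- build_site_map(pol, read_plink_map(sim$paths$map))
  res_p <- ihs_scan(pol$P, sm)
  res_u <- ihs_scan(twin$P, twin$site_map)
  common <- intersect(res_p$vid, res_u$vid)
  rp <- res_p[match(common, res_p$vid), ]
  ru <- res_u[match(common, res_u$vid), ]
  flipped <- pol$sites$flipped[match(common, pol$sites$vid)]
  # raw scores agree at non-flipped sites and negate at flipped sites
  expect_equal(ru$ihs_unstd[!flipped], rp$ihs_unstd[!flipped])
  expect_equal(ru$ihs_unstd[flipped], -rp$ihs_unstd[flipped])
})
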