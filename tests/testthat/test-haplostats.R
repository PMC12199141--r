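simple_map <- function(bp, cM = bp / 1e6) {
  data.frame(chrom = "2", vid = paste0("s", seq_along(bp)), cM = cM, bp = bp)
}

test_that("identical carrier haplotypes keep EHH at 1 everywhere", {
  P <- rbind(matrix(1L, 4, 5), matrix(rep(c(0L, 1L, 0L, 1L, 0L), 2), 2,
                                      byrow = TRUE))
  map <- simple_map(c(10, 20, 30, 40, 50))
  curve <- ehh(P, map, core = 3, allele = "derived", cutoff = 0)
  expect_equal(curve$ehh, rep(1, 5))
})

test_that("two carriers differing at the first flanking site drop to EHH 0", {
  P <- rbind(c(0L, 1L, 1L), c(1L, 1L, 0L), c(0L, 0L, 0L), c(1L, 0L, 1L))
  map <- simple_map(c(10, 20, 30))
  right <- ehh(P, map, core = 2, allele = "derived", direction = "right",
               cutoff = 0)
  expect_equal(right$ehh, c(1, 0))
})

test_that("a singleton allele class is an explicit error, not silently zero", {
  P <- rbind(c(1L, 1L), c(0L, 1L), c(0L, 0L), c(0L, 1L))
  map <- simple_map(c(10, 20))
  expect_error(ehh(P, map, 1, "derived"), "only 1 carrier")
})

test_that("grouping EHH equals the all-pairs shared-prefix oracle", {
  set.seed(77)
  for (rep in 1:10) {
    nh <- sample(6:20, 1L); ns <- sample(5:30, 1L)
    P <- matrix(rbinom(nh * ns, 1L, runif(1, 0.3, 0.7)), nrow = nh)
    core <- sample(ns, 1L)
    for (al in c("derived", "ancestral")) {
      target <- if (al == "derived") 1L else 0L
      if (sum(P[, core] == target) < 2L) next
      map <- simple_map(seq_len(ns) * 100)
      full <- ehh(P, map, core, al, cutoff = 0)
      right <- full$ehh[full$bp > map$bp[core]]
      left <- rev(full$ehh[full$bp < map$bp[core]])
      expect_equal(right, ehh_pairs_oracle(P, core, al, "right"))
      expect_equal(left, ehh_pairs_oracle(P, core, al, "left"))
      # bounds and monotone decay outward
      expect_true(all(full$ehh >= 0 & full$ehh <= 1))
      expect_equal(full$ehh[full$bp == map$bp[core]], 1)
      expect_true(all(diff(right) <= 1e-12))
      expect_true(all(diff(left) <= 1e-12))
    }
  }
})

test_that("iHH over a fully homozygous 2-cM window is 2.0 exactly", {
  P <- rbind(matrix(1L, 4, 5), matrix(0L, 4, 5))
  map <- simple_map(c(10, 20, 30, 40, 50), cM = c(0, 0.5, 1, 1.5, 2))
  expect_equal(ihh(P, map, core = 3, allele = "derived"), 2.0)
})

test_that("iHH with an immediate drop is the two first-interval trapezoids", {
  # derived carriers identical at the core but split at both flanks
  P <- rbind(c(0L, 1L, 1L), c(1L, 1L, 0L), c(0L, 0L, 1L), c(1L, 0L, 0L))
  map <- simple_map(c(10, 20, 30), cM = c(0.0, 0.3, 0.7))
  # each direction: trapezoid from EHH 1 at the core down to 0 at the flank
  expected <- 0.3 * (1 + 0) / 2 + 0.4 * (1 + 0) / 2
  expect_equal(ihh(P, map, core = 2, allele = "derived", cutoff = 0), expected)
})

test_that("scaling the genetic map doubles iHH", {
  set.seed(42)
  P <- matrix(rbinom(12 * 9, 1L, 0.5), nrow = 12)
  P[, 5] <- rep(c(1L, 0L), each = 6)
  map <- simple_map(seq_len(9) * 10, cM = cumsum(runif(9, 0.01, 0.2)))
  map2 <- map; map2$cM <- 2 * map$cM
  expect_equal(ihh(P, map2, 5, "derived"), 2 * ihh(P, map, 5, "derived"))
})

test_that("relabeling ancestral and derived at every site negates raw iHS", {
  set.seed(19)
  P <- matrix(rbinom(20 * 30, 1L, 0.5), nrow = 20)
  map <- simple_map(seq_len(30) * 1000, cM = seq_len(30) * 0.05)
  res <- ihs_scan(P, map, bins = 5)
  res_rel <- ihs_scan(1L - P, map, bins = 5)
  expect_equal(res_rel$vid, res$vid)
  expect_equal(res_rel$ihs_unstd, -res$ihs_unstd)
  expect_equal(res_rel$ihh1, res$ihh0)
})

test_that("per-bin standardized scores have mean 0 and sd 1 exactly", {
  set.seed(55)
  P <- matrix(rbinom(40 * 60, 1L, runif(60, 0.2, 0.8)), nrow = 40, byrow = FALSE)
  map <- simple_map(seq_len(60) * 500, cM = seq_len(60) * 0.02)
  res <- ihs_scan(P, map, bins = 4)
  bin <- pmin(pmax(ceiling(res$derived_freq * 4), 1L), 4L)
  for (b in unique(bin)) {
    z <- res$ihs_std[bin == b & !res$std_flag & is.finite(res$ihs_std)]
    if (length(z) >= 2L) {
      expect_lt(abs(mean(z)), 1e-9)
      expect_lt(abs(sd(z) - 1), 1e-9)
    }
  }
})

test_that("a bin with fewer than two scores is flagged, not standardized", {
  set.seed(8)
  P <- matrix(rbinom(10 * 8, 1L, 0.5), nrow = 10)
  # force one isolated frequency: a single site near freq 0.1
  P[, 4] <- c(1L, rep(0L, 9L))
  P[1:2, 4] <- 1L
  map <- simple_map(seq_len(8) * 100, cM = seq_len(8) * 0.1)
  res <- ihs_scan(P, map, bins = 10, maf_min = 0.05)
  low <- res[res$derived_freq == 0.2, ]
  if (nrow(low) == 1L) {
    expect_true(low$std_flag)
    expect_equal(low$ihs_std, low$ihs_unstd)
  }
})

test_that("a planted derived sweep scores strongly positive at the focal site", {
  sim <- simulate_cohort(file.path(tempdir(), "hs-sweep"), n_samples = 50,
                         sweep = sweep_spec(), seed = 101)
  ch <- assign_missing_ids(read_phased_vcf(sim$paths$vcf))
  pol <- polarize(ch, load_ancestral_fasta(sim$paths$fasta, "2"))
  sm <- build_site_map(pol, read_plink_map(sim$paths$map))
  res <- ihs_scan(pol$P, sm)
  focal <- res[res$vid == sim$focal_vid, ]
  expect_equal(nrow(focal), 1L)
  expect_gt(focal$ihs_std, 2)
  expect_gt(focal$ihh1, focal$ihh0)

  # mirrored construction: the ancestral allele carries the long haplotype
  sim_a <- simulate_cohort(file.path(tempdir(), "hs-sweep-a"), n_samples = 50,
                           n_sites = 500,
                           sweep = sweep_spec(swept_class = "ancestral"),
                           seed = 101)
  ch_a <- assign_missing_ids(read_phased_vcf(sim_a$paths$vcf))
  pol_a <- polarize(ch_a, load_ancestral_fasta(sim_a$paths$fasta, "2"))
  sm_a <- build_site_map(pol_a, read_plink_map(sim_a$paths$map))
  res_a <- ihs_scan(pol_a$P, sm_a)
  focal_a <- res_a[res_a$vid == sim_a$focal_vid, ]
  expect_lt(focal_a$ihs_std, -2)
})
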