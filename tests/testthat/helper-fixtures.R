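# Shared fixture builders and independent oracles.

write_toy_vcf <- function(records, samples = "S1",
                          path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

vcf_record <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# build a phased_cohort in memory without touching disk
toy_cohort <- function(H, pos, ref, alt, chrom = "2",
                       vid = paste0("rs", seq_along(pos))) {
  n <- nrow(H) / 2L
  structure(list(
    samples = paste0("S", seq_len(n)),
    sites = data.frame(chrom = chrom, pos = pos, vid = vid, ref = ref,
                       alt = alt, stringsAsFactors = FALSE),
    H = H, skipped = c(multiallelic = 0L, indel = 0L, symbolic = 0L),
    n_records = length(pos)), class = "phased_cohort")
}

write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(seqs), function(h) c(paste0(">", h), seqs[[h]])))
  writeLines(lines, path)
  path
}

toy_genetic_map <- function(bp, cM, chrom = "2") {
  structure(list(chrom = chrom, anchors = data.frame(bp = bp, cM = cM)),
            class = "genetic_map")
}

# independent piecewise-linear interpolation oracle: explicit flank search,
# no shared code with interpolate_cM
interp_oracle <- function(q, bp, cM) {
  vapply(q, function(x) {
    n <- length(bp)
    if (x <= bp[1L]) {
      y <- cM[1L] + (x - bp[1L]) * (cM[2L] - cM[1L]) / (bp[2L] - bp[1L])
    } else if (x >= bp[n]) {
      y <- cM[n] + (x - bp[n]) * (cM[n] - cM[n - 1L]) / (bp[n] - bp[n - 1L])
    } else {
      i <- max(which(bp <= x))
      y <- cM[i] + (x - bp[i]) * (cM[i + 1L] - cM[i]) / (bp[i + 1L] - bp[i])
    }
    max(y, 0)
  }, numeric(1))
}

# brute-force EHH oracle: all-pairs shared-prefix, one value per site outward
# from the core (untruncated); direction "left" or "right"
ehh_pairs_oracle <- function(P, core, allele, direction) {
  target <- if (allele == "derived") 1L else 0L
  carriers <- which(P[, core] == target)
  nc <- length(carriers)
  idx <- if (direction == "right") seq(core + 1L, length.out = ncol(P) - core)
         else seq(core - 1L, length.out = core - 1L, by = -1L)
  if (length(idx) == 0L) return(numeric(0))
  pairs <- utils::combn(carriers, 2L)
  out <- numeric(length(idx))
  for (k in seq_along(idx)) {
    span <- if (direction == "right") core:idx[k] else idx[k]:core
    same <- vapply(seq_len(ncol(pairs)), function(j) {
      all(P[pairs[1L, j], span] == P[pairs[2L, j], span])
    }, logical(1))
    out[k] <- mean(same)
  }
  out
}

# the 10-site hand-built polarization fixture: 8 clean (4 of them flipped),
# 1 low-confidence, 1 mismatch
ten_site_fixture <- function() {
  pos <- c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L, 900L, 1000L)
  ref <- c("G", "A", "C", "T", "G", "A", "C", "T", "G", "A")
  alt <- c("A", "G", "T", "C", "A", "G", "T", "C", "A", "G")
  # ancestral base per position: sites 1-4 match REF, 5 lowercase (low conf),
  # 6 mismatches both alleles, 7-10 match ALT (flipped)
  anc_base <- c("G", "A", "C", "T", "g", "C", "T", "C", "A", "G")
  seq_chars <- rep("N", 1000L)
  seq_chars[pos] <- anc_base
  set.seed(7)
  H <- matrix(rbinom(4L * 10L, 1L, 0.5), nrow = 4L)
  list(cohort = toy_cohort(H, pos, ref, alt),
       fasta = write_toy_fasta(list("2" = paste(seq_chars, collapse = ""))),
       expected_flipped = c(rep(FALSE, 4L), rep(TRUE, 4L)),
       expected_retained = c(1:4, 7:10),
       expected_reasons = c("low_confidence", "mismatch"),
       H = H, pos = pos, ref = ref, alt = alt)
}

# REF/ALT label swap of a cohort: alleles renamed, H bit-flipped - the same
# biological data under the opposite file orientation
swap_ref_alt <- function(cohort) {
  s <- cohort$sites
  cohort$sites$ref <- s$alt
  cohort$sites$alt <- s$ref
  cohort$H <- 1L - cohort$H
  cohort
}

# small scan_records builder for scan_io / viz tests
toy_scan_records <- function(ihs_std, bp = seq_along(ihs_std) * 1000L,
                             vid = paste0("rs", seq_along(ihs_std))) {
  d <- data.frame(vid = vid, bp = bp, derived_freq = 0.5,
                  ihh1 = exp(ihs_std / 2), ihh0 = exp(-ihs_std / 2),
                  ihs_unstd = ihs_std, ihs_std = ihs_std,
                  is_outlier = abs(ihs_std) > 2, stringsAsFactors = FALSE)
  class(d) <- c("scan_records", class(d))
  d
}
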