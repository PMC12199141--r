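#' Specify a planted selective sweep
#'
#' Describes the haplotype structure the simulator plants: at a focal
#' site, a fraction of haplotypes (the carriers) all carry the swept core
#' allele and share one identical haplotype across a segment of given
#' genetic length around the core — the signature of a classic sweep.
#' Outside the segment carrier haplotypes revert to the exchangeable
#' random background, emulating recombination breaking up the swept
#' haplotype.
#'
#' @param focal_bp physical position of the swept site; \code{NULL}
#'   (default) places it at the chromosome midpoint.
#' @param swept_class \code{"derived"} (classic sweep on a new mutation)
#'   or \code{"ancestral"} (selection on standing variation).
#' @param freq carrier frequency of the swept allele, in (0, 1);
#'   default 0.6.
#' @param segment_cM genetic length of the shared segment (cM),
#'   default 1.
#' @return list of class \code{sweep_spec}.
#' @export
sweep_spec <- function(focal_bp = NULL, swept_class = c("derived", "ancestral"),
                       freq = 0.6, segment_cM = 1) {
  swept_class <- match.arg(swept_class)
  if (freq <= 0 || freq >= 1) stop("carrier frequency must be in (0, 1)")
  if (segment_cM <= 0) stop("segment_cM must be positive")
  structure(list(focal_bp = focal_bp, swept_class = swept_class,
                 freq = freq, segment_cM = segment_cM),
            class = "sweep_spec")
}

#' Simulate a fully self-consistent synthetic cohort
#'
#' Generates, deterministically for a given seed, the complete input set
#' the pipeline consumes — a phased biallelic VCF, an ancestral-allele
#' FASTA honoring the case convention (uppercase = high-confidence,
#' lowercase = low-confidence, "." = unknown), a PLINK-format genetic map
#' with randomly spaced monotone anchors, and a BED-like gene file —
#' together with a truth table recording, per site, the true
#' ancestral/derived nucleotides, the confidence class planted in the
#' FASTA, the expected polarization outcome (retained or drop reason),
#' and whether REF/ALT are flipped relative to ancestral/derived.
#'
#' The haplotype background is exchangeable-random: each site gets an
#' independent derived-allele frequency drawn uniformly from
#' (0.05, 0.95) and haplotype alleles are independent Bernoulli draws.
#' This is fast and dependency-free but carries no linkage
#' disequilibrium, so EHH decays faster than in coalescent data; a
#' planted \code{\link{sweep_spec}} adds the long shared haplotype that
#' selection scans detect.
#'
#' @param dir output directory (created if needed).
#' @param n_samples diploid sample count (N >= 2); haplotype count is 2N.
#' @param n_sites number of biallelic SNVs.
#' @param chrom chromosome label.
#' @param chrom_length chromosome length in bp.
#' @param sweep a \code{\link{sweep_spec}} or \code{NULL} for a neutral
#'   cohort.
#' @param frac_missing_id fraction of sites whose VCF ID is "." (to
#'   exercise identifier repair).
#' @param frac_low_conf,frac_unknown,frac_mismatch fractions of sites
#'   planted with a low-confidence, unknown, or mismatching ancestral
#'   base; counts are exact (\code{round(frac * n_sites)}). Must sum
#'   to < 1.
#' @param cM_per_Mb mean recombination rate for the simulated map
#'   (default 1 cM/Mb, the human genome-wide average).
#' @param n_anchors number of genetic-map anchors.
#' @param seed integer seed; identical seeds give byte-identical files.
#' @return object of class \code{sim_cohort}: list with \code{paths}
#'   (vcf, fasta, map, genes, truth), \code{truth} (data.frame), plus
#'   \code{chrom}, \code{seed}, \code{sweep}, \code{focal_vid} (planted
#'   sweep site identifier, or NA).
#' @export
simulate_cohort <- function(dir, n_samples = 50, n_sites = 500,
                            chrom = "2", chrom_length = 5e6,
                            sweep = NULL,
                            frac_missing_id = 0.1, frac_low_conf = 0.05,
                            frac_unknown = 0.05, frac_mismatch = 0.02,
                            cM_per_Mb = 1, n_anchors = 20, seed = 1) {
  stopifnot(n_samples >= 2, n_sites >= 2)
  if (frac_low_conf + frac_unknown + frac_mismatch >= 1) {
    stop("confidence-class fractions must sum to < 1")
  }
  if (!is.null(sweep)) {
    stopifnot(inherits(sweep, "sweep_spec"))
    if (sweep$segment_cM / cM_per_Mb * 1e6 > chrom_length) {
      stop("infeasible sweep: shared segment longer than the chromosome")
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  nH <- 2L * n_samples
  nuc <- c("A", "C", "G", "T")

  pos <- sort(sample.int(chrom_length, n_sites))
  anc <- sample(nuc, n_sites, replace = TRUE)
  der <- vapply(anc, function(a) sample(setdiff(nuc, a), 1L), character(1))
  flipped <- runif(n_sites) < 0.5      # TRUE: REF = derived, ALT = ancestral
  ref <- ifelse(flipped, der, anc)
  alt <- ifelse(flipped, anc, der)

  # plant confidence classes with exact counts
  n_low <- round(frac_low_conf * n_sites)
  n_unk <- round(frac_unknown * n_sites)
  n_mis <- round(frac_mismatch * n_sites)
  conf <- rep("high", n_sites)
  special <- sample.int(n_sites, n_low + n_unk + n_mis)
  conf[special[seq_len(n_low)]] <- "low"
  conf[special[n_low + seq_len(n_unk)]] <- "unknown"
  conf[special[n_low + n_unk + seq_len(n_mis)]] <- "mismatch"

  # derived-coded haplotype matrix: exchangeable background
  p <- runif(n_sites, 0.05, 0.95)
  D <- matrix(rbinom(nH * n_sites, 1L, rep(p, each = nH)), nrow = nH)

  focal <- NA_integer_
  if (!is.null(sweep)) {
    focal_bp <- if (is.null(sweep$focal_bp)) chrom_length / 2 else sweep$focal_bp
    focal <- which.min(abs(pos - focal_bp))
    conf[focal] <- "high"              # the focal site must survive curation
    half_bp <- sweep$segment_cM / cM_per_Mb * 1e6 / 2
    seg <- which(pos >= pos[focal] - half_bp & pos <= pos[focal] + half_bp)
    carriers <- sample.int(nH, round(sweep$freq * nH))
    template <- rbinom(length(seg), 1L, p[seg])
    D[carriers, seg] <- matrix(template, nrow = length(carriers),
                               ncol = length(seg), byrow = TRUE)
    core <- if (sweep$swept_class == "derived") 1L else 0L
    D[, focal] <- 1L - core
    D[carriers, focal] <- core
  }

  H <- D
  H[, flipped] <- 1L - H[, flipped]    # recode to REF/ALT orientation

  vid <- sprintf("rs%07d", sample.int(9999999L, n_sites))
  missing_id <- sample.int(n_sites, round(frac_missing_id * n_sites))
  vid[missing_id] <- "."

  samples <- sprintf("S%03d", seq_len(n_samples))
  cohort <- structure(list(
    samples = samples,
    sites = data.frame(chrom = chrom, pos = pos, vid = vid, ref = ref,
                       alt = alt, stringsAsFactors = FALSE),
    H = H, skipped = c(multiallelic = 0L, indel = 0L, symbolic = 0L),
    n_records = n_sites), class = "phased_cohort")

  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                fasta = file.path(dir, "ancestral.fa"),
                map = file.path(dir, "reference.map"),
                genes = file.path(dir, "genes.bed"),
                truth = file.path(dir, "truth.tsv"))

  write_phased_vcf(cohort, paths$vcf)
  vcf_lines <- readLines(paths$vcf)
  writeLines(append(vcf_lines, paste0("##simulation_seed=", seed), after = 1L),
             paths$vcf)

  # ancestral FASTA: background random high-confidence, planted classes at sites
  bases <- sample(nuc, chrom_length, replace = TRUE)
  bases[pos] <- anc
  bases[pos[conf == "low"]] <- tolower(anc[conf == "low"])
  bases[pos[conf == "unknown"]] <- "."
  mis <- which(conf == "mismatch")
  bases[pos[mis]] <- vapply(mis, function(i) {
    sample(setdiff(nuc, c(ref[i], alt[i])), 1L)
  }, character(1))
  seq_str <- paste(bases, collapse = "")
  wrap <- substring(seq_str, seq(1L, chrom_length, 60L),
                    pmin(seq(1L, chrom_length, 60L) + 59L, chrom_length))
  writeLines(c(sprintf(">%s synthetic ancestral sequence seed=%d", chrom, seed),
               wrap), paths$fasta)

  # genetic map: monotone anchors with jittered local rates
  anchor_bp <- sort(c(1L, sample.int(chrom_length - 2L, n_anchors - 2L) + 1L,
                      as.integer(chrom_length)))
  anchor_bp <- unique(anchor_bp)
  rate <- runif(length(anchor_bp) - 1L, 0.2, 1.8) * cM_per_Mb
  anchor_cM <- c(0, cumsum(diff(anchor_bp) / 1e6 * rate))
  writeLines(sprintf("%s anchor%03d %.6f %d", chrom, seq_along(anchor_bp),
                     anchor_cM, anchor_bp), paths$map)

  # gene annotation: one gene over the focal region plus flanking genes
  mid <- if (is.na(focal)) chrom_length / 2 else pos[focal]
  genes <- data.frame(
    chrom = chrom,
    start = as.integer(c(max(0, mid - 5e4), 1e5, chrom_length - 3e5)),
    end   = as.integer(c(min(chrom_length, mid + 5e4), 2e5, chrom_length - 2e5)),
    name  = c("GENE_FOCAL", "GENE_LEFT", "GENE_RIGHT"))
  write.table(genes, paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  expected_reason <- rep(NA_character_, n_sites)
  expected_reason[conf == "low"] <- "low_confidence"
  expected_reason[conf == "unknown"] <- "no_ancestral_call"
  expected_reason[conf == "mismatch"] <- "mismatch"
  default_id <- paste(chrom, pos, ref, alt, sep = "_")
  truth <- data.frame(vid = vid, expected_vid = ifelse(vid == ".", default_id, vid),
                      pos = pos, ref = ref, alt = alt, anc = anc, der = der,
                      confidence = conf, expected_reason = expected_reason,
                      flipped = flipped, derived_freq = colMeans(D),
                      focal = seq_len(n_sites) == focal,
                      stringsAsFactors = FALSE)
  write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)

  structure(list(paths = paths, truth = truth, chrom = chrom, seed = seed,
                 sweep = sweep,
                 focal_vid = if (is.na(focal)) NA_character_
                             else truth$expected_vid[focal]),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort: chromosome", x$chrom, "-", nrow(x$truth), "sites, seed",
      x$seed, if (!is.null(x$sweep)) paste0(", planted ", x$sweep$swept_class,
                                            " sweep at ", x$focal_vid) else "",
      "\n")
  cat("  files:", paste(unlist(x$paths), collapse = " "), "\n")
  invisible(x)
}

#' Unpolarized twin of a simulated cohort
#'
#' Writes a .hap/.map pair directly from the simulated VCF's REF/ALT
#' coding, skipping polarization entirely — the comparison arm for
#' polarized-versus-unpolarized scans. All biallelic SNV sites are kept
#' (no ancestral curation), genetic positions come from the same
#' reference map, and the flipped-site truth (sites where 0/1 is
#' inverted relative to ancestral/derived) is returned so per-site sign
#' bookkeeping is possible downstream.
#'
#' @param sim a \code{sim_cohort} from \code{\link{simulate_cohort}}.
#' @param dir output directory for \code{unpolarized.hap} /
#'   \code{unpolarized.map}.
#' @return list with \code{hap}, \code{map} (paths), \code{P} (REF/ALT
#'   coded matrix), \code{site_map}, and \code{flipped} (logical per
#'   site).
#' @export
make_unpolarized_twin <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_phased_vcf(sim$paths$vcf)
  cohort <- assign_missing_ids(cohort)
  gm <- read_plink_map(sim$paths$map)
  site_map <- data.frame(chrom = cohort$sites$chrom, vid = cohort$sites$vid,
                         cM = interpolate_cM(cohort$sites$pos, gm),
                         bp = cohort$sites$pos, stringsAsFactors = FALSE)
  hap <- file.path(dir, "unpolarized.hap")
  map <- file.path(dir, "unpolarized.map")
  write_hap(cohort$H, hap)
  write_map(site_map, map)
  list(hap = hap, map = map, P = cohort$H, site_map = site_map,
       flipped = sim$truth$flipped)
}
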