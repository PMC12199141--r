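#' Read a phased biallelic VCF into a haplotype cohort
#'
#' Parses a VCF (v4.x, plain or gzipped) and returns the phased haplotypes
#' as a 2N x M matrix of 0/1 alleles coded against REF/ALT, together with
#' the site table. Only biallelic SNV records are retained; multiallelic,
#' indel and symbolic-allele records are skipped and counted. The workflow
#' downstream (polarization, EHH/iHS) is undefined on partial data, so any
#' unphased ("/") or missing ("." or "./.") genotype is a hard error naming
#' the offending site and sample rather than a silent drop.
#'
#' @param path path to the VCF file (".vcf" or ".vcf.gz").
#' @param chrom_filter optional chromosome label; records on other
#'   chromosomes are ignored. Required when the file spans several
#'   chromosomes, since a cohort holds exactly one.
#' @return an object of class \code{phased_cohort}: a list with
#'   \item{samples}{ordered sample labels (length N)}
#'   \item{sites}{data.frame with columns chrom, pos (1-based bp), vid,
#'     ref, alt; rows in strictly increasing pos order}
#'   \item{H}{integer matrix, 2N rows (two consecutive rows per sample,
#'     first then second haplotype) by M columns, entries 0 (REF) / 1 (ALT)}
#'   \item{skipped}{named integer vector with counts of skipped records:
#'     multiallelic, indel, symbolic}
#'   \item{n_records}{number of VCF records examined (after any
#'     chromosome filter)}
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
#'   "2\t1000\trs1\tG\tA\t.\tPASS\t.\tGT\t0|1"), vcf)
#' ch <- read_phased_vcf(vcf)
#' ch$H
#' @export
read_phased_vcf <- function(path, chrom_filter = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix   # always a matrix, unlike getFIX() on single-record files
  if (is.null(fix) || nrow(fix) == 0L) stop("VCF contains no records: ", path)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)

  keep_chrom <- rep(TRUE, nrow(fix))
  if (!is.null(chrom_filter)) {
    keep_chrom <- fix$CHROM == chrom_filter
    if (!any(keep_chrom)) {
      stop("no records on chromosome '", chrom_filter, "'; chromosomes present: ",
           paste(unique(fix$CHROM), collapse = ", "))
    }
  } else if (length(unique(fix$CHROM)) > 1L) {
    stop("VCF spans several chromosomes (",
         paste(unique(fix$CHROM), collapse = ", "),
         "); a cohort holds one chromosome - pass chrom_filter")
  }

  ref <- fix$REF
  alt <- fix$ALT
  multiallelic <- grepl(",", alt, fixed = TRUE)
  symbolic <- !multiallelic &
    (grepl("^<", ref) | grepl("^<", alt) | alt == "*" |
       (nchar(ref) == 1L & nchar(alt) == 1L &
          !(ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T"))))
  indel <- !multiallelic & !symbolic & (nchar(ref) != 1L | nchar(alt) != 1L)
  snv <- !multiallelic & !symbolic & !indel

  keep <- keep_chrom & snv
  skipped <- c(multiallelic = sum(multiallelic & keep_chrom),
               indel        = sum(indel & keep_chrom),
               symbolic     = sum(symbolic & keep_chrom))

  if (!any(keep)) stop("no biallelic SNV records retained from ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  if (length(samples) == 0L) stop("VCF has no sample columns: ", path)

  sites <- data.frame(chrom = fix$CHROM[keep],
                      pos   = as.integer(fix$POS[keep]),
                      vid   = ifelse(is.na(fix$ID[keep]), ".", fix$ID[keep]),
                      ref   = ref[keep],
                      alt   = alt[keep],
                      stringsAsFactors = FALSE)
  if (is.unsorted(sites$pos, strictly = TRUE)) {
    stop("site positions are not strictly increasing within the chromosome")
  }

  bad <- matrix(!grepl("^[01]\\|[01]$", gt), nrow = nrow(gt))
  bad[is.na(gt)] <- TRUE
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    g <- gt[idx[1L], idx[2L]]
    what <- if (is.na(g) || grepl("\\.", g)) "missing genotype"
            else if (grepl("/", g, fixed = TRUE)) "unphased genotype"
            else "malformed genotype"
    stop(what, " '", if (is.na(g)) "." else g, "' at site ",
         sites$vid[idx[1L]], " (", sites$chrom[idx[1L]], ":",
         sites$pos[idx[1L]], "), sample ", samples[idx[2L]],
         "; the pipeline requires fully phased, complete genotypes")
  }

  # two consecutive haplotype rows per sample: S_1, S_2
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  H <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(sites))
  H[seq(1L, nrow(H), by = 2L), ] <- t(a1)
  H[seq(2L, nrow(H), by = 2L), ] <- t(a2)
  rownames(H) <- paste0(rep(samples, each = 2L), "_", rep(1:2, length(samples)))

  structure(list(samples = samples, sites = sites, H = H,
                 skipped = skipped, n_records = sum(keep_chrom)),
            class = "phased_cohort")
}

#' @export
print.phased_cohort <- function(x, ...) {
  cat("phased_cohort:", length(x$samples), "samples,",
      nrow(x$sites), "biallelic SNVs on chromosome",
      x$sites$chrom[1L], "\n")
  cat("  haplotypes:", nrow(x$H), "  skipped records:",
      paste(names(x$skipped), x$skipped, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Replace missing variant identifiers
#'
#' Rewrites every missing ID (".") with a unique identifier built from the
#' site's coordinates; existing identifiers are left untouched. Downstream
#' .map files and scan output are keyed by these identifiers, so the result
#' must be collision-free: duplicate resulting IDs are a hard error.
#'
#' @param cohort a \code{phased_cohort}.
#' @param template glue-style template with placeholders \code{{chrom}},
#'   \code{{pos}}, \code{{ref}}, \code{{alt}}. Default
#'   \code{"{chrom}_{pos}_{ref}_{alt}"}.
#' @return the cohort with every vid non-missing and unique.
#' @export
assign_missing_ids <- function(cohort, template = "{chrom}_{pos}_{ref}_{alt}") {
  stopifnot(inherits(cohort, "phased_cohort"),
            is.character(template), length(template) == 1L, nzchar(template))
  s <- cohort$sites
  missing <- is.na(s$vid) | s$vid == "." | s$vid == ""
  if (any(missing)) {
    filled <- template
    filled <- rep(filled, sum(missing))
    sub1 <- function(tpl, key, val) {
      mapply(function(t, v) gsub(paste0("{", key, "}"), v, t, fixed = TRUE),
             tpl, val, USE.NAMES = FALSE)
    }
    filled <- sub1(filled, "chrom", s$chrom[missing])
    filled <- sub1(filled, "pos",   s$pos[missing])
    filled <- sub1(filled, "ref",   s$ref[missing])
    filled <- sub1(filled, "alt",   s$alt[missing])
    s$vid[missing] <- filled
  }
  dup <- s$vid[duplicated(s$vid)]
  if (length(dup)) {
    stop("duplicate variant identifiers after filling: ",
         paste(unique(dup), collapse = ", "))
  }
  cohort$sites <- s
  cohort
}

#' Write a phased cohort back to VCF
#'
#' Emits a minimal phased VCF v4.2 (CHROM/POS/ID/REF/ALT/GT only) that
#' \code{\link{read_phased_vcf}} re-reads to the identical cohort. Used by
#' the simulator and for round-trip verification.
#'
#' @param cohort a \code{phased_cohort}.
#' @param path output path (".vcf"; plain text).
#' @return \code{path}, invisibly.
#' @export
write_phased_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "phased_cohort"))
  s <- cohort$sites
  H <- cohort$H
  n <- length(cohort$samples)
  a1 <- t(H[seq(1L, 2L * n, by = 2L), , drop = FALSE])
  a2 <- t(H[seq(2L, 2L * n, by = 2L), , drop = FALSE])
  gtm <- matrix(paste0(a1, "|", a2), nrow = nrow(s))
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=polarscan"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t"),
    paste(s$chrom, s$pos, s$vid, s$ref, s$alt, ".", "PASS", ".", "GT",
          apply(gtm, 1L, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
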