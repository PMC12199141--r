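#' Load an ancestral-allele reference sequence
#'
#' Reads one chromosome from an ancestral-allele FASTA in the Ensembl
#' convention: uppercase A/C/G/T are high-confidence ancestral calls,
#' lowercase a/c/g/t low-confidence calls, and ".", "-", "N"/"n" mark
#' positions with no usable ancestral state. Any other character is mapped
#' to unknown. Case is preserved because it carries the confidence class.
#'
#' Ensembl ancestral FASTA headers look like
#' \code{ANCESTOR_for_chromosome:GRCh38:2:1:242193529:1}; the chromosome is
#' matched either by exact header equality or by a configurable regex with
#' one capture group holding the chromosome label.
#'
#' @param path FASTA file (plain or gzipped).
#' @param chrom chromosome label to extract (e.g. \code{"2"}).
#' @param header_regex regex applied to each FASTA header; the first
#'   capture group is compared to \code{chrom}. The default matches both
#'   bare labels ("2", "chr2") and the Ensembl ancestor dialect.
#' @return an object of class \code{ancestral_seq}: list with
#'   \code{chrom}, \code{bases} (single string, 1-based indexing via
#'   \code{\link{ancestral_base}}), \code{length}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">2", "ACgT."), fa)
#' anc <- load_ancestral_fasta(fa, "2")
#' ancestral_base(anc, 1:6)   # "A" "C" "g" "T" "." "."
#' @export
load_ancestral_fasta <- function(path, chrom,
                                 header_regex = "^(?:ANCESTOR_for_chromosome:[^:]+:)?(?:chr)?([^: ]+).*$") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # BStringSet (not DNAStringSet): preserves case and the . / - characters
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  labels <- sub(header_regex, "\\1", headers)
  hit <- which(headers == chrom | labels == chrom |
                 labels == sub("^chr", "", chrom))
  if (length(hit) == 0L) {
    stop("chromosome '", chrom, "' not found in ", path,
         "; available headers: ", paste(headers, collapse = ", "))
  }
  if (length(hit) > 1L) {
    stop("chromosome '", chrom, "' matches several headers: ",
         paste(headers[hit], collapse = ", "))
  }
  bases <- as.character(seqs[[hit]])
  structure(list(chrom = chrom, bases = bases, length = nchar(bases)),
            class = "ancestral_seq")
}

#' @export
print.ancestral_seq <- function(x, ...) {
  cat("ancestral_seq: chromosome", x$chrom, "-", x$length, "bp\n")
  invisible(x)
}

#' Ancestral base at 1-based positions
#'
#' Returns the raw FASTA character at each position: uppercase =
#' high-confidence, lowercase = low-confidence, "." = unknown. Positions
#' outside the sequence, and characters outside the allowed alphabet,
#' come back as ".".
#'
#' @param anc an \code{ancestral_seq}.
#' @param pos integer vector of 1-based positions.
#' @return character vector, same length as \code{pos}.
#' @export
ancestral_base <- function(anc, pos) {
  stopifnot(inherits(anc, "ancestral_seq"))
  out <- rep(".", length(pos))
  ok <- !is.na(pos) & pos >= 1L & pos <= anc$length
  if (any(ok)) {
    b <- substring(anc$bases, pos[ok], pos[ok])
    b[!b %in% c("A", "C", "G", "T", "a", "c", "g", "t")] <- "."
    out[ok] <- b
  }
  out
}

#' Polarize a phased cohort into ancestral/derived alleles
#'
#' Recodes the 0/1 (REF/ALT) haplotype matrix so that 0 means ancestral and
#' 1 means derived, by comparing each site's alleles to the ancestral base
#' at the same coordinate. Sites whose ancestral state cannot be resolved
#' are dropped and logged:
#' \itemize{
#'   \item ancestral base unknown ("." / "-" / "N") -> \code{no_ancestral_call}
#'   \item lowercase (low-confidence) ancestral base -> \code{low_confidence},
#'     unless \code{keep_low_confidence = TRUE}, in which case the base is
#'     uppercased and matched like a high-confidence call
#'   \item ancestral base equal to neither REF nor ALT -> \code{mismatch}
#' }
#' When the ancestral base equals REF the column is copied unchanged; when
#' it equals ALT the column is bit-flipped and the site is flagged
#' \code{flipped}. Column order of retained sites is preserved.
#'
#' @param cohort a \code{phased_cohort}.
#' @param anc_seq an \code{ancestral_seq} for the same chromosome.
#' @param keep_low_confidence keep sites whose ancestral call is
#'   low-confidence (lowercase), matching case-insensitively. Default
#'   \code{FALSE}: such sites are dropped, since only high-confidence calls
#'   polarize reliably.
#' @return an object of class \code{polarized_cohort}: list with
#'   \item{samples}{as input}
#'   \item{sites}{retained sites with added columns \code{anc}, \code{der}
#'     (nucleotides) and \code{flipped} (TRUE when ALT is ancestral)}
#'   \item{P}{2N x M' matrix, 0 = ancestral, 1 = derived}
#'   \item{drop_log}{see \code{\link{drop_log}}}
#' @export
polarize <- function(cohort, anc_seq, keep_low_confidence = FALSE) {
  stopifnot(inherits(cohort, "phased_cohort"),
            inherits(anc_seq, "ancestral_seq"))
  s <- cohort$sites
  chrom <- unique(s$chrom)
  if (!identical(sub("^chr", "", chrom), sub("^chr", "", anc_seq$chrom))) {
    stop("chromosome mismatch: cohort is on '", chrom,
         "', ancestral sequence is '", anc_seq$chrom, "'")
  }

  ab <- ancestral_base(anc_seq, s$pos)
  low <- ab %in% c("a", "c", "g", "t")
  unknown <- ab == "."
  cmp <- if (keep_low_confidence) toupper(ab) else ab

  reason <- rep(NA_character_, nrow(s))
  reason[unknown] <- "no_ancestral_call"
  reason[low & !keep_low_confidence] <- "low_confidence"
  undecided <- is.na(reason)
  is_ref <- undecided & cmp == s$ref
  is_alt <- undecided & cmp == s$alt
  reason[undecided & !is_ref & !is_alt] <- "mismatch"

  keep <- is.na(reason)
  if (!any(keep)) stop("no sites retained after polarization")

  P <- cohort$H[, keep, drop = FALSE]
  flipped <- is_alt[keep]
  P[, flipped] <- 1L - P[, flipped]

  sites <- s[keep, , drop = FALSE]
  rownames(sites) <- NULL
  sites$anc <- ifelse(flipped, sites$alt, sites$ref)
  sites$der <- ifelse(flipped, sites$ref, sites$alt)
  sites$flipped <- flipped

  dropped <- data.frame(vid = s$vid[!keep], chrom = s$chrom[!keep],
                        pos = s$pos[!keep], ref = s$ref[!keep],
                        alt = s$alt[!keep], ancestral_base = ab[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  counts <- setNames(integer(4),
                     c("no_ancestral_call", "low_confidence", "mismatch", "not_snv"))
  tab <- table(dropped$reason)
  counts[names(tab)] <- as.integer(tab)
  log <- structure(list(dropped = dropped, counts = counts,
                        n_retained = sum(keep),
                        loss_fraction = sum(!keep) / nrow(s)),
                   class = "drop_log")

  structure(list(samples = cohort$samples, sites = sites, P = P,
                 drop_log = log),
            class = "polarized_cohort")
}

#' @export
print.polarized_cohort <- function(x, ...) {
  cat("polarized_cohort:", length(x$samples), "samples,",
      nrow(x$sites), "polarized sites (", sum(x$sites$flipped),
      "flipped ), chromosome", x$sites$chrom[1L], "\n")
  print(x$drop_log)
  invisible(x)
}

#' Drop log from polarization
#'
#' Records every site removed during polarization with its reason
#' (\code{no_ancestral_call}, \code{low_confidence}, \code{mismatch},
#' \code{not_snv}), per-reason counts, and the overall
#' \code{loss_fraction} = dropped / (dropped + retained). Reasons are
#' mutually exclusive and the counts sum to the number of dropped sites.
#'
#' @param x a \code{drop_log} (component of a \code{polarized_cohort}).
#' @param ... unused.
#' @name drop_log
#' @export
print.drop_log <- function(x, ...) {
  cat("drop_log:", nrow(x$dropped), "sites dropped /",
      x$n_retained + nrow(x$dropped), "input sites (loss_fraction ",
      sprintf("%.4f", x$loss_fraction), ")\n", sep = " ")
  nz <- x$counts[x$counts > 0]
  if (length(nz)) cat("  ", paste(names(nz), nz, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Write a drop log as TSV
#'
#' One row per dropped site with header
#' \code{vid chrom pos ref alt ancestral_base reason}.
#'
#' @param log a \code{drop_log}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_drop_log <- function(log, path) {
  stopifnot(inherits(log, "drop_log"))
  write.table(log$dropped, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
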