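#' Read a PLINK-format genetic map
#'
#' Reads a whitespace-delimited 4-column map (chromosome, variant ID,
#' genetic position in cM, physical position in bp) into a sorted anchor
#' table for interpolation. Anchors are sorted by bp; duplicate bp entries
#' are collapsed to their first occurrence with a warning. A map whose cM
#' decrease along bp after sorting is corrupt and rejected, as is a map
#' with fewer than two anchors.
#'
#' @param path PLINK .map file (plain or gzipped), no header.
#' @return an object of class \code{genetic_map}: list with \code{chrom}
#'   and \code{anchors}, a data.frame of (bp, cM) with bp strictly
#'   increasing and cM non-decreasing.
#' @export
read_plink_map <- function(path) {
  m <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(m) < 4L) stop("PLINK map must have 4 columns (chrom id cM bp): ", path)
  chrom <- as.character(m[[1L]])
  if (length(unique(chrom)) > 1L) {
    stop("PLINK map spans several chromosomes: ",
         paste(unique(chrom), collapse = ", "))
  }
  anchors <- data.frame(bp = as.numeric(m[[4L]]), cM = as.numeric(m[[3L]]))
  anchors <- anchors[order(anchors$bp), , drop = FALSE]
  dup <- duplicated(anchors$bp)
  if (any(dup)) {
    warning(sum(dup), " duplicate bp anchor(s) in ", path,
            "; keeping first occurrence of each")
    anchors <- anchors[!dup, , drop = FALSE]
  }
  rownames(anchors) <- NULL
  if (nrow(anchors) < 2L) stop("genetic map needs at least 2 anchors: ", path)
  if (any(diff(anchors$cM) < 0)) {
    stop("corrupt genetic map: cM decreases along bp in ", path)
  }
  structure(list(chrom = chrom[1L], anchors = anchors), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  a <- x$anchors
  cat("genetic_map: chromosome", x$chrom, "-", nrow(a), "anchors,",
      "bp", a$bp[1L], "-", a$bp[nrow(a)], ", cM", a$cM[1L], "-",
      a$cM[nrow(a)], "\n")
  invisible(x)
}

#' Interpolate genetic position (cM) at physical positions
#'
#' Linear interpolation against the reference map's anchors: a query at an
#' anchor returns that anchor's cM exactly; a query strictly between two
#' anchors is linearly interpolated between them. Queries outside the
#' anchor range are extrapolated with the slope of the nearest terminal
#' interval and floored at 0 cM, so every site receives a finite,
#' non-decreasing genetic position (selscan and HaploSweep require one for
#' every site; dropping unanchored telomeric sites would silently shrink
#' the dataset).
#'
#' @param bp numeric vector of 1-based physical positions.
#' @param ref a \code{genetic_map}.
#' @return numeric vector of genetic positions (cM), monotone
#'   non-decreasing in \code{bp}.
#' @examples
#' gm <- structure(list(chrom = "2",
#'   anchors = data.frame(bp = c(100, 200), cM = c(0.1, 0.3))),
#'   class = "genetic_map")
#' interpolate_cM(c(100, 150, 250), gm)   # 0.1 0.2 0.4
#' @export
interpolate_cM <- function(bp, ref) {
  stopifnot(inherits(ref, "genetic_map"))
  a <- ref$anchors
  n <- nrow(a)
  out <- approx(a$bp, a$cM, xout = bp, method = "linear",
                rule = 2, ties = "ordered")$y
  below <- !is.na(bp) & bp < a$bp[1L]
  above <- !is.na(bp) & bp > a$bp[n]
  if (any(below)) {
    slope <- (a$cM[2L] - a$cM[1L]) / (a$bp[2L] - a$bp[1L])
    out[below] <- a$cM[1L] + (bp[below] - a$bp[1L]) * slope
  }
  if (any(above)) {
    slope <- (a$cM[n] - a$cM[n - 1L]) / (a$bp[n] - a$bp[n - 1L])
    out[above] <- a$cM[n] + (bp[above] - a$bp[n]) * slope
  }
  pmax(out, 0)
}

#' Build the per-site genetic map for a polarized cohort
#'
#' One record per retained site, in physical-position order, with its
#' interpolated genetic position. The output feeds \code{\link{write_map}}
#' and the EHH/iHS engine. Swapping in a population-specific reference map
#' changes only the cM values, never the site set.
#'
#' @param polar a \code{polarized_cohort}.
#' @param ref a \code{genetic_map} for the same chromosome.
#' @return data.frame with columns chrom, vid, cM, bp; rows ordered by bp,
#'   cM non-decreasing.
#' @export
build_site_map <- function(polar, ref) {
  stopifnot(inherits(polar, "polarized_cohort"), inherits(ref, "genetic_map"))
  s <- polar$sites
  if (nrow(s) == 0L) stop("polarized cohort has no retained sites")
  if (!identical(sub("^chr", "", s$chrom[1L]), sub("^chr", "", ref$chrom))) {
    stop("chromosome mismatch: cohort is on '", s$chrom[1L],
         "', genetic map is '", ref$chrom, "'")
  }
  data.frame(chrom = s$chrom, vid = s$vid,
             cM = interpolate_cM(s$pos, ref), bp = s$pos,
             stringsAsFactors = FALSE)
}
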