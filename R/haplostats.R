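#' Extended haplotype homozygosity around a core site
#'
#' EHH at distance x from a core site is the probability that two
#' randomly chosen haplotypes carrying the chosen core allele are
#' identical at every site from the core out to x. It is computed by
#' extending haplotype groups one site at a time outward from the core:
#' with carriers partitioned into identical-extended-haplotype groups of
#' sizes \eqn{n_g}, EHH = \eqn{\sum_g C(n_g,2) / C(n_c,2)} where
#' \eqn{n_c} is the carrier count. EHH is 1 at the core and
#' non-increasing outward; the walk stops at the chromosome end or once
#' EHH falls below \code{cutoff} (that first below-cutoff point is still
#' reported, so the iHH integral includes its trapezoid).
#'
#' @param P haplotype x site 0/1 matrix (0 = ancestral, 1 = derived).
#' @param map site map data.frame (columns vid, cM, bp) aligned with the
#'   columns of \code{P}.
#' @param core column index of the core site.
#' @param allele \code{"derived"} (carriers have 1 at the core) or
#'   \code{"ancestral"} (0).
#' @param direction \code{"both"}, \code{"left"} or \code{"right"}.
#' @param cutoff truncation threshold on EHH (default 0.05, the common
#'   selscan default); use 0 for the full untruncated curve.
#' @return data.frame with columns bp, cM, ehh, ordered by bp and
#'   containing the core point (ehh = 1).
#' @export
ehh <- function(P, map, core, allele = c("derived", "ancestral"),
                direction = c("both", "left", "right"), cutoff = 0.05) {
  allele <- match.arg(allele)
  direction <- match.arg(direction)
  stopifnot(is.matrix(P), nrow(map) == ncol(P),
            core >= 1L, core <= ncol(P))
  target <- if (allele == "derived") 1L else 0L
  carriers <- which(P[, core] == target)
  nc <- length(carriers)
  if (nc < 2L) {
    stop("EHH undefined for the ", allele, " allele at ", map$vid[core],
         ": only ", nc, " carrier haplotype(s)")
  }
  denom <- choose(nc, 2L)

  walk <- function(idx) {
    if (length(idx) == 0L) return(NULL)
    g <- rep(1L, nc)
    e <- numeric(length(idx))
    n_used <- 0L
    for (k in seq_along(idx)) {
      key <- g * 2L + P[carriers, idx[k]]
      g <- match(key, unique(key))
      e[k] <- sum(choose(tabulate(g), 2L)) / denom
      n_used <- k
      if (e[k] < cutoff) break
    }
    data.frame(bp = map$bp[idx[seq_len(n_used)]],
               cM = map$cM[idx[seq_len(n_used)]],
               ehh = e[seq_len(n_used)])
  }

  left <- if (direction %in% c("both", "left") && core > 1L)
    walk(seq(core - 1L, 1L)) else NULL
  right <- if (direction %in% c("both", "right") && core < ncol(P))
    walk(seq(core + 1L, ncol(P))) else NULL
  corept <- data.frame(bp = map$bp[core], cM = map$cM[core], ehh = 1)
  out <- rbind(if (!is.null(left)) left[rev(seq_len(nrow(left))), ] else NULL,
               corept, right)
  rownames(out) <- NULL
  out
}

#' Integrated haplotype homozygosity (iHH)
#'
#' Area under the EHH curve integrated over genetic distance (cM) by the
#' trapezoid rule, summed over both directions from the core, truncated
#' where EHH falls below \code{cutoff} (the first below-cutoff trapezoid
#' is included). Integration is over genetic, not physical, distance -
#' the genetic map is built precisely so homozygosity is integrated on
#' the recombination scale.
#'
#' @inheritParams ehh
#' @return a single number (cM units).
#' @export
ihh <- function(P, map, core, allele = c("derived", "ancestral"),
                cutoff = 0.05) {
  allele <- match.arg(allele)
  trap <- function(curve) {
    if (is.null(curve) || nrow(curve) < 2L) return(0)
    sum(diff(curve$cM) * (head(curve$ehh, -1L) + curve$ehh[-1L]) / 2)
  }
  left <- ehh(P, map, core, allele, direction = "left", cutoff = cutoff)
  right <- ehh(P, map, core, allele, direction = "right", cutoff = cutoff)
  trap(left) + trap(right)
}

#' Two-allele EHH decay curve at a core site
#'
#' Computes the EHH decay for both core allele classes, for plotting with
#' \code{\link{ehh_plot}}. Points where one class has been truncated
#' carry NA for that series.
#'
#' @inheritParams ehh
#' @return object of class \code{ehh_curve}: list with \code{core_vid},
#'   \code{core_bp} and \code{points}, a data.frame (bp, distance_bp,
#'   distance_cM, ehh_derived, ehh_ancestral) ordered by bp.
#' @export
ehh_curve <- function(P, map, core, cutoff = 0.05) {
  d <- ehh(P, map, core, "derived", cutoff = cutoff)
  a <- ehh(P, map, core, "ancestral", cutoff = cutoff)
  bp <- sort(unique(c(d$bp, a$bp)))
  cM <- ifelse(bp %in% d$bp, d$cM[match(bp, d$bp)], a$cM[match(bp, a$bp)])
  points <- data.frame(bp = bp, distance_bp = bp - map$bp[core],
                       distance_cM = cM - map$cM[core],
                       ehh_derived = d$ehh[match(bp, d$bp)],
                       ehh_ancestral = a$ehh[match(bp, a$bp)])
  structure(list(core_vid = map$vid[core], core_bp = map$bp[core],
                 points = points),
            class = "ehh_curve")
}

#' @export
print.ehh_curve <- function(x, ...) {
  cat("ehh_curve at core", x$core_vid, "(bp", x$core_bp, "):",
      nrow(x$points), "points spanning",
      x$points$bp[1L], "-", x$points$bp[nrow(x$points)], "bp\n")
  invisible(x)
}

#' Chromosome-wide iHS scan
#'
#' For every site with derived-allele frequency strictly inside
#' \code{(maf_min, 1 - maf_min)} and at least two haplotypes in each core
#' allele class, computes iHH for the derived and ancestral classes and
#' the unstandardized score \code{ln(iHH_derived / iHH_ancestral)}.
#' Scores are then standardized (mean 0, sd 1) within equal-width
#' derived-allele-frequency bins, which removes the frequency dependence
#' of the raw statistic. The sign convention follows selscan and
#' HaploSweep: extreme positive standardized scores mean unusually long
#' haplotypes around the derived allele (classic sweep), extreme negative
#' scores mean long haplotypes around the ancestral allele (selection on
#' standing variation).
#'
#' @inheritParams ehh
#' @param maf_min minor-allele-frequency floor; sites outside
#'   \code{(maf_min, 1 - maf_min)} are not scored (default 0.05).
#' @param bins number of equal-width frequency bins over [0, 1] for
#'   standardization (default 20; small datasets need fewer bins than
#'   selscan's 100 to keep every bin populated).
#' @return data.frame of class \code{c("ihs_scan", "scan_records")}, one
#'   row per scored site: vid, bp, derived_freq, ihh1 (derived), ihh0
#'   (ancestral), ihs_unstd, ihs_std, is_outlier (|ihs_std| > 2),
#'   std_flag (TRUE where the bin held < 2 scores and the score is left
#'   unstandardized).
#' @export
ihs_scan <- function(P, map, maf_min = 0.05, bins = 20, cutoff = 0.05) {
  stopifnot(is.matrix(P), nrow(map) == ncol(P), ncol(P) >= 2L)
  freq <- colMeans(P)
  scored <- which(freq > maf_min & freq < 1 - maf_min &
                    colSums(P) >= 2L & colSums(1L - P) >= 2L)
  if (length(scored) == 0L) stop("no sites pass the frequency filter")

  ihh1 <- ihh0 <- rep(NA_real_, length(scored))
  for (k in seq_along(scored)) {
    ihh1[k] <- ihh(P, map, scored[k], "derived", cutoff = cutoff)
    ihh0[k] <- ihh(P, map, scored[k], "ancestral", cutoff = cutoff)
  }
  # log(ihh1) - log(ihh0) rather than log(ihh1/ihh0): relabeling the core
  # alleles then negates the score bit-exactly
  unstd <- ifelse(ihh1 > 0 & ihh0 > 0, log(ihh1) - log(ihh0), NA_real_)

  f <- freq[scored]
  bin <- pmin(pmax(ceiling(f * bins), 1L), bins)
  std <- rep(NA_real_, length(unstd))
  flag <- rep(FALSE, length(unstd))
  for (b in unique(bin)) {
    i <- which(bin == b & is.finite(unstd))
    if (length(i) >= 2L && sd(unstd[i]) > 0) {
      std[i] <- (unstd[i] - mean(unstd[i])) / sd(unstd[i])
    } else {
      std[i] <- unstd[i]
      flag[i] <- TRUE
    }
  }

  out <- data.frame(vid = map$vid[scored], bp = map$bp[scored],
                    derived_freq = f, ihh1 = ihh1, ihh0 = ihh0,
                    ihs_unstd = unstd, ihs_std = std,
                    is_outlier = !is.na(std) & abs(std) > 2,
                    std_flag = flag, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ihs_scan", "scan_records", class(out))
  out
}
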