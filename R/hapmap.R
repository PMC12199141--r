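#' Write a .hap haplotype file for selscan / HaploSweep
#'
#' Writes the polarized 0/1 matrix as plain text, space-separated, no
#' header, trailing newline. Default orientation is one line per haplotype
#' (2N lines, one token per retained site); \code{transposed = TRUE}
#' writes one line per site instead. The orientation in use is recorded in
#' a message so log files document the layout.
#'
#' @param polar a \code{polarized_cohort}, or a plain 0/1 matrix with
#'   haplotypes in rows.
#' @param path output path; a ".gz" suffix gzip-compresses.
#' @param transposed write one line per site instead of per haplotype.
#' @return \code{path}, invisibly.
#' @export
write_hap <- function(polar, path, transposed = FALSE) {
  P <- if (inherits(polar, "polarized_cohort")) polar$P else polar
  if (!is.matrix(P) || nrow(P) == 0L || ncol(P) == 0L) {
    stop("refusing to write an empty .hap file: no haplotypes or no retained sites")
  }
  if (!all(P %in% c(0L, 1L))) stop(".hap matrix must contain only 0/1")
  if (transposed) P <- t(P)
  message("writing .hap: ", nrow(P), " lines x ", ncol(P), " tokens (",
          if (transposed) "rows are sites" else "rows are haplotypes", ")")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(apply(P, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Write a .map genetic-map file for selscan / HaploSweep
#'
#' One line per site: chromosome, variant ID, genetic position (cM, six
#' decimal places), physical position (bp); whitespace-delimited, no
#' header. Records must already be in bp order.
#'
#' @param records site map data.frame from \code{\link{build_site_map}}
#'   (columns chrom, vid, cM, bp).
#' @param path output path; a ".gz" suffix gzip-compresses.
#' @return \code{path}, invisibly.
#' @export
write_map <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("chrom", "vid", "cM", "bp") %in% names(records)))
  if (nrow(records) == 0L) stop("refusing to write an empty .map file")
  if (is.unsorted(records$bp)) stop(".map records must be ordered by bp")
  lines <- sprintf("%s %s %.6f %d", records$chrom, records$vid,
                   records$cM, as.integer(records$bp))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a .hap/.map file pair
#'
#' Inverse of \code{\link{write_hap}} / \code{\link{write_map}} on their
#' own output; used for round-trip verification and as input to the
#' built-in EHH/iHS engine. Readers are whitespace-tolerant. Ragged rows,
#' tokens other than 0/1, and a dimension mismatch between the two files
#' are hard errors.
#'
#' @param hap_path .hap file (rows are haplotypes unless
#'   \code{transposed}).
#' @param map_path .map file (chrom, vid, cM, bp; no header).
#' @param transposed the .hap file has one line per site.
#' @return list with \code{P} (haplotype x site 0/1 integer matrix) and
#'   \code{map} (data.frame chrom, vid, cM, bp).
#' @export
read_hap_map <- function(hap_path, map_path, transposed = FALSE) {
  lines <- readLines(hap_path)
  if (length(lines) == 0L) stop("empty .hap file: ", hap_path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  width <- lengths(toks)
  if (length(unique(width)) > 1L) {
    stop("ragged .hap file: line ", which(width != width[1L])[1L],
         " has ", width[which(width != width[1L])[1L]], " tokens, expected ",
         width[1L])
  }
  flat <- unlist(toks)
  bad <- which(!flat %in% c("0", "1"))
  if (length(bad)) {
    i <- bad[1L]
    stop("invalid .hap token '", flat[i], "' at line ",
         ceiling(i / width[1L]), ", column ", (i - 1L) %% width[1L] + 1L)
  }
  P <- matrix(as.integer(flat), nrow = length(lines), byrow = TRUE)
  if (transposed) P <- t(P)

  m <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(m) < 4L) stop(".map must have 4 columns (chrom vid cM bp): ", map_path)
  map <- data.frame(chrom = as.character(m[[1L]]), vid = as.character(m[[2L]]),
                    cM = as.numeric(m[[3L]]), bp = as.integer(m[[4L]]),
                    stringsAsFactors = FALSE)
  if (ncol(P) != nrow(map)) {
    stop("dimension mismatch: .hap has ", ncol(P), " sites, .map has ",
         nrow(map), " records")
  }
  list(P = P, map = map)
}
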