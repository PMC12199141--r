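#' Read normalized iHS output from selscan or HaploSweep
#'
#' Parses the normalized iHS table into a uniform record model. The
#' selscan dialect is the \code{*.ihs.out.*.norm} layout: headerless
#' columns \code{id pos freq ihh1 ihh0 unstandardized standardized crit}.
#' The HaploSweep dialect is expressed as a column mapping onto the same
#' record model; by default it expects a header line naming at least
#' \code{id, pos, freq, ihh1, ihh0, ihs, std_ihs} and matches columns by
#' name (strict mode rejects unrecognized layouts).
#'
#' @param path tabular scan output, whitespace-delimited.
#' @param dialect \code{"selscan"} (default) or \code{"haplosweep"}.
#' @param columns for the haplosweep dialect, a named character vector
#'   mapping record fields to file column names.
#' @return data.frame of class \code{scan_records} with columns vid, bp,
#'   derived_freq, ihh1, ihh0, ihs_unstd, ihs_std, is_outlier; attribute
#'   \code{n_malformed} counts rows that failed to parse.
#' @export
read_norm_ihs <- function(path, dialect = c("selscan", "haplosweep"),
                          columns = c(vid = "id", bp = "pos",
                                      derived_freq = "freq", ihh1 = "ihh1",
                                      ihh0 = "ihh0", ihs_unstd = "ihs",
                                      ihs_std = "std_ihs")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty scan output file: ", path)

  if (dialect == "selscan") {
    # headerless; tolerate an optional header line starting with a non-number
    first <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
    if (length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L])))) {
      lines <- lines[-1L]
    }
    toks <- strsplit(trimws(lines), "[ \t]+")
    ok <- lengths(toks) >= 7L
    fields <- do.call(rbind, lapply(toks[ok], function(t) t[1:8][1:8]))
    d <- data.frame(vid = fields[, 1L],
                    bp = suppressWarnings(as.numeric(fields[, 2L])),
                    derived_freq = suppressWarnings(as.numeric(fields[, 3L])),
                    ihh1 = suppressWarnings(as.numeric(fields[, 4L])),
                    ihh0 = suppressWarnings(as.numeric(fields[, 5L])),
                    ihs_unstd = suppressWarnings(as.numeric(fields[, 6L])),
                    ihs_std = suppressWarnings(as.numeric(fields[, 7L])),
                    stringsAsFactors = FALSE)
    crit <- suppressWarnings(as.numeric(fields[, 8L]))
    parse_ok <- !is.na(d$bp) & !is.na(d$ihs_std)
    d <- d[parse_ok, , drop = FALSE]
    crit <- crit[parse_ok]
    d$is_outlier <- !is.na(crit) & crit == 1
    n_malformed <- sum(!ok) + sum(!parse_ok)
  } else {
    tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE)
    missing_cols <- setdiff(unname(columns), names(tab))
    if (length(missing_cols)) {
      stop("haplosweep table in ", path, " lacks expected column(s): ",
           paste(missing_cols, collapse = ", "),
           "; present: ", paste(names(tab), collapse = ", "))
    }
    d <- data.frame(vid = as.character(tab[[columns[["vid"]]]]),
                    bp = as.numeric(tab[[columns[["bp"]]]]),
                    derived_freq = as.numeric(tab[[columns[["derived_freq"]]]]),
                    ihh1 = as.numeric(tab[[columns[["ihh1"]]]]),
                    ihh0 = as.numeric(tab[[columns[["ihh0"]]]]),
                    ihs_unstd = as.numeric(tab[[columns[["ihs_unstd"]]]]),
                    ihs_std = as.numeric(tab[[columns[["ihs_std"]]]]),
                    stringsAsFactors = FALSE)
    parse_ok <- !is.na(d$bp) & !is.na(d$ihs_std)
    d <- d[parse_ok, , drop = FALSE]
    d$is_outlier <- abs(d$ihs_std) > 2
    n_malformed <- sum(!parse_ok)
  }
  if (nrow(d) == 0L) stop("no parseable rows in ", path)
  rownames(d) <- NULL
  attr(d, "n_malformed") <- n_malformed
  class(d) <- c("scan_records", class(d))
  d
}

#' Write scan results in the selscan normalized layout
#'
#' Emits the headerless \code{id pos freq ihh1 ihh0 unstd std crit} table
#' so results from the built-in engine and from external selscan runs flow
#' through the same downstream parsing and plotting.
#'
#' @param records a \code{scan_records} data.frame (or \code{ihs_scan}
#'   result) with columns vid, bp, derived_freq, ihh1, ihh0, ihs_unstd,
#'   ihs_std.
#' @param path output path.
#' @param threshold |ihs_std| above which the crit flag is set (default 2).
#' @return \code{path}, invisibly.
#' @export
write_norm_ihs <- function(records, path, threshold = 2) {
  stopifnot(all(c("vid", "bp", "derived_freq", "ihh1", "ihh0",
                  "ihs_unstd", "ihs_std") %in% names(records)))
  ok <- !is.na(records$ihs_std)
  r <- records[ok, , drop = FALSE]
  lines <- sprintf("%s %d %.6f %.6f %.6f %.6f %.6f %d",
                   r$vid, as.integer(r$bp), r$derived_freq, r$ihh1, r$ihh0,
                   r$ihs_unstd, r$ihs_std,
                   as.integer(abs(r$ihs_std) > threshold))
  writeLines(lines, path)
  invisible(path)
}

#' Classify standardized iHS scores into outlier classes
#'
#' Partitions records by standardized score against a symmetric threshold:
#' \code{extreme_negative} (score < -threshold, long haplotypes around the
#' ancestral allele), \code{extreme_positive} (score > threshold, long
#' haplotypes around the derived allele), and \code{non_extreme}. The
#' conventional threshold 2 captures roughly the most extreme 5\% of an
#' empirical standard-normal-like score distribution.
#'
#' @param records a \code{scan_records} data.frame (needs \code{ihs_std}).
#' @param threshold positive cutoff (default 2).
#' @return list with \code{counts} (named integer vector), \code{class}
#'   (factor over records), and \code{threshold}.
#' @export
classify_outliers <- function(records, threshold = 2) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number")
  }
  if (NROW(records) == 0L) stop("no records to classify")
  score <- records$ihs_std
  cls <- factor(ifelse(score < -threshold, "extreme_negative",
                       ifelse(score > threshold, "extreme_positive",
                              "non_extreme")),
                levels = c("extreme_negative", "extreme_positive", "non_extreme"))
  list(counts = setNames(as.integer(table(cls)), levels(cls)),
       class = cls, threshold = threshold)
}

#' Compare outlier rates between polarized and unpolarized scans
#'
#' Builds the 2x2 dataset-by-extremeness contingency table at
#' \code{|ihs_std| > threshold} and tests equality of the two extreme
#' fractions with a chi-square two-proportion test (continuity-corrected).
#' An excess of extreme scores in the unpolarized arm suggests that part
#' of its outlier "hits" are artifacts of arbitrary REF/ALT coding rather
#' than signals of selection.
#'
#' @param polarized,unpolarized \code{scan_records} from the two arms,
#'   same chromosome.
#' @param threshold outlier cutoff (default 2).
#' @return list of class \code{scan_comparison}: \code{table} (2x2 counts),
#'   \code{extreme_fraction} (named, both arms), \code{statistic} (X^2),
#'   \code{p_value}.
#' @export
compare_scan_sets <- function(polarized, unpolarized, threshold = 2) {
  if (NROW(polarized) == 0L || NROW(unpolarized) == 0L) {
    stop("both scan record sets must be non-empty")
  }
  ex_p <- sum(abs(polarized$ihs_std) > threshold, na.rm = TRUE)
  ex_u <- sum(abs(unpolarized$ihs_std) > threshold, na.rm = TRUE)
  n_p <- sum(!is.na(polarized$ihs_std))
  n_u <- sum(!is.na(unpolarized$ihs_std))
  tab <- matrix(c(ex_p, n_p - ex_p, ex_u, n_u - ex_u), nrow = 2L,
                byrow = TRUE,
                dimnames = list(dataset = c("polarized", "unpolarized"),
                                class = c("extreme", "non_extreme")))
  ht <- suppressWarnings(prop.test(tab))
  structure(list(table = tab,
                 extreme_fraction = c(polarized = ex_p / n_p,
                                      unpolarized = ex_u / n_u),
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 threshold = threshold),
            class = "scan_comparison")
}

#' @export
print.scan_comparison <- function(x, ...) {
  cat("scan_comparison at |iHS| >", x$threshold, "\n")
  print(x$table)
  cat(sprintf("extreme fractions: polarized %.4f, unpolarized %.4f\n",
              x$extreme_fraction[["polarized"]],
              x$extreme_fraction[["unpolarized"]]))
  cat(sprintf("chi-square = %.4f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Export a scan comparison as TSV
#'
#' @param x a \code{scan_comparison}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_scan_comparison <- function(x, path) {
  stopifnot(inherits(x, "scan_comparison"))
  d <- data.frame(dataset = rownames(x$table),
                  extreme = x$table[, "extreme"],
                  non_extreme = x$table[, "non_extreme"],
                  extreme_fraction = x$extreme_fraction,
                  statistic = x$statistic, p_value = x$p_value)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
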