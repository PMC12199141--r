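save_plot_formats <- function(p, out, formats, width = 7, height = 4.5) {
  known <- c("pdf", "eps", "svg", "png")
  bad <- setdiff(formats, known)
  if (length(bad)) {
    stop("unknown output format(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(known, collapse = ", "))
  }
  if (length(formats) == 0L) stop("at least one output format is required")
  out <- sub("\\.(pdf|eps|svg|png)$", "", out)
  paths <- character(0)
  for (fmt in formats) {
    f <- paste0(out, ".", fmt)
    switch(fmt,
      pdf = pdf(f, width = width, height = height),
      eps = postscript(f, width = width, height = height,
                       horizontal = FALSE, onefile = FALSE, paper = "special"),
      svg = svg(f, width = width, height = height),
      png = png(f, width = width, height = height, units = "in", res = 150))
    print(p)
    dev.off()
    paths <- c(paths, f)
  }
  paths
}

#' Manhattan plot of standardized iHS scores
#'
#' Plots standardized iHS against physical position with dashed
#' horizontal outlier lines at +threshold and -threshold. Points above
#' +threshold (long haplotypes around the derived allele) are drawn red,
#' points below -threshold (around the ancestral allele) green, the rest
#' gray; selected variants can be labeled with their identifiers. With a
#' gene annotation, the names of genes harboring outlier scores are
#' written to a text file.
#'
#' @param records a \code{scan_records} data.frame (vid, bp, ihs_std).
#' @param threshold positive outlier cutoff for the dashed lines and the
#'   color classes (default 2).
#' @param highlight_ids variant identifiers to label on the plot;
#'   identifiers absent from \code{records} produce a warning, not an
#'   error.
#' @param dot_size point size (default 1).
#' @param colors named vector with entries \code{above}, \code{below},
#'   \code{neutral} overriding the default red/green/gray scheme.
#' @param gene_annot optional gene annotation: a BED-like 4-column
#'   data.frame (chrom, start, end, name; 0-based half-open intervals) or
#'   the path of such a file (tab- or space-delimited, no header).
#' @param gene_file path for the outlier gene list (.txt, one gene name
#'   per line); required when \code{gene_annot} is given.
#' @param out optional output base path; one file per requested format is
#'   written as \code{<out>.<fmt>}.
#' @param formats subset of \code{c("pdf", "eps", "svg", "png")}.
#' @return the ggplot object, invisibly, with attribute \code{files}
#'   (written image paths) and, when genes were annotated,
#'   \code{outlier_genes}.
#' @export
manhattan_plot <- function(records, threshold = 2, highlight_ids = NULL,
                           dot_size = 1, colors = NULL,
                           gene_annot = NULL, gene_file = NULL,
                           out = NULL, formats = "png") {
  if (NROW(records) == 0L) stop("no records to plot")
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be positive")
  }
  pal <- c(above = "red", below = "green4", neutral = "gray60")
  if (!is.null(colors)) pal[names(colors)] <- colors

  d <- data.frame(vid = records$vid, bp = records$bp,
                  ihs_std = records$ihs_std, stringsAsFactors = FALSE)
  d <- d[!is.na(d$ihs_std), , drop = FALSE]
  d$class <- ifelse(d$ihs_std > threshold, "above",
                    ifelse(d$ihs_std < -threshold, "below", "neutral"))

  p <- ggplot2::ggplot(d, ggplot2::aes(x = bp / 1e6, y = ihs_std)) +
    ggplot2::geom_point(ggplot2::aes(color = class), size = dot_size,
                        show.legend = FALSE) +
    ggplot2::scale_color_manual(values = pal) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "Position (Mb)", y = "Standardized iHS") +
    ggplot2::theme_classic()

  if (!is.null(highlight_ids)) {
    miss <- setdiff(highlight_ids, d$vid)
    if (length(miss)) {
      warning("highlight id(s) not present in records: ",
              paste(miss, collapse = ", "))
    }
    hi <- d[d$vid %in% highlight_ids, , drop = FALSE]
    if (nrow(hi)) {
      p <- p +
        ggplot2::geom_point(data = hi, color = "red", size = dot_size * 2) +
        ggplot2::geom_text(data = hi, ggplot2::aes(label = vid),
                           vjust = -1, size = 3)
    }
  }

  genes <- NULL
  if (!is.null(gene_annot)) {
    if (is.character(gene_annot)) {
      gene_annot <- read.table(gene_annot, header = FALSE,
                               stringsAsFactors = FALSE)
    }
    names(gene_annot)[1:4] <- c("chrom", "start", "end", "name")
    outl <- d[abs(d$ihs_std) > threshold, , drop = FALSE]
    # BED is 0-based half-open: 1-based bp falls in [start, end) iff
    # start < bp <= end
    hit <- vapply(seq_len(nrow(gene_annot)), function(i) {
      any(outl$bp > gene_annot$start[i] & outl$bp <= gene_annot$end[i])
    }, logical(1))
    genes <- unique(gene_annot$name[hit])
    if (is.null(gene_file)) {
      stop("gene_annot supplied without gene_file to write the gene list to")
    }
    writeLines(genes, gene_file)
  }

  files <- if (!is.null(out)) save_plot_formats(p, out, formats) else character(0)
  attr(p, "files") <- files
  attr(p, "outlier_genes") <- genes
  invisible(p)
}

#' EHH decay plot around a core site
#'
#' Line plot of EHH against signed physical distance from the core site
#' (Mb; the core sits at 0.0, negative distances upstream, positive
#' downstream on the forward strand). Chromosomes carrying the derived
#' core allele are drawn in red, those carrying the ancestral allele in
#' blue, with a legend. A genetic-distance x-axis (cM) is available as an
#' option.
#'
#' @param curve an \code{ehh_curve}.
#' @param out optional output base path (one file per format).
#' @param formats subset of \code{c("pdf", "eps", "svg", "png")}.
#' @param distance x-axis scale: \code{"physical"} (Mb, default) or
#'   \code{"genetic"} (cM).
#' @return the ggplot object, invisibly, with attribute \code{files}.
#' @export
ehh_plot <- function(curve, out = NULL, formats = "png",
                     distance = c("physical", "genetic")) {
  stopifnot(inherits(curve, "ehh_curve"))
  distance <- match.arg(distance)
  pts <- curve$points
  if (nrow(pts) == 0L) stop("empty EHH curve")
  x <- if (distance == "physical") pts$distance_bp / 1e6 else pts$distance_cM
  long <- rbind(
    data.frame(distance = x, ehh = pts$ehh_derived,
               allele = "derived", stringsAsFactors = FALSE),
    data.frame(distance = x, ehh = pts$ehh_ancestral,
               allele = "ancestral", stringsAsFactors = FALSE))
  long <- long[!is.na(long$ehh), , drop = FALSE]
  present <- unique(long$allele)
  if (length(present) < 2L) {
    warning("EHH curve has only the ", present, " allele class; ",
            "plotting a single series")
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = distance, y = ehh,
                                          color = allele)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_color_manual(
      values = c(derived = "red", ancestral = "blue"), name = "Core allele") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = paste0("Distance from ", curve$core_vid,
                             if (distance == "physical") " (Mb)" else " (cM)"),
                  y = "EHH") +
    ggplot2::theme_classic()
  files <- if (!is.null(out)) save_plot_formats(p, out, formats) else character(0)
  attr(p, "files") <- files
  invisible(p)
}
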