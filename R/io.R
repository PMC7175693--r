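#' Read a one-dimensional signal from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`plain`}{one numeric value per line; blank lines and `#` comment
#'     lines are ignored.}
#'   \item{`csv_column`}{a delimited file with a header; the signal is taken
#'     from `column` (name or index).}
#'   \item{`bedgraph`}{four tab-separated columns chrom, start, end, value;
#'     rows are taken in file order within the chromosome and the value
#'     column becomes the signal. Genomic coordinates are returned alongside
#'     so segmentations can be written back as BED.}
#' }
#' Non-numeric signal entries are rejected with their line number; files
#' mixing chromosomes must be filtered with `chrom`.
#'
#' @param path file path.
#' @param format one of `"plain"`, `"csv_column"`, `"bedgraph"`.
#' @param column column name or index holding the signal (`csv_column`).
#' @param chrom chromosome filter (`bedgraph` with several chromosomes).
#' @param sep field separator for `csv_column` (default `,`).
#' @return a [time_series()]; for bedGraph input it carries the extra
#'   attributes `chrom`, `start`, `end` (0-based half-open, as in the file).
#' @export
read_series <- function(path, format = c("plain", "csv_column", "bedgraph"),
                        column = 1L, chrom = NULL, sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "plain") {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    if (length(idx) == 0L) stop("empty signal file: ", path, call. = FALSE)
    vals <- suppressWarnings(as.numeric(lines[keep]))
    if (anyNA(vals))
      stop("non-numeric value on line ", idx[which(is.na(vals))[1L]],
           " of ", path, call. = FALSE)
    return(time_series(vals))
  }
  if (format == "csv_column") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("empty signal file: ", path, call. = FALSE)
    vals <- df[[column]]
    if (is.null(vals)) stop("no column '", column, "' in ", path, call. = FALSE)
    if (!is.numeric(vals)) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals))))[1L]
      stop("non-numeric value on line ", bad + 1L, " of ", path, call. = FALSE)
    }
    if (anyNA(vals))
      stop("missing values in column '", column, "' of ", path, call. = FALSE)
    return(time_series(vals))
  }
  # bedgraph
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|track|browser|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty bedGraph file: ", path, call. = FALSE)
  parts <- strsplit(lines[keep], "\t| +")
  bad <- which(vapply(parts, length, integer(1)) < 4L)
  if (length(bad))
    stop("malformed bedGraph row on line ", idx[bad[1L]], " of ", path,
         call. = FALSE)
  chroms <- vapply(parts, `[[`, character(1), 1L)
  starts <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  ends <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 4L)))
  if (anyNA(vals))
    stop("non-numeric value on line ", idx[which(is.na(vals))[1L]], " of ",
         path, call. = FALSE)
  if (anyNA(starts) || anyNA(ends))
    stop("non-numeric coordinates in ", path, call. = FALSE)
  if (!is.null(chrom)) {
    sel <- chroms == chrom
    if (!any(sel)) stop("no rows for chromosome '", chrom, "'", call. = FALSE)
    chroms <- chroms[sel]; starts <- starts[sel]; ends <- ends[sel]
    vals <- vals[sel]
  } else if (length(unique(chroms)) > 1L) {
    stop("bedGraph mixes chromosomes (",
         paste(utils::head(unique(chroms), 5L), collapse = ", "),
         "); use 'chrom' to pick one", call. = FALSE)
  }
  ts <- time_series(vals)
  attr(ts, "chrom") <- chroms
  attr(ts, "start") <- starts
  attr(ts, "end") <- ends
  ts
}

#' Segment table of a fitted segmentation
#'
#' Converts a fit into one row per segment with 1-based inclusive
#' boundaries, the fitted segment parameter (Gaussian: the segment mean;
#' Poisson: the segment rate) and the segment cost. Segments tile `1..n`;
#' the end of segment `j` is the `j`-th changepoint.
#'
#' @param fit a `"penalised_fit"` or `"constrained_fit"`.
#' @param series the signal the fit was computed from.
#' @param k for a constrained fit, which segmentation to tabulate
#'   (default `fit$K`).
#' @param model the [cost_model()] used for the fit (for the cost column).
#' @return data.frame with columns `segment`, `start`, `end`, `mean`,
#'   `cost`.
#' @export
segment_table <- function(fit, series, k = NULL,
                          model = cost_model(fit$family)) {
  series <- time_series(series)
  cps <- if (inherits(fit, "penalised_fit")) {
    fit$changepoints
  } else if (inherits(fit, "constrained_fit")) {
    if (is.null(k)) k <- fit$K
    if (k == 0L) integer(0) else fit$segmentations[[k]]
  } else stop("'fit' must be a penalised_fit or constrained_fit",
              call. = FALSE)
  bounds <- c(0L, cps, series$n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  means <- vapply(seq_along(starts), function(j) {
    mean(series$values[starts[j]:ends[j]])
  }, numeric(1))
  costs <- vapply(seq_along(starts), function(j) {
    segment_cost(model, series, starts[j] - 1L, ends[j])
  }, numeric(1))
  data.frame(segment = seq_along(starts), start = starts, end = ends,
             mean = means, cost = costs)
}

#' Write a segmentation to CSV or BED
#'
#' CSV output has columns `segment, start, end, mean, cost` (1-based
#' inclusive coordinates) preceded by `#`-comment header lines recording
#' the method and its settings. BED output converts to 0-based half-open
#' coordinates; when the series was read from a bedGraph file the original
#' genomic coordinates are used, otherwise the data index.
#'
#' @param fit a `"penalised_fit"` or `"constrained_fit"`.
#' @param series the signal the fit was computed from.
#' @param path output file.
#' @param format `"csv"` or `"bed"`.
#' @param k constrained fits: which segmentation to write.
#' @param model the [cost_model()] used for the fit.
#' @param metadata named list of extra `key: value` header comments
#'   (e.g. seed, sigma_hat).
#' @return the segment table, invisibly.
#' @export
write_segmentation <- function(fit, series, path, format = c("csv", "bed"),
                               k = NULL, model = cost_model(fit$family),
                               metadata = list()) {
  format <- match.arg(format)
  series <- time_series(series)
  tab <- segment_table(fit, series, k = k, model = model)
  hdr <- c(
    paste0("# method: ", fit$method),
    if (inherits(fit, "penalised_fit"))
      paste0("# beta: ", format(fit$beta, digits = 12))
    else
      paste0("# K: ", fit$K, if (!is.null(k)) paste0(" (k = ", k, ")")),
    paste0("# family: ", fit$family),
    vapply(names(metadata), function(nm)
      paste0("# ", nm, ": ", metadata[[nm]]), character(1))
  )
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(tab, con, sep = ",", row.names = FALSE,
                       quote = FALSE)
  } else {
    chrom <- attr(series, "chrom")
    gstart <- attr(series, "start")
    gend <- attr(series, "end")
    if (is.null(chrom)) {
      bed <- data.frame(chrom = "signal", start = tab$start - 1L,
                        end = tab$end,
                        name = paste0("segment_", tab$segment),
                        score = signif(tab$mean, 8))
    } else {
      bed <- data.frame(chrom = chrom[tab$start],
                        start = gstart[tab$start], end = gend[tab$end],
                        name = paste0("segment_", tab$segment),
                        score = signif(tab$mean, 8))
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(bed, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(tab)
}
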