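# Homology-search hit tables and the benchmark close-homolog filter.

#' Construct a hit table
#'
#' @param query Target accession.
#' @param hits Data frame with columns `subject`, `evalue`. Duplicate
#'   subjects are collapsed to their minimum E-value; rows are sorted by
#'   ascending E-value (ties by subject).
#' @return A `hit_table`.
#' @export
hit_table <- function(query, hits) {
  stopifnot(is.data.frame(hits))
  if (!nrow(hits)) {
    hits <- data.frame(subject = character(0), evalue = numeric(0))
  } else {
    hits <- data.frame(subject = as.character(hits$subject),
                       evalue = as.numeric(hits$evalue))
    if (any(hits$evalue < 0)) stop("negative E-value")
    # best (smallest) E-value per subject
    hits <- hits[order(hits$evalue, hits$subject, method = "radix"), , drop = FALSE]
    hits <- hits[!duplicated(hits$subject), , drop = FALSE]
    hits <- hits[order(hits$evalue, hits$subject, method = "radix"), , drop = FALSE]
    rownames(hits) <- NULL
  }
  structure(list(query = as.character(query), hits = hits), class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat("hit_table:", x$query, "-", nrow(x$hits), "hits\n")
  invisible(x)
}

#' Parse BLAST tabular hit files
#'
#' Accepts standard 12-column BLAST `-outfmt 6` (query, subject, ...,
#' E-value in column 11) or a reduced 3-column dialect
#' `(query, subject, evalue)`. E-value 0 is preserved as literal 0: the
#' log transform in scoring floors it later, but the benchmark `x = 0`
#' homolog filter needs the literal value.
#'
#' @param x Path to a hit file, or a character vector of its lines.
#' @return List of `hit_table`, one per distinct query, in order of first
#'   appearance; duplicate subjects collapsed to the minimum E-value.
#' @export
parse_hits <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else as.character(x)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(list())

  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  ecol <- ifelse(ncol >= 11L, 11L, 3L)
  if (any(ncol < 3L))
    stop("line ", lineno[which(ncol < 3L)[1L]], ": expected >= 3 tab-separated columns")
  q <- vapply(parts, `[[`, "", 1L)
  s <- vapply(parts, `[[`, "", 2L)
  ev <- suppressWarnings(as.numeric(mapply(function(p, k) p[[k]], parts, ecol)))
  if (anyNA(ev))
    stop("line ", lineno[which(is.na(ev))[1L]], ": non-numeric E-value")

  out <- lapply(unique(q), function(qq) {
    i <- q == qq
    hit_table(qq, data.frame(subject = s[i], evalue = ev[i]))
  })
  out
}

#' Write hit tables in the reduced 3-column dialect
#' @param tables A `hit_table` or list of them. @param path Output path.
#' @export
write_hits <- function(tables, path) {
  if (inherits(tables, "hit_table")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(t) {
    if (!nrow(t$hits)) return(NULL)
    data.frame(query = t$query, subject = t$hits$subject,
               evalue = sprintf("%.17g", t$hits$evalue))
  }))
  if (is.null(rows)) rows <- data.frame(query = character(0), subject = character(0),
                                        evalue = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove close homologs from a hit table
#'
#' Benchmark filter simulating the absence of close homologs: hits at or
#' below the E-value cutoff (more significant) are removed. At `cutoff = 0`
#' only hits with an E-value of exactly 0 are removed, i.e. annotation
#' transfer from exact sequence matches is suppressed.
#'
#' @param table A `hit_table`. @param cutoff Non-negative E-value cutoff.
#' @return Filtered `hit_table` (subset, order preserved).
#' @export
remove_close_homologs <- function(table, cutoff) {
  stopifnot(inherits(table, "hit_table"), cutoff >= 0)
  keep <- if (cutoff > 0) table$hits$evalue > cutoff else table$hits$evalue != 0
  out <- table
  out$hits <- table$hits[keep, , drop = FALSE]
  rownames(out$hits) <- NULL
  out
}
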