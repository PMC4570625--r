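# Protein -> GO annotation store; FAM conditional-probability matrix,
# evidence filtering, coverage statistics and term frequencies.

#' Construct an annotation database
#'
#' @param records Data frame with columns `protein`, `go_id`, `evidence`,
#'   `source`. Duplicate `(protein, go_id, source)` triples are collapsed.
#' @param proteins Character vector of all protein accessions known to the
#'   database, including unannotated ones; defaults to the proteins seen in
#'   `records`. Passing the full set explicitly is what makes sequence
#'   coverage meaningful.
#' @return An `annotation_db` object.
#' @export
annotation_db <- function(records, proteins = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("protein", "go_id", "evidence", "source")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  records <- records[, need]
  for (col in need) records[[col]] <- as.character(records[[col]])
  bad <- !grepl("^[A-Z]{2,3}$", records$evidence)
  if (any(bad))
    stop("invalid evidence code(s): ",
         paste(unique(records$evidence[bad])[1:min(3, sum(bad))], collapse = ", "))
  records <- records[!duplicated(records[c("protein", "go_id", "source")]), , drop = FALSE]
  rownames(records) <- NULL
  if (is.null(proteins)) proteins <- unique(records$protein)
  proteins <- unique(as.character(proteins))
  if (!all(records$protein %in% proteins))
    stop("records reference proteins absent from the proteins set")
  structure(list(records = records, proteins = proteins), class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("annotation_db:", nrow(x$records), "records,",
      length(x$proteins), "proteins,",
      length(unique(x$records$go_id)), "distinct GO terms\n")
  invisible(x)
}

#' Read an annotation TSV
#'
#' Expects columns `protein_id`, `go_id`, `evidence`, `source` (with or
#' without a header line). An optional side file lists all known protein
#' accessions, one per line, so unannotated sequences are representable.
#'
#' @param path Annotation TSV path.
#' @param proteins_file Optional path to a one-accession-per-line file.
#' @return An `annotation_db`.
#' @export
read_annotations <- function(path, proteins_file = NULL) {
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("protein", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE,
                          colClasses = "character")
  names(df) <- c("protein", "go_id", "evidence", "source")[seq_len(ncol(df))]
  proteins <- if (!is.null(proteins_file)) readLines(proteins_file, warn = FALSE) else NULL
  annotation_db(df, proteins = proteins)
}

#' Write an annotation database as TSV
#' @param db An `annotation_db`.
#' @param path Output path.
#' @export
write_annotations <- function(db, path) {
  out <- db$records
  names(out)[1L] <- "protein_id"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GAF 2.x gene-association file
#'
#' Maps GAF columns 2 (DB object id), 5 (GO id), 7 (evidence code) and 15
#' (assigned-by) onto the annotation record fields. Comment lines starting
#' with `!` are skipped.
#'
#' @param path GAF file path.
#' @return An `annotation_db`.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) stop("empty GAF file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 15L)) stop("GAF rows must have >= 15 columns")
  df <- data.frame(protein  = vapply(parts, `[[`, "", 2L),
                   go_id    = vapply(parts, `[[`, "", 5L),
                   evidence = vapply(parts, `[[`, "", 7L),
                   source   = vapply(parts, `[[`, "", 15L),
                   stringsAsFactors = FALSE)
  annotation_db(df)
}

# One row per (protein, go_id): a protein either has a term or it does not,
# regardless of how many resources assigned it.
.direct_pairs <- function(db) {
  unique(db$records[c("protein", "go_id")])
}

#' Build the functional association matrix (FAM)
#'
#' Conditional probabilities `P(f_a | f_j)` that term `f_a` co-annotates a
#' protein given that `f_j` does: the number of proteins directly annotated
#' with both terms divided by the number annotated with `f_j`. Counting is on
#' directly assigned terms only (no DAG propagation), and duplicate
#' assignments of the same term from different resources count once per
#' protein.
#'
#' @param db An `annotation_db`.
#' @return A `fam_matrix`: list with `co` (sparse symmetric co-annotation
#'   count matrix, terms x terms) and `counts` (named integer vector of
#'   per-term protein counts). Use [fam_prob()] / [fam_associates()] to query.
#' @export
build_fam <- function(db) {
  pairs <- .direct_pairs(db)
  if (!nrow(pairs)) {
    co <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(0L, 0L))
    return(structure(list(co = co, counts = stats::setNames(integer(0), character(0))),
                     class = "fam_matrix"))
  }
  terms <- sort(unique(pairs$go_id), method = "radix")
  prots <- unique(pairs$protein)
  inc <- Matrix::sparseMatrix(i = match(pairs$protein, prots),
                              j = match(pairs$go_id, terms),
                              x = 1, dims = c(length(prots), length(terms)),
                              dimnames = list(prots, terms))
  co <- Matrix::crossprod(inc)              # co[j, a] = #proteins with both
  counts <- stats::setNames(as.integer(Matrix::diag(co)), terms)
  structure(list(co = co, counts = counts), class = "fam_matrix")
}

#' @export
print.fam_matrix <- function(x, ...) {
  nz <- length(x$co@x)
  cat("fam_matrix:", length(x$counts), "terms,", nz, "nonzero co-annotation pairs\n")
  invisible(x)
}

#' Conditional probability P(f_a | f_j) from a FAM
#' @param fam A `fam_matrix`.
#' @param f_j Given term. @param f_a Associated term.
#' @return `P(f_a | f_j)`; 0 when either term is unannotated or never co-occurs.
#' @export
fam_prob <- function(fam, f_j, f_a) {
  terms <- names(fam$counts)
  if (!(f_j %in% terms) || !(f_a %in% terms)) return(0)
  as.numeric(fam$co[f_j, f_a]) / fam$counts[[f_j]]
}

#' All terms associated with f_j at or above a FAM cutoff
#' @param fam A `fam_matrix`. @param f_j Given term.
#' @param cutoff Minimum conditional probability in \[0, 1\].
#' @return Named numeric vector of `P(f_a | f_j)` over qualifying `f_a`
#'   (always includes `f_j` itself at 1 when annotated).
#' @export
fam_associates <- function(fam, f_j, cutoff) {
  terms <- names(fam$counts)
  if (!(f_j %in% terms)) return(stats::setNames(numeric(0), character(0)))
  row <- fam$co[f_j, ]
  p <- as.numeric(row) / fam$counts[[f_j]]
  names(p) <- terms
  p[p >= cutoff & p > 0]
}

#' Remove records by evidence code
#'
#' @param db An `annotation_db`.
#' @param exclude Character vector of evidence codes to drop (e.g. `"IEA"`).
#' @return An `annotation_db` with matching records removed; the proteins set
#'   is unchanged.
#' @export
filter_evidence <- function(db, exclude) {
  keep <- !(db$records$evidence %in% exclude)
  out <- db
  out$records <- db$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Fraction of proteins with at least one annotation
#' @param db An `annotation_db` with a non-empty proteins set.
#' @return Fraction in \[0, 1\].
#' @export
sequence_coverage <- function(db) {
  if (!length(db$proteins)) stop("proteins set is empty")
  length(intersect(db$proteins, unique(db$records$protein))) / length(db$proteins)
}

#' Fraction of the GO vocabulary represented in the database
#' @param db An `annotation_db`. @param dag A non-empty `go_dag`.
#' @return Fraction of non-obsolete ontology terms that annotate >= 1 protein.
#' @export
go_coverage <- function(db, dag) {
  if (!length(dag$ids)) stop("empty ontology")
  length(intersect(unique(db$records$go_id), dag$ids)) / length(dag$ids)
}

#' Normalized GO-term frequencies
#'
#' Raw frequency of a term is the fraction of proteins directly annotated
#' with it; frequencies are then rescaled so the most frequent term is 1.0.
#'
#' @param db An `annotation_db` with at least one record.
#' @return Named numeric vector of normalized frequencies in (0, 1\].
#' @export
term_frequency <- function(db) {
  pairs <- .direct_pairs(db)
  if (!nrow(pairs)) stop("annotation database has no records")
  counts <- table(pairs$go_id)
  freq <- as.numeric(counts) / length(db$proteins)
  stats::setNames(freq / max(freq), names(counts))
}
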