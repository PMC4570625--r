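# PFP scoring: E-value-weighted GO-term transfer from homology hits with
# FAM association expansion, parental raw-score transfer and max-normalized
# confidences.

#' Scored GO terms for one target
#'
#' @param target Target accession.
#' @param scores Named numeric vector keyed by GO accession.
#' @param stage One of `"raw"`, `"propagated"`, `"confidence"`.
#' @return A `scored_terms` object.
#' @export
scored_terms <- function(target, scores, stage = c("raw", "propagated", "confidence")) {
  stage <- match.arg(stage)
  scores <- if (length(scores)) scores[order(names(scores), method = "radix")]
            else stats::setNames(numeric(0), character(0))
  structure(list(target = as.character(target), scores = scores, stage = stage),
            class = "scored_terms")
}

#' @export
print.scored_terms <- function(x, ...) {
  cat("scored_terms:", x$target, "-", length(x$scores), "terms, stage", x$stage, "\n")
  if (length(x$scores))
    print(utils::head(sort(x$scores, decreasing = TRUE), 5L))
  invisible(x)
}

#' PFP configuration
#'
#' @param b Additive constant keeping per-hit scores positive for hits up to
#'   the E-value-100 search bound; the published value 2 equals log10(100).
#' @param fam_cutoff Minimum conditional probability `P(f_a | f_j)` at which
#'   associated terms are pulled in (the published settings range 0.25-0.9;
#'   0.9 performed best and is the default).
#' @param evalue_ceiling Hits above this E-value are ignored at scoring time.
#' @param evalue_floor Substitute for a literal E-value 0 before the log
#'   (search programs report 0.0 for extreme hits and -log(0) is undefined).
#' @return A `pfp_config` list.
#' @export
pfp_config <- function(b = 2, fam_cutoff = 0.9, evalue_ceiling = 100,
                       evalue_floor = 1e-180) {
  stopifnot(b >= 0, fam_cutoff >= 0, fam_cutoff <= 1, evalue_floor > 0)
  structure(list(b = b, fam_cutoff = fam_cutoff,
                 evalue_ceiling = evalue_ceiling, evalue_floor = evalue_floor),
            class = "pfp_config")
}

#' Direct (raw) PFP scores
#'
#' For each hit `i` with E-value within the ceiling and each GO term `f_j`
#' directly annotating that hit, every term `f_a` with
#' `P(f_a | f_j) >= fam_cutoff` receives
#' `(-log10(Evalue(i)) + b) * P(f_a | f_j)`. The annotating term itself is
#' always included through its self-conditional `P = 1`. Hits whose subjects
#' carry no annotations contribute nothing.
#'
#' @param table A `hit_table`. @param db An `annotation_db`.
#' @param fam A `fam_matrix` built from `db` (or a compatible database).
#' @param cfg A [pfp_config()].
#' @return `scored_terms` at stage `"raw"`.
#' @export
pfp_raw <- function(table, db, fam, cfg = pfp_config()) {
  stopifnot(inherits(table, "hit_table"))
  hits <- table$hits[table$hits$evalue <= cfg$evalue_ceiling, , drop = FALSE]
  pairs <- .direct_pairs(db)
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(hits))) {
    e <- max(hits$evalue[[i]], cfg$evalue_floor)
    w <- -log10(e) + cfg$b
    anns <- pairs$go_id[pairs$protein == hits$subject[[i]]]
    for (fj in anns) {
      assoc <- fam_associates(fam, fj, cfg$fam_cutoff)
      for (k in seq_along(assoc)) {
        fa <- names(assoc)[[k]]
        acc[[fa]] <- (acc[[fa]] %||% 0) + w * assoc[[k]]
      }
    }
  }
  scored_terms(table$query, unlist(as.list(acc)) %||%
                 stats::setNames(numeric(0), character(0)), "raw")
}

# Ancestor-closed annotation counts: number of proteins whose closed direct
# annotation set contains each term. Closure guarantees count(parent) >=
# count(child), so transfer ratios stay <= 1.
.closed_counts <- function(db, dag) {
  pairs <- .direct_pairs(db)
  pairs <- pairs[pairs$go_id %in% dag$ids, , drop = FALSE]
  anc_cache <- new.env(parent = emptyenv())
  closed <- tapply(pairs$go_id, pairs$protein, function(terms) {
    up <- lapply(unique(terms), function(t) {
      got <- anc_cache[[t]]
      if (is.null(got)) { got <- c(t, go_ancestors(dag, t)); anc_cache[[t]] <- got }
      got
    })
    unique(unlist(up, use.names = FALSE))
  })
  counts <- table(unlist(closed, use.names = FALSE))
  stats::setNames(as.integer(counts), names(counts))
}

#' Transfer raw PFP scores to parental terms
#'
#' Each directly scored term passes a share of its raw score to every
#' ancestor, weighted by the proportion of database proteins annotated
#' (after ancestor closure) with the term relative to those annotated with
#' the ancestor. Transfer runs once, from directly scored terms only, so
#' transferred mass is never re-transferred. The sum of direct and
#' transferred scores is the final raw score.
#'
#' @param scores `scored_terms` at stage `"raw"`.
#' @param dag A `go_dag`. @param db The `annotation_db` used for counts.
#' @return `scored_terms` at stage `"propagated"`.
#' @export
pfp_parent_transfer <- function(scores, dag, db) {
  stopifnot(inherits(scores, "scored_terms"), scores$stage == "raw")
  out <- scores$scores
  if (!length(out)) return(scored_terms(scores$target, out, "propagated"))
  unknown <- setdiff(names(out), dag$ids)
  if (length(unknown)) {
    warning("dropping ", length(unknown), " term(s) absent from the ontology: ",
            paste(utils::head(unknown, 3L), collapse = ", "))
    out <- out[setdiff(names(out), unknown)]
  }
  counts <- .closed_counts(db, dag)
  cnt <- function(t) if (t %in% names(counts)) counts[[t]] else 0L
  add <- new.env(parent = emptyenv())
  warned <- FALSE
  for (f in names(out)) {
    cf <- cnt(f)
    if (cf == 0L) next   # unannotated term transfers nothing
    for (p in go_ancestors(dag, f)) {
      cp <- cnt(p)
      if (cp == 0L) { warned <- TRUE; next }
      add[[p]] <- (add[[p]] %||% 0) + out[[f]] * cf / cp
    }
  }
  if (warned) warning("parent term(s) with zero annotation count contributed 0")
  extra <- unlist(as.list(add))
  for (p in names(extra)) out[[p]] <- (if (p %in% names(out)) out[[p]] else 0) + extra[[p]]
  scored_terms(scores$target, out, "propagated")
}

#' Max-normalize propagated scores into confidences
#' @param scores `scored_terms` at stage `"propagated"`.
#' @return `scored_terms` at stage `"confidence"` with maximum 1 when non-empty.
#' @export
pfp_confidence <- function(scores) {
  stopifnot(inherits(scores, "scored_terms"), scores$stage == "propagated")
  s <- scores$scores
  if (length(s) && max(s) > 0) s <- s / max(s)
  scored_terms(scores$target, s, "confidence")
}

#' Full PFP pipeline for one target
#'
#' Raw E-value/FAM scoring, parental raw-score transfer, then
#' max-normalization to confidences.
#'
#' @inheritParams pfp_raw
#' @param dag A `go_dag`.
#' @return `scored_terms` at stage `"confidence"`.
#' @export
pfp_predict <- function(table, db, fam, dag, cfg = pfp_config()) {
  pfp_confidence(pfp_parent_transfer(pfp_raw(table, db, fam, cfg), dag, db))
}
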