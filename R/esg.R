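# ESG scoring: two-level exploration of sequence-similarity space with
# -log10(E-value)-proportional hit weights.

#' Construct an ESG input
#'
#' @param target Target accession.
#' @param level1 `hit_table` from the search seeded by the target.
#' @param level2 Named list of `hit_table`s, one per level-1 subject that was
#'   itself used to seed a second-level search. Every name must appear among
#'   the level-1 subjects.
#' @return An `esg_input`.
#' @export
esg_input <- function(target, level1, level2 = list()) {
  stopifnot(inherits(level1, "hit_table"))
  if (length(level2)) {
    stopifnot(all(vapply(level2, inherits, TRUE, "hit_table")))
    extra <- setdiff(names(level2), level1$hits$subject)
    if (length(extra))
      stop("level-2 seed(s) not among level-1 subjects: ",
           paste(utils::head(extra, 3L), collapse = ", "))
  }
  structure(list(target = as.character(target), level1 = level1, level2 = level2),
            class = "esg_input")
}

#' Per-hit ESG weights within one search level
#'
#' Each retained hit's weight is its share of `-log10(E-value)` relative to
#' the sum over all retained hits of the same search. Hits above E-value 100
#' (the search bound) and hits with E-value >= 1 are excluded: the latter
#' have non-positive logs, which are meaningless as proportions. A literal
#' E-value 0 is floored before the log.
#'
#' @param table A `hit_table`.
#' @param floor Substitute for E-value 0 (default `1e-180`).
#' @return Named numeric vector of weights by subject, summing to 1 when any
#'   hit is retained; empty when all hits are excluded.
#' @export
esg_level_weights <- function(table, floor = 1e-180) {
  stopifnot(inherits(table, "hit_table"))
  h <- table$hits[table$hits$evalue < 1, , drop = FALSE]
  if (!nrow(h)) return(stats::setNames(numeric(0), character(0)))
  logs <- -log10(pmax(h$evalue, floor))
  stats::setNames(logs / sum(logs), h$subject)
}

#' ESG score for one target
#'
#' Level-1 hit `i` contributes its weight `w1(i)` to every GO term directly
#' annotating it; each level-2 hit `j` from the search seeded by `i`
#' contributes `w1(i) * w2_i(j)` to its terms. Per-term scores are the sum of
#' all contributions, clamped to \[0, 1\] (level-1 weights already sum to 1,
#' so the clamp only guards pathological overlaps between levels).
#'
#' @param inp An [esg_input()]. @param db An `annotation_db`.
#' @param floor Substitute for E-value 0 before the log.
#' @return `scored_terms` at stage `"confidence"` with scores in \[0, 1\].
#' @export
esg_score <- function(inp, db, floor = 1e-180) {
  stopifnot(inherits(inp, "esg_input"))
  pairs <- .direct_pairs(db)
  terms_of <- function(subject) pairs$go_id[pairs$protein == subject]
  acc <- new.env(parent = emptyenv())
  bump <- function(terms, w) for (t in terms) acc[[t]] <- (acc[[t]] %||% 0) + w

  w1 <- esg_level_weights(inp$level1, floor)
  for (s in names(w1)) {
    bump(terms_of(s), w1[[s]])
    t2 <- inp$level2[[s]]
    if (!is.null(t2)) {
      w2 <- esg_level_weights(t2, floor)
      for (s2 in names(w2)) bump(terms_of(s2), w1[[s]] * w2[[s2]])
    }
  }
  scores <- unlist(as.list(acc)) %||% stats::setNames(numeric(0), character(0))
  scored_terms(inp$target, pmin(scores, 1), "confidence")
}
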