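# GO vocabulary as a DAG: OBO parsing, ancestor closure, score propagation.

#' Parse a Gene Ontology OBO file
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 file and builds a directed
#' acyclic graph over the non-obsolete terms. Only `is_a` edges are kept;
#' `part_of` and other `relationship:` lines are ignored, matching the
#' minimal CAFA-style reading of the hierarchy. Obsolete terms are dropped
#' (their ids are remembered so downstream inputs referencing them can be
#' discarded with a warning rather than a hard error).
#'
#' @param x Path to an OBO file, or a character vector of OBO lines.
#' @return A `go_dag` object: a list with elements `ids`, `name`
#'   (named character), `namespace` (named character), `parents` (named list
#'   of character vectors of direct `is_a` parents), `children` (inverse of
#'   `parents`), `roots` (ids with no parents, one per namespace in a
#'   well-formed ontology) and `obsolete` (ids of dropped obsolete terms).
#' @examples
#' obo <- c("[Term]", "id: GO:0000001", "name: root",
#'          "namespace: biological_process",
#'          "[Term]", "id: GO:0000002", "name: leaf",
#'          "namespace: biological_process", "is_a: GO:0000001 ! root")
#' dag <- parse_obo(obo)
#' go_ancestors(dag, "GO:0000002")
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(x)
  }
  lines <- trimws(lines)

  # split into stanzas at [Term] / other headers
  hdr <- grep("^\\[", lines)
  if (!length(hdr)) stop("no stanzas found in OBO input")
  starts <- hdr[lines[hdr] == "[Term]"]
  ends <- c(hdr[-1L] - 1L, length(lines))[match(starts, hdr)]

  ids <- character(0); nm <- character(0); ns <- character(0)
  parents <- list(); obsolete <- character(0)
  for (k in seq_along(starts)) {
    body <- lines[seq(starts[k] + 1L, ends[k])]
    field <- function(key) {
      v <- body[startsWith(body, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", v))
    }
    id <- field("id")[1L]
    if (is.na(id) || !grepl("^GO:[0-9]{7}$", id)) {
      if (is.na(id)) stop("[Term] stanza without an id")
      # tolerate non-GO ids in mixed ontologies? no -- this is a GO tool
      stop("malformed GO accession in OBO: ", id)
    }
    if (identical(field("is_obsolete")[1L], "true")) {
      obsolete <- c(obsolete, id)
      next
    }
    isa <- field("is_a")
    isa <- sub(" *!.*$", "", isa)                 # strip trailing "! name"
    ids <- c(ids, id)
    nm <- c(nm, field("name")[1L] %||% "")
    ns <- c(ns, field("namespace")[1L] %||% "")
    parents[[id]] <- unique(isa)
  }
  if (anyDuplicated(ids)) stop("duplicate term id in OBO: ", ids[duplicated(ids)][1L])
  names(nm) <- ids; names(ns) <- ids

  all_parents <- unique(unlist(parents, use.names = FALSE))
  missing <- setdiff(all_parents, ids)   # includes edges into obsolete terms
  if (length(missing))
    stop("is_a parent not defined (or obsolete) in file: ",
         paste(utils::head(missing, 3L), collapse = ", "))

  dag <- structure(list(ids = ids, name = nm, namespace = ns,
                        parents = parents, children = NULL,
                        roots = ids[lengths(parents) == 0L],
                        obsolete = obsolete),
                   class = "go_dag")
  dag$children <- .invert_edges(parents, ids)
  .check_acyclic(dag)
  dag
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a
}

.invert_edges <- function(parents, ids) {
  ch <- vector("list", length(ids)); names(ch) <- ids
  for (id in ids) for (p in parents[[id]]) ch[[p]] <- c(ch[[p]], id)
  ch
}

# Kahn's algorithm; leftover nodes imply a cycle.
.check_acyclic <- function(dag) {
  indeg <- lengths(dag$parents)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  indeg <- indeg  # local copy
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (c in dag$children[[v]]) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (seen < length(dag$ids)) {
    bad <- names(indeg)[indeg > 0L][1L]
    stop("cyclic is_a graph; cycle involves ", bad)
  }
  invisible(TRUE)
}

#' @export
print.go_dag <- function(x, ...) {
  cat("go_dag:", length(x$ids), "terms,", length(x$roots), "root(s),",
      length(x$obsolete), "obsolete dropped\n")
  print(table(x$namespace))
  invisible(x)
}

#' Ancestors of a GO term
#'
#' Transitive closure over `is_a` parent edges, excluding the term itself.
#'
#' @param dag A `go_dag`.
#' @param id A GO accession present in `dag`.
#' @return Character vector of ancestor accessions (possibly empty).
#' @export
go_ancestors <- function(dag, id) {
  if (!id %in% dag$ids) stop("unknown GO id: ", id)
  out <- character(0)
  frontier <- dag$parents[[id]]
  while (length(frontier)) {
    new <- setdiff(frontier, out)
    out <- c(out, new)
    frontier <- unique(unlist(dag$parents[new], use.names = FALSE))
  }
  out
}

#' Propagate term scores up the ontology
#'
#' Extends a score map with every ancestor of each scored term; each term's
#' propagated score is the maximum over its own score and the scores of all
#' its scored descendants. The max rule keeps confidences interpretable as
#' threshold cuts (an ancestor is at least as confidently true as any of its
#' descendants) and makes propagation idempotent. Truth sets are propagated
#' with the same operation using score 1.0 on every true term.
#'
#' Obsolete ids are dropped with a warning; ids absent from the ontology
#' altogether are an error.
#'
#' @param dag A `go_dag`.
#' @param scored Named numeric vector of scores keyed by GO accession.
#' @return Named numeric vector covering `scored` and all ancestors.
#' @export
go_propagate <- function(dag, scored) {
  if (!length(scored)) return(stats::setNames(numeric(0), character(0)))
  ids <- names(scored)
  obs <- ids %in% dag$obsolete
  if (any(obs)) {
    warning("dropping ", sum(obs), " obsolete GO id(s): ",
            paste(utils::head(ids[obs], 3L), collapse = ", "))
    scored <- scored[!obs]; ids <- names(scored)
    if (!length(scored)) return(stats::setNames(numeric(0), character(0)))
  }
  unknown <- setdiff(ids, dag$ids)
  if (length(unknown)) stop("unknown GO id: ", unknown[1L])

  out <- new.env(parent = emptyenv())
  for (i in seq_along(scored)) {
    s <- scored[[i]]
    for (t in c(ids[[i]], go_ancestors(dag, ids[[i]]))) {
      cur <- out[[t]]
      if (is.null(cur) || cur < s) out[[t]] <- s
    }
  }
  res <- unlist(as.list(out))
  res[order(names(res), method = "radix")]
}

#' Per-namespace term counts
#'
#' @param dag A `go_dag`.
#' @return Named integer vector of non-obsolete term counts per namespace.
#' @export
ontology_stats <- function(dag) {
  tab <- table(dag$namespace)
  stats::setNames(as.integer(tab), names(tab))
}
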