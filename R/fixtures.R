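# Deterministic synthetic fixtures: toy DAGs, annotation databases, hit
# tables and multi-method prediction bundles with planted truth, so every
# stage of the pipeline is testable offline and byte-stably.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fixture generation parameters
#'
#' @param seed Integer seed; the same seed yields byte-identical fixtures.
#' @param n_terms Number of ontology terms. @param n_proteins Database size.
#' @param n_methods Number of prediction methods in a bundle.
#' @param agreement Probability that a method reports a planted true term.
#' @param noise Expected number of spurious terms per true term
#'   (binomial rate per method).
#' @param conf_model Lower/upper bound of the uniform confidence draw.
#' @param accuracies Optional per-method accuracy weights (recycled default
#'   0.8).
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_terms = 50L, n_proteins = 30L,
                         n_methods = 3L, agreement = 0.8, noise = 0.1,
                         conf_model = c(0.5, 1.0), accuracies = NULL) {
  stopifnot(n_terms >= 1L, n_proteins >= 1L, n_methods >= 1L,
            agreement >= 0, agreement <= 1, noise >= 0, noise <= 1,
            length(conf_model) == 2L, conf_model[1L] <= conf_model[2L])
  if (is.null(accuracies)) accuracies <- rep(0.8, n_methods)
  stopifnot(length(accuracies) == n_methods,
            all(accuracies >= 0 & accuracies <= 1))
  structure(list(seed = as.integer(seed), n_terms = as.integer(n_terms),
                 n_proteins = as.integer(n_proteins),
                 n_methods = as.integer(n_methods), agreement = agreement,
                 noise = noise, conf_model = conf_model,
                 accuracies = accuracies),
            class = "fixture_spec")
}

.go_id <- function(i) sprintf("GO:%07d", i)

#' Synthesize a random single-namespace GO DAG
#'
#' Term 1 is the namespace root; every later term draws one or two parents
#' uniformly from the earlier terms, so the graph is acyclic by
#' construction with a single root.
#'
#' @param spec A [fixture_spec()].
#' @return A `go_dag`.
#' @export
synth_dag <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_preserved_seed(spec$seed, {
    n <- spec$n_terms
    ids <- .go_id(seq_len(n))
    parents <- vector("list", n); names(parents) <- ids
    parents[[1L]] <- character(0)
    for (i in seq_len(n)[-1L]) {
      k <- if (i > 2L) sample(1:2, 1L) else 1L
      parents[[i]] <- ids[sample.int(i - 1L, min(k, i - 1L))]
    }
    dag <- structure(list(ids = ids,
                          name = stats::setNames(paste("synthetic term", seq_len(n)), ids),
                          namespace = stats::setNames(rep("biological_process", n), ids),
                          parents = parents, children = NULL,
                          roots = ids[1L], obsolete = character(0)),
                     class = "go_dag")
    dag$children <- .invert_edges(parents, ids)
    dag
  })
}

#' Synthesize an annotation database over a DAG's vocabulary
#'
#' Each protein receives one to four directly assigned terms drawn from the
#' DAG, with mixed experimental and electronic evidence codes.
#'
#' @param spec A [fixture_spec()]. @param dag A `go_dag`.
#' @return An `annotation_db`.
#' @export
synth_db <- function(spec, dag) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(dag, "go_dag"))
  with_preserved_seed(spec$seed + 1L, {
    prots <- sprintf("P%04d", seq_len(spec$n_proteins))
    rows <- lapply(prots, function(p) {
      terms <- sample(dag$ids, sample(1:4, 1L))
      data.frame(protein = p, go_id = terms,
                 evidence = sample(c("EXP", "IDA", "IEA"), length(terms),
                                   replace = TRUE, prob = c(0.3, 0.2, 0.5)),
                 source = "SYN", stringsAsFactors = FALSE)
    })
    annotation_db(do.call(rbind, rows), proteins = prots)
  })
}

#' Synthesize a homology hit table against database proteins
#'
#' E-values are drawn log-uniformly between `1e-40` and `1`.
#'
#' @param spec A [fixture_spec()]. @param db An `annotation_db`.
#' @param query Query accession. @param n_hits Number of hits.
#' @return A `hit_table`.
#' @export
synth_hits <- function(spec, db, query = "TARGET", n_hits = 5L) {
  with_preserved_seed(spec$seed + 2L, {
    subj <- sample(db$proteins, min(n_hits, length(db$proteins)))
    hit_table(query, data.frame(subject = subj,
                                evalue = 10^stats::runif(length(subj), -40, 0)))
  })
}

#' Synthesize prediction bundles with planted truth
#'
#' For each target a truth set of 3-6 DAG terms is planted. Each method
#' reports each true term with probability `agreement` at a confidence drawn
#' uniformly from `conf_model`, and adds spurious terms at binomial rate
#' `noise` per true term, drawn from outside the truth set.
#'
#' @param spec A [fixture_spec()]. @param dag A `go_dag`.
#' @param n_targets Number of benchmark targets.
#' @return List with `truth` (named list of character truth sets) and
#'   `bundles` (named list of `prediction_bundle`).
#' @export
synth_bundle <- function(spec, dag, n_targets = 5L) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(dag, "go_dag"))
  with_preserved_seed(spec$seed + 3L, {
    targets <- sprintf("T%03d", seq_len(n_targets))
    truth <- list(); bundles <- list()
    for (tg in targets) {
      tset <- sort(sample(dag$ids, sample(3:6, 1L)), method = "radix")
      preds <- lapply(seq_len(spec$n_methods), function(m) {
        hit <- tset[stats::runif(length(tset)) < spec$agreement]
        n_spur <- stats::rbinom(1L, length(tset), spec$noise)
        pool <- setdiff(dag$ids, tset)
        spur <- if (n_spur > 0L && length(pool))
          sample(pool, min(n_spur, length(pool))) else character(0)
        terms <- c(hit, spur)
        conf <- stats::runif(length(terms), spec$conf_model[1L], spec$conf_model[2L])
        method_prediction(paste0("method", m),
                          stats::setNames(conf, terms), spec$accuracies[[m]])
      })
      truth[[tg]] <- tset
      bundles[[tg]] <- prediction_bundle(tg, preds)
    }
    list(truth = truth, bundles = bundles)
  })
}

#' The worked FPM example bundle
#'
#' Three methods predicting five GO terms for one target, with precomputed
#' accuracy weights: method A (accuracy 0.6) predicts GO1:0.5, GO2:0.6,
#' GO3:0.4; method B (accuracy 0.7) predicts GO2:0.7, GO3:0.8, GO4:0.4,
#' GO5:0.6; method C (accuracy 0.5) predicts GO2:0.8, GO3:0.9, GO5:0.6.
#' This is the canonical desk-check input for the FPM weights and the
#' mining iterations.
#'
#' @return A `prediction_bundle` for target `"toy"`.
#' @export
toy_fpm_bundle <- function() {
  prediction_bundle("toy", list(
    method_prediction("MethodA", c(GO1 = 0.5, GO2 = 0.6, GO3 = 0.4), 0.6),
    method_prediction("MethodB", c(GO2 = 0.7, GO3 = 0.8, GO4 = 0.4, GO5 = 0.6), 0.7),
    method_prediction("MethodC", c(GO2 = 0.8, GO3 = 0.9, GO5 = 0.6), 0.5)
  ))
}

#' Write a DAG as a minimal OBO file
#' @param dag A `go_dag`. @param path Output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in dag$ids) {
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$name[[id]]),
                 paste0("namespace: ", dag$namespace[[id]]),
                 if (length(dag$parents[[id]]))
                   paste0("is_a: ", dag$parents[[id]]),
                 ""), con)
  }
  invisible(path)
}
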