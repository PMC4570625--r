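# Ensemble fusion of per-method GO predictions: CONS (accuracy-weighted
# consensus) and FPM (weighted frequent-pattern mining over GO-term sets).

#' One method's prediction for a target
#'
#' @param method Method name.
#' @param conf Named numeric vector of confidences in \[0, 1\] by GO accession.
#' @param accuracy The method's prior accuracy weight in \[0, 1\] (an
#'   F-max-style score, typically computed leave-one-out on a benchmark).
#' @return A `method_prediction`.
#' @export
method_prediction <- function(method, conf, accuracy) {
  conf <- unlist(conf)
  stopifnot(all(conf >= 0 & conf <= 1), accuracy >= 0, accuracy <= 1)
  if (length(conf)) conf <- conf[order(names(conf), method = "radix")]
  structure(list(method = as.character(method), conf = conf,
                 accuracy = as.numeric(accuracy)),
            class = "method_prediction")
}

#' A target's predictions from several methods
#'
#' @param target Target accession.
#' @param methods List of [method_prediction()]s with unique names.
#' @return A `prediction_bundle`.
#' @export
prediction_bundle <- function(target, methods) {
  stopifnot(all(vapply(methods, inherits, TRUE, "method_prediction")))
  nm <- vapply(methods, `[[`, "", "method")
  if (anyDuplicated(nm)) stop("duplicate method name: ", nm[duplicated(nm)][1L])
  names(methods) <- nm
  structure(list(target = as.character(target), methods = methods),
            class = "prediction_bundle")
}

#' @export
print.prediction_bundle <- function(x, ...) {
  cat("prediction_bundle:", x$target, "-", length(x$methods), "methods (",
      paste(names(x$methods), collapse = ", "), ")\n")
  invisible(x)
}

#' CONS consensus score
#'
#' The consensus score of a GO term is the accuracy-weighted sum of the
#' term's confidences over all methods (0 where a method does not predict
#' the term), normalized by the maximum weighted sum over the target's own
#' predicted terms so the top consensus term scores 1. Normalization is per
#' target: the denominator runs over the N unique GO terms predicted for
#' this target.
#'
#' @param bundle A `prediction_bundle` with at least one method.
#' @return `scored_terms` at stage `"confidence"`.
#' @export
cons_score <- function(bundle) {
  stopifnot(inherits(bundle, "prediction_bundle"), length(bundle$methods) >= 1L)
  terms <- sort(unique(unlist(lapply(bundle$methods, function(m) names(m$conf)),
                              use.names = FALSE)), method = "radix")
  if (!length(terms))
    return(scored_terms(bundle$target, stats::setNames(numeric(0), character(0)),
                        "confidence"))
  raw <- stats::setNames(numeric(length(terms)), terms)
  for (m in bundle$methods) {
    if (!length(m$conf)) next
    raw[names(m$conf)] <- raw[names(m$conf)] + m$accuracy * m$conf
  }
  mx <- max(raw)
  if (mx == 0) {
    warning("all consensus scores are zero for target ", bundle$target)
    return(scored_terms(bundle$target, raw, "confidence"))
  }
  scored_terms(bundle$target, raw / mx, "confidence")
}

#' Leave-one-out accuracy weights
#'
#' For each method, the mean of its per-target F-max over all benchmark
#' targets except the one being predicted; used as the method's accuracy
#' weight in CONS and FPM.
#'
#' @param per_target_fmax Numeric matrix or data frame of F-max values,
#'   targets in rows (rownames) and methods in columns.
#' @param target Target accession to hold out.
#' @return Named numeric vector of per-method weights.
#' @export
loo_accuracy <- function(per_target_fmax, target) {
  m <- as.matrix(per_target_fmax)
  if (nrow(m) < 2L) stop("need at least 2 targets for leave-one-out weights")
  if (!target %in% rownames(m)) stop("unknown target: ", target)
  colMeans(m[rownames(m) != target, , drop = FALSE])
}

#' FPM method weight
#'
#' The mean of a method's predicted confidences times its accuracy weight.
#' A method with an empty prediction gets weight 0 (with a warning) and so
#' drops out of the set-weight sums.
#'
#' @param pred A `method_prediction`.
#' @return Scalar weight.
#' @export
fpm_method_weight <- function(pred) {
  stopifnot(inherits(pred, "method_prediction"))
  if (!length(pred$conf)) {
    warning("method ", pred$method, " predicts no terms; weight 0")
    return(0)
  }
  mean(pred$conf) * pred$accuracy
}

.fpm_weights <- function(bundle) {
  vapply(bundle$methods, fpm_method_weight, numeric(1))
}

#' FPM weight of a GO-term set
#'
#' The summed weight of the methods predicting every member of the set,
#' divided by the summed weight of all methods.
#'
#' @param members Character vector of GO accessions (non-empty).
#' @param bundle A `prediction_bundle`.
#' @param method_weights Optional precomputed [fpm_method_weight()] vector
#'   (named by method); computed from `bundle` when omitted.
#' @return Set weight in \[0, 1\]; 0 with a warning when all methods have
#'   weight 0.
#' @export
fpm_set_weight <- function(members, bundle, method_weights = NULL) {
  stopifnot(length(members) >= 1L)
  if (is.null(method_weights)) method_weights <- .fpm_weights(bundle)
  denom <- sum(method_weights)
  if (denom == 0) {
    warning("all method weights are zero; set weight 0")
    return(0)
  }
  supports <- vapply(bundle$methods, function(m) all(members %in% names(m$conf)),
                     logical(1))
  sum(method_weights[supports]) / denom
}

#' A weighted GO-term set
#' @param members Character vector of GO accessions (stored sorted).
#' @param weight Set weight in \[0, 1\].
#' @return A `go_set`.
#' @export
go_set <- function(members, weight) {
  structure(list(members = sort(unique(members), method = "radix"),
                 weight = as.numeric(weight)),
            class = "go_set")
}

#' Mine frequent GO-term sets (apriori-style, weighted)
#'
#' Iteration 1 keeps every singleton whose set weight passes the cutoff,
#' forming the lexicographically ordered list L. Each later iteration
#' extends every surviving set with each L member lexicographically greater
#' than the set's last member, keeping candidates whose weight passes the
#' cutoff, until no new set can be generated. Lexicographic order is plain
#' string order of GO accessions.
#'
#' @param bundle A `prediction_bundle`.
#' @param weight_cutoff Minimum set weight retained (published default 0.7).
#' @return List of iterations; each iteration is a list of [go_set()]s.
#'   When no singleton survives, a single empty iteration is returned.
#' @export
fpm_mine <- function(bundle, weight_cutoff = 0.7) {
  w <- .fpm_weights(bundle)
  terms <- sort(unique(unlist(lapply(bundle$methods, function(m) names(m$conf)),
                              use.names = FALSE)), method = "radix")
  L <- character(0); g1 <- list()
  for (t in terms) {
    sw <- fpm_set_weight(t, bundle, w)
    if (sw >= weight_cutoff) {
      L <- c(L, t)
      g1 <- c(g1, list(go_set(t, sw)))
    }
  }
  glists <- list(g1)
  prev <- g1
  while (length(prev)) {
    nxt <- list()
    for (g in prev) {
      last <- g$members[[length(g$members)]]
      for (l in L[L > last]) {
        cand <- c(g$members, l)
        sw <- fpm_set_weight(cand, bundle, w)
        if (sw >= weight_cutoff) nxt <- c(nxt, list(go_set(cand, sw)))
      }
    }
    if (!length(nxt)) break
    glists <- c(glists, list(nxt))
    prev <- nxt
  }
  glists
}

#' Select the final FPM prediction
#'
#' `maxLen` picks the largest set across all iterations; `maxScoreLen` picks,
#' among the sets attaining the global maximum weight, the largest one. Ties
#' are broken by higher weight (for `maxLen`), then by lexicographically
#' smallest member tuple, so selection is deterministic.
#'
#' @param glists Output of [fpm_mine()].
#' @param mode `"maxLen"` or `"maxScoreLen"`.
#' @return A [go_set()]; empty (`members = character(0)`, weight 0) when
#'   nothing was mined.
#' @export
fpm_select <- function(glists, mode = c("maxLen", "maxScoreLen")) {
  mode <- match.arg(mode)
  all_sets <- unlist(glists, recursive = FALSE)
  if (!length(all_sets)) return(go_set(character(0), 0))
  lens <- vapply(all_sets, function(g) length(g$members), integer(1))
  wts <- vapply(all_sets, `[[`, numeric(1), "weight")
  keys <- vapply(all_sets, function(g) paste(g$members, collapse = "|"), "")
  cand <- if (mode == "maxLen") {
    which(lens == max(lens))
  } else {
    top <- wts >= max(wts) - 1e-12
    which(top & lens == max(lens[top]))
  }
  # ties: highest weight first, then lexicographically smallest tuple
  cand <- cand[order(-wts[cand], keys[cand], method = "radix")]
  all_sets[[cand[[1L]]]]
}

#' Full FPM pipeline for one target
#'
#' Mines frequent GO-term sets and returns the selected set's members as a
#' prediction, each member carrying the set's weight as a uniform
#' confidence (so the result can feed the F-max evaluator).
#'
#' @inheritParams fpm_mine
#' @param mode Selection mode, see [fpm_select()].
#' @return `scored_terms` at stage `"confidence"`.
#' @export
fpm_predict <- function(bundle, weight_cutoff = 0.7, mode = c("maxLen", "maxScoreLen")) {
  sel <- fpm_select(fpm_mine(bundle, weight_cutoff), match.arg(mode))
  scored_terms(bundle$target,
               stats::setNames(rep(sel$weight, length(sel$members)), sel$members),
               "confidence")
}
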