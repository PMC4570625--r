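# CAFA-style evaluation: per-threshold precision/recall, F-max over a
# threshold grid, prior-distribution augmentation, per-target win counting.

#' Evaluation configuration
#'
#' @param thresholds Strictly increasing confidence grid in \[0, 1\]; the
#'   default is the 0.01-step grid `0:100 / 100`, computed by division so
#'   that two-decimal confidences land exactly on grid points.
#' @param propagate Propagate truth and predictions to the ontology root
#'   before comparing (requires a `dag` at evaluation time).
#' @param namespaces GO namespaces to keep, or `NULL` for all three
#'   (requires a `dag` when set).
#' @param count_empty_precision Count targets with an empty prediction set
#'   at a threshold in the precision average (as precision 0) instead of
#'   excluding them. Default `FALSE`: excluded from the precision average
#'   but always counted in recall.
#' @return An `eval_config`.
#' @export
eval_config <- function(thresholds = 0:100 / 100, propagate = TRUE,
                        namespaces = NULL, count_empty_precision = FALSE) {
  stopifnot(all(thresholds >= 0 & thresholds <= 1), !is.unsorted(thresholds, strictly = TRUE))
  structure(list(thresholds = thresholds, propagate = propagate,
                 namespaces = namespaces,
                 count_empty_precision = count_empty_precision),
            class = "eval_config")
}

.as_conf <- function(pred) {
  if (inherits(pred, "scored_terms")) pred$scores else unlist(pred) %||%
    stats::setNames(numeric(0), character(0))
}

#' Precision and recall at one confidence threshold
#'
#' The predicted set at threshold `t` is every term with confidence `>= t`.
#' Precision is `NA` (undefined) when that set is empty.
#'
#' @param truth Character vector of true GO accessions (non-empty).
#' @param pred `scored_terms` or a named numeric confidence vector. Truth and
#'   prediction are compared as-is; propagate both first if evaluating with
#'   parental terms.
#' @param t Threshold in \[0, 1\].
#' @return List with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
pr_at_threshold <- function(truth, pred, t) {
  if (!length(truth)) stop("empty truth set; unannotated targets must be excluded upstream")
  conf <- .as_conf(pred)
  p_t <- names(conf)[conf >= t]
  tp <- length(intersect(truth, p_t))
  fp <- length(setdiff(p_t, truth))
  fn <- length(setdiff(truth, p_t))
  precision <- if (length(p_t)) tp / (tp + fp) else NA_real_
  list(precision = precision, recall = tp / (tp + fn), tp = tp, fp = fp, fn = fn)
}

.prepare_pairs <- function(targets, cfg, dag) {
  lapply(targets, function(tg) {
    truth <- unique(as.character(tg$truth))
    conf <- .as_conf(tg$pred)
    if (!is.null(dag)) {
      if (cfg$propagate) {
        truth <- names(go_propagate(dag, stats::setNames(rep(1, length(truth)), truth)))
        if (length(conf)) conf <- go_propagate(dag, conf)
      }
      if (!is.null(cfg$namespaces)) {
        keep_ns <- function(ids) ids[dag$namespace[ids] %in% cfg$namespaces]
        truth <- keep_ns(intersect(truth, dag$ids))
        conf <- conf[keep_ns(intersect(names(conf), dag$ids))]
      }
    }
    list(truth = truth, conf = conf)
  })
}

#' F-max over a threshold grid
#'
#' At each threshold, precision is averaged over targets with a defined
#' precision (non-empty predicted set, unless `count_empty_precision`) and
#' recall is averaged over all targets; the F-measure is their harmonic
#' mean, and F-max is the maximum across the grid. Thresholds where the
#' average precision is undefined, or where both averages are zero, are
#' skipped.
#'
#' @param targets List of `list(truth = <character>, pred = <scored_terms or
#'   named numeric>)`, one per benchmark target.
#' @param cfg An [eval_config()].
#' @param dag Optional `go_dag`; needed when `cfg$propagate` or
#'   `cfg$namespaces` is set. When `NULL`, truth/predictions are compared
#'   as given.
#' @return List with `fmax`, `threshold` (smallest argmax) and `curve`
#'   (data frame of threshold, precision, recall, f).
#' @export
fmax <- function(targets, cfg = eval_config(), dag = NULL) {
  stopifnot(length(targets) >= 1L)
  pairs <- .prepare_pairs(targets, cfg, dag)
  empty_truth <- vapply(pairs, function(p) length(p$truth) == 0L, logical(1))
  if (any(empty_truth)) stop("target(s) with empty truth set after filtering")
  grid <- cfg$thresholds
  prec <- rec <- f <- rep(NA_real_, length(grid))
  for (k in seq_along(grid)) {
    t <- grid[[k]]
    pr <- lapply(pairs, function(p) pr_at_threshold(p$truth, p$conf, t))
    precs <- vapply(pr, `[[`, numeric(1), "precision")
    recs <- vapply(pr, `[[`, numeric(1), "recall")
    if (cfg$count_empty_precision) precs[is.na(precs)] <- 0
    defined <- !is.na(precs)
    if (!any(defined)) next
    p_avg <- mean(precs[defined])
    r_avg <- mean(recs)
    prec[[k]] <- p_avg; rec[[k]] <- r_avg
    if (p_avg + r_avg > 0) f[[k]] <- 2 * p_avg * r_avg / (p_avg + r_avg)
  }
  if (all(is.na(f))) {
    warning("no threshold yields a defined F-measure; F-max 0")
    return(list(fmax = 0, threshold = NA_real_,
                curve = data.frame(threshold = grid, precision = prec,
                                   recall = rec, f = f)))
  }
  best <- which.max(f)   # first (smallest threshold) among ties up to fp noise
  list(fmax = f[[best]], threshold = grid[[best]],
       curve = data.frame(threshold = grid, precision = prec, recall = rec, f = f))
}

#' Augment a prediction with the prior GO-term distribution
#'
#' The prediction's confidences are first normalized so the maximum is 1.0;
#' the `top_n` most frequent vocabulary terms (by normalized frequency) are
#' then merged in at their frequency, keeping the larger score on collision.
#' The same `top_n` terms are added for every target. The input prediction
#' object is not modified.
#'
#' @param pred `scored_terms` or named numeric confidences.
#' @param freq Named numeric vector of normalized term frequencies, as from
#'   [term_frequency()].
#' @param top_n Number of most-frequent terms to add (published protocol:
#'   1000).
#' @return `scored_terms` at stage `"confidence"`; its `scores` field is
#'   stored term-sorted, so use `sort(x$scores, decreasing = TRUE)` for the
#'   score-ranked view.
#' @export
augment_with_prior <- function(pred, freq, top_n = 1000) {
  target <- if (inherits(pred, "scored_terms")) pred$target else ""
  conf <- .as_conf(pred)
  if (length(conf) && max(conf) > 0) conf <- conf / max(conf)
  ord <- order(-freq, names(freq), method = "radix")
  prior <- freq[ord][seq_len(min(top_n, length(freq)))]
  for (t in names(prior)) {
    cur <- if (t %in% names(conf)) conf[[t]] else -Inf
    if (prior[[t]] > cur) conf[[t]] <- prior[[t]]
  }
  scored_terms(target, conf, "confidence")
}

#' Fraction of targets on which each method achieves the best F-max
#'
#' Ties credit every tied method, so the fractions can sum to more than 1.
#'
#' @param per_target_fmax Numeric matrix or data frame of F-max values,
#'   targets in rows, methods in columns; every target must have a value
#'   for every method.
#' @param tol Numerical tolerance for calling a tie.
#' @return Named numeric vector of win fractions by method.
#' @export
win_counts <- function(per_target_fmax, tol = 1e-12) {
  m <- as.matrix(per_target_fmax)
  if (anyNA(m)) stop("every target needs an F-max value for every method")
  wins <- m >= apply(m, 1L, max) - tol
  colMeans(wins)
}
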