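# In-code fixtures and independent brute-force oracles used across tests.

chain_obo <- function() c(
  "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process",
  "",
  "[Term]", "id: GO:0000002", "name: mid", "namespace: biological_process",
  "is_a: GO:0000001 ! root",
  "",
  "[Term]", "id: GO:0000003", "name: leaf", "namespace: biological_process",
  "is_a: GO:0000002 ! mid"
)

chain_dag <- function() parse_obo(chain_obo())

diamond_dag <- function() {
  parse_obo(system.file("extdata", "diamond.obo", package = "gofuse"))
}

# Random DAG rendered as OBO text (node 1 is the root; parents drawn among
# earlier nodes), so property tests also exercise the parser.
random_obo <- function(n) {
  ids <- sprintf("GO:%07d", seq_len(n))
  lines <- character(0)
  for (i in seq_len(n)) {
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
               paste0("name: node ", i), "namespace: biological_process")
    if (i > 1L) {
      k <- sample.int(min(2L, i - 1L), 1L)
      for (p in ids[sample.int(i - 1L, k)]) lines <- c(lines, paste0("is_a: ", p))
    }
    lines <- c(lines, "")
  }
  lines
}

# Recursive reachability oracle over the parent relation.
oracle_ancestors <- function(dag, id) {
  seen <- character(0)
  recurse <- function(x) {
    for (p in dag$parents[[x]]) {
      if (!p %in% seen) {
        seen <<- c(seen, p)
        recurse(p)
      }
    }
  }
  recurse(id)
  sort(seen, method = "radix")
}

# O(n^2) pairwise co-annotation counter.
oracle_fam_prob <- function(records, f_j, f_a) {
  pairs <- unique(records[c("protein", "go_id")])
  with_j <- unique(pairs$protein[pairs$go_id == f_j])
  if (!length(with_j)) return(0)
  with_both <- intersect(with_j, unique(pairs$protein[pairs$go_id == f_a]))
  length(with_both) / length(with_j)
}

# Direct-loop evaluation of the PFP raw score from explicit inputs:
# hits as data.frame(subject, evalue), annotations as a named list
# subject -> GO terms, fam probabilities as a function(f_j) -> named vector.
oracle_pfp_raw <- function(hits, annotations, fam_row, b = 2, cutoff = 0.9,
                           ceiling = 100, floor = 1e-180) {
  acc <- list()
  for (i in seq_len(nrow(hits))) {
    if (hits$evalue[i] > ceiling) next
    w <- -log10(max(hits$evalue[i], floor)) + b
    for (fj in annotations[[hits$subject[i]]]) {
      probs <- fam_row(fj)
      probs <- probs[probs >= cutoff]
      for (fa in names(probs))
        acc[[fa]] <- (if (is.null(acc[[fa]])) 0 else acc[[fa]]) + w * probs[[fa]]
    }
  }
  unlist(acc)
}

# Exact F-max: every distinct confidence value (plus 0) is a threshold;
# same averaging semantics as the evaluator (targets with an empty
# predicted set are excluded from the precision average).
oracle_fmax <- function(targets) {
  cands <- sort(unique(c(0, unlist(lapply(targets, function(tg) {
    conf <- if (inherits(tg$pred, "scored_terms")) tg$pred$scores else tg$pred
    as.numeric(conf)
  })))))
  cands <- cands[cands >= 0 & cands <= 1]
  best <- 0
  for (t in cands) {
    precs <- numeric(0); recs <- numeric(0)
    for (tg in targets) {
      conf <- if (inherits(tg$pred, "scored_terms")) tg$pred$scores else tg$pred
      p_t <- names(conf)[conf >= t]
      tp <- length(intersect(tg$truth, p_t))
      if (length(p_t)) precs <- c(precs, tp / length(p_t))
      recs <- c(recs, tp / length(tg$truth))
    }
    if (!length(precs)) next
    p <- mean(precs); r <- mean(recs)
    if (p + r > 0) best <- max(best, 2 * p * r / (p + r))
  }
  best
}

# Brute-force frequent-set enumeration: all non-empty subsets of the
# surviving singleton list, filtered by set weight.
oracle_fpm_sets <- function(bundle, cutoff) {
  w <- sapply(bundle$methods, fpm_method_weight)
  terms <- sort(unique(unlist(lapply(bundle$methods, function(m) names(m$conf)))),
                method = "radix")
  L <- terms[vapply(terms, function(t) fpm_set_weight(t, bundle, w) >= cutoff,
                    logical(1))]
  out <- character(0)
  for (k in seq_along(L)) {
    combos <- utils::combn(L, k, simplify = FALSE)
    for (s in combos)
      if (fpm_set_weight(s, bundle, w) >= cutoff)
        out <- c(out, paste(s, collapse = "|"))
  }
  sort(out, method = "radix")
}

flatten_mined <- function(glists) {
  sets <- unlist(glists, recursive = FALSE)
  sort(vapply(sets, function(g) paste(g$members, collapse = "|"), ""),
       method = "radix")
}
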