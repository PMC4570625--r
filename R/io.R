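# Readers/writers for prediction bundles, truth sets and accuracy side
# files (TSV throughout; YAML accepted for accuracies when available).

#' Read a prediction-bundle TSV
#'
#' Columns `target_id`, `method`, `go_id`, `confidence` (header optional).
#' Method accuracy weights come from a side table, see
#' [read_method_accuracies()].
#'
#' @param path Prediction TSV path.
#' @param accuracies Named numeric vector of per-method accuracy weights;
#'   methods absent from it default to accuracy 1 with a warning.
#' @return Named list of `prediction_bundle`, one per target.
#' @export
read_bundles <- function(path, accuracies = NULL) {
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("target", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  names(df) <- c("target_id", "method", "go_id", "confidence")[seq_len(ncol(df))]
  df$confidence <- as.numeric(df$confidence)
  missing <- setdiff(unique(df$method), names(accuracies))
  if (length(missing) && !is.null(accuracies))
    warning("no accuracy weight for method(s) ",
            paste(missing, collapse = ", "), "; using 1")
  acc_of <- function(m) if (m %in% names(accuracies)) accuracies[[m]] else 1
  out <- lapply(split(df, df$target_id), function(d) {
    preds <- lapply(split(d, d$method), function(md) {
      method_prediction(md$method[[1L]],
                        stats::setNames(md$confidence, md$go_id),
                        acc_of(md$method[[1L]]))
    })
    prediction_bundle(d$target_id[[1L]], unname(preds))
  })
  out[order(names(out), method = "radix")]
}

#' Write prediction bundles (or scored terms) as TSV
#'
#' @param x A `prediction_bundle`, `scored_terms`, or a list of either.
#'   Scored terms are written under method name `"gofuse"`.
#' @param path Output path.
#' @export
write_predictions <- function(x, path) {
  if (inherits(x, c("prediction_bundle", "scored_terms"))) x <- list(x)
  rows <- do.call(rbind, lapply(x, function(el) {
    if (inherits(el, "scored_terms")) {
      if (!length(el$scores)) return(NULL)
      data.frame(target_id = el$target, method = "gofuse",
                 go_id = names(el$scores), confidence = el$scores)
    } else {
      do.call(rbind, lapply(el$methods, function(m) {
        if (!length(m$conf)) return(NULL)
        data.frame(target_id = el$target, method = m$method,
                   go_id = names(m$conf), confidence = m$conf)
      }))
    }
  }))
  if (is.null(rows))
    rows <- data.frame(target_id = character(0), method = character(0),
                       go_id = character(0), confidence = numeric(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-method accuracy weights
#'
#' Accepts a two-column TSV (`method`, `accuracy`, header optional) or a
#' flat YAML mapping when the yaml package is installed.
#'
#' @param path Side-file path.
#' @return Named numeric vector of accuracies by method.
#' @export
read_method_accuracies <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML accuracy files requires the yaml package")
    v <- unlist(yaml::read_yaml(path))
    return(v[order(names(v), method = "radix")])
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("method", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2L]]), df[[1L]])
}

#' Read a truth TSV (`target_id`, `go_id`)
#' @param path Truth TSV path.
#' @return Named list of character GO-accession vectors by target.
#' @export
read_truth <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("target", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  names(df) <- c("target_id", "go_id")[seq_len(ncol(df))]
  lapply(split(df$go_id, df$target_id), function(v) sort(unique(v), method = "radix"))
}

#' Write truth sets as TSV
#' @param truth Named list of character GO-accession vectors by target.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  rows <- data.frame(target_id = rep(names(truth), lengths(truth)),
                     go_id = unlist(truth, use.names = FALSE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
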