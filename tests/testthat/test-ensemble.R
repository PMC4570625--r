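test_that("cons_score is the max-normalized accuracy-weighted sum", {
  b <- prediction_bundle("t", list(
    method_prediction("m1", c(a = 1.0, b = 0.5), 0.8),
    method_prediction("m2", c(b = 0.5), 0.4)))
  s <- cons_score(b)
  expect_equal(s$scores[["a"]], 1.0)     # raw 0.8 / max 0.8
  expect_equal(s$scores[["b"]], 0.75)    # raw 0.6 / max 0.8

  # single method: its confidences rescaled to max 1
  one <- cons_score(prediction_bundle("t", list(
    method_prediction("m", c(x = 0.4, y = 0.2), 0.9))))
  expect_equal(unname(one$scores[c("x", "y")]), c(1, 0.5))

  # identical maps under equal weights reduce to the same rescaling
  same <- cons_score(prediction_bundle("t", list(
    method_prediction("m1", c(x = 0.4, y = 0.2), 0.5),
    method_prediction("m2", c(x = 0.4, y = 0.2), 0.5))))
  expect_equal(same$scores, one$scores)

  # all-zero raw maximum: scores stay 0, with a warning
  expect_warning(z <- cons_score(prediction_bundle("t", list(
    method_prediction("m", c(x = 0.4), 0)))), "zero")
  expect_equal(z$scores[["x"]], 0)
})

test_that("cons_score max is exactly 1 whenever any raw score is positive", {
  set.seed(41)
  for (rep in 1:10) {
    preds <- lapply(1:3, function(i)
      method_prediction(paste0("m", i),
                        stats::setNames(runif(4), sample(letters[1:6], 4)),
                        runif(1, 0.1, 1)))
    s <- cons_score(prediction_bundle("t", preds))
    expect_equal(max(s$scores), 1)
  }
})

test_that("leave-one-out accuracy averages over the remaining targets", {
  m <- matrix(c(0.5, 0.7, 0.9), nrow = 3,
              dimnames = list(c("t1", "t2", "t3"), "m"))
  expect_equal(loo_accuracy(m, "t1")[["m"]], 0.8)
  expect_equal(loo_accuracy(m, "t3")[["m"]], 0.6)
  flat <- matrix(0.4, nrow = 3, ncol = 2,
                 dimnames = list(c("t1", "t2", "t3"), c("a", "b")))
  expect_equal(unname(loo_accuracy(flat, "t2")), c(0.4, 0.4))
  expect_error(loo_accuracy(m, "nope"), "unknown")
})

test_that("FPM method and set weights reproduce the worked example", {
  b <- toy_fpm_bundle()
  expect_equal(round(fpm_method_weight(b$methods$MethodA), 1), 0.3)
  expect_equal(round(fpm_method_weight(b$methods$MethodB), 2), 0.44)
  expect_equal(round(fpm_method_weight(b$methods$MethodC), 2), 0.38)
  expect_equal(fpm_method_weight(method_prediction("z", c(g = 0.7), 0)), 0)
  expect_warning(
    w0 <- fpm_method_weight(method_prediction("empty", numeric(0), 0.5)),
    "no terms")
  expect_equal(w0, 0)

  expect_equal(round(fpm_set_weight("GO1", b), 2), 0.27)
  expect_equal(fpm_set_weight("GO2", b), 1.0)
  expect_equal(round(fpm_set_weight("GO4", b), 2), 0.39)
  expect_equal(round(fpm_set_weight("GO5", b), 2), 0.73)
  expect_equal(round(fpm_set_weight(c("GO2", "GO5"), b), 2), 0.73)
})

test_that("fpm_mine reproduces the worked iterations at cutoff 0.5", {
  g <- fpm_mine(toy_fpm_bundle(), 0.5)
  expect_length(g, 3L)
  expect_identical(vapply(g[[1]], function(s) s$members, ""),
                   c("GO2", "GO3", "GO5"))
  expect_identical(lapply(g[[2]], function(s) s$members),
                   list(c("GO2", "GO3"), c("GO2", "GO5"), c("GO3", "GO5")))
  expect_identical(g[[3]][[1]]$members, c("GO2", "GO3", "GO5"))

  # nothing survives an impossible cutoff; cutoff 0 keeps every term
  expect_identical(fpm_mine(toy_fpm_bundle(), 1.01), list(list()))
  g0 <- fpm_mine(toy_fpm_bundle(), 0)
  expect_length(g0[[1]], 5L)
})

test_that("fpm_mine equals brute-force subset enumeration", {
  expect_identical(flatten_mined(fpm_mine(toy_fpm_bundle(), 0.5)),
                   oracle_fpm_sets(toy_fpm_bundle(), 0.5))
  expect_identical(flatten_mined(fpm_mine(toy_fpm_bundle(), 0)),
                   oracle_fpm_sets(toy_fpm_bundle(), 0))
  set.seed(43)
  for (rep in 1:8) {
    preds <- lapply(1:3, function(i) {
      k <- sample(2:5, 1)
      method_prediction(paste0("m", i),
                        stats::setNames(runif(k), sample(paste0("GO", 1:6), k)),
                        runif(1, 0.2, 1))
    })
    bundle <- prediction_bundle("t", preds)
    cutoff <- runif(1, 0.2, 0.8)
    mined <- fpm_mine(bundle, cutoff)
    if (length(mined[[1]]))
      expect_identical(flatten_mined(mined), oracle_fpm_sets(bundle, cutoff))
  }
})

test_that("set weights are anti-monotone under set extension", {
  set.seed(47)
  for (rep in 1:10) {
    preds <- lapply(1:4, function(i)
      method_prediction(paste0("m", i),
                        stats::setNames(runif(4), sample(paste0("GO", 1:7), 4)),
                        runif(1, 0.1, 1)))
    bundle <- prediction_bundle("t", preds)
    terms <- unique(unlist(lapply(preds, function(p) names(p$conf))))
    s <- sample(terms, 2L)
    sup <- c(s, sample(setdiff(terms, s), 1L))
    for (sub in s)
      expect_lte(fpm_set_weight(sup, bundle), fpm_set_weight(sub, bundle) + 1e-12)
  }
})

test_that("fpm_select picks maxLen and maxScoreLen deterministically", {
  g <- fpm_mine(toy_fpm_bundle(), 0.5)
  ml <- fpm_select(g, "maxLen")
  expect_identical(ml$members, c("GO2", "GO3", "GO5"))
  expect_equal(round(ml$weight, 2), 0.73)

  msl <- fpm_select(g, "maxScoreLen")
  expect_identical(msl$members, c("GO2", "GO3"))
  expect_equal(msl$weight, 1.0)

  # a single surviving singleton is chosen by both modes
  lone <- list(list(go_set("GO9", 0.8)))
  expect_identical(fpm_select(lone, "maxLen")$members, "GO9")
  expect_identical(fpm_select(lone, "maxScoreLen")$members, "GO9")

  expect_identical(fpm_select(list(list()), "maxLen")$members, character(0))
})

test_that("CONS and FPM are invariant under method order", {
  set.seed(53)
  preds <- lapply(1:4, function(i)
    method_prediction(paste0("m", i),
                      stats::setNames(runif(4), sample(paste0("GO", 1:6), 4)),
                      runif(1, 0.2, 1)))
  b1 <- prediction_bundle("t", preds)
  b2 <- prediction_bundle("t", rev(preds))
  expect_equal(cons_score(b1)$scores, cons_score(b2)$scores)
  expect_identical(flatten_mined(fpm_mine(b1, 0.4)), flatten_mined(fpm_mine(b2, 0.4)))
  expect_identical(fpm_select(fpm_mine(b1, 0.4), "maxLen")$members,
                   fpm_select(fpm_mine(b2, 0.4), "maxLen")$members)
})

test_that("fpm_predict carries the selected set weight as uniform confidence", {
  p <- fpm_predict(toy_fpm_bundle(), 0.5, "maxLen")
  expect_setequal(names(p$scores), c("GO2", "GO3", "GO5"))
  expect_equal(unname(p$scores), rep(fpm_set_weight(c("GO2", "GO3", "GO5"),
                                                    toy_fpm_bundle()), 3))
})
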