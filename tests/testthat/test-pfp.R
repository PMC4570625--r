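# Databases used for the hand-evaluated raw-score cases.
pfp_db_fg <- function() {
  # h1 carries f only; p2 carries f and g, so P(g|f) = 0.5 and P(f|f) = 1
  annotation_db(data.frame(
    protein = c("h1", "p2", "p2"),
    go_id = c("f", "f", "g"),
    evidence = "EXP", source = "S", stringsAsFactors = FALSE))
}

test_that("pfp_raw reproduces the hand-evaluated score cases", {
  db <- pfp_db_fg()
  fam <- build_fam(db)

  # one hit at 1e-10 annotated f: (10 + 2) * 1 = 12
  tab <- hit_table("q", data.frame(subject = "h1", evalue = 1e-10))
  s <- pfp_raw(tab, db, fam, pfp_config(fam_cutoff = 0.9))
  expect_equal(s$scores[["f"]], 12)
  expect_false("g" %in% names(s$scores))

  # association expansion at a permissive cutoff: s(g) = 12 * 0.5 = 6
  s2 <- pfp_raw(tab, db, fam, pfp_config(fam_cutoff = 0.25))
  expect_equal(s2$scores[["g"]], 6)
  expect_equal(s2$scores[["f"]], 12)

  # two hits at 1e-10 and 1e-2 both annotated f: 12 + 4 = 16
  db3 <- annotation_db(data.frame(protein = c("h1", "h2"), go_id = "f",
                                  evidence = "EXP", source = "S"))
  tab3 <- hit_table("q", data.frame(subject = c("h1", "h2"),
                                    evalue = c(1e-10, 1e-2)))
  s3 <- pfp_raw(tab3, db3, build_fam(db3), pfp_config(fam_cutoff = 0.9))
  expect_equal(s3$scores[["f"]], 16)
})

test_that("pfp_raw honors the E-value ceiling, the zero floor and empty input", {
  db <- pfp_db_fg()
  fam <- build_fam(db)
  over <- hit_table("q", data.frame(subject = "h1", evalue = 200))
  expect_length(pfp_raw(over, db, fam, pfp_config())$scores, 0L)

  zero <- hit_table("q", data.frame(subject = "h1", evalue = 0))
  s <- pfp_raw(zero, db, fam, pfp_config(evalue_floor = 1e-180))
  expect_equal(s$scores[["f"]], 182)

  empty <- hit_table("q", data.frame(subject = character(0), evalue = numeric(0)))
  expect_length(pfp_raw(empty, db, fam, pfp_config())$scores, 0L)
})

test_that("pfp_raw matches an independent direct-loop evaluation", {
  set.seed(23)
  for (rep in 1:5) {
    df <- data.frame(protein = sprintf("p%02d", sample.int(12, 60, replace = TRUE)),
                     go_id = sprintf("GO:%07d", sample.int(8, 60, replace = TRUE)),
                     evidence = "EXP", source = "S", stringsAsFactors = FALSE)
    db <- annotation_db(df)
    fam <- build_fam(db)
    terms <- names(fam$counts)
    tab <- hit_table("q", data.frame(subject = sample(db$proteins, 5L),
                                     evalue = 10^runif(5, -30, 1)))
    cutoff <- sample(c(0.25, 0.5, 0.9, 1.0), 1L)
    got <- pfp_raw(tab, db, fam, pfp_config(fam_cutoff = cutoff))
    anns <- lapply(stats::setNames(nm = db$proteins), function(p)
      unique(df$go_id[df$protein == p]))
    fam_row <- function(fj) vapply(stats::setNames(nm = terms),
                                   function(fa) fam_prob(fam, fj, fa), numeric(1))
    want <- oracle_pfp_raw(tab$hits, anns, fam_row, cutoff = cutoff)
    expect_equal(got$scores[order(names(got$scores))],
                 want[order(names(want))])
  }
})

test_that("raising the FAM cutoff or dropping a hit never raises a score", {
  set.seed(31)
  df <- data.frame(protein = sprintf("p%02d", sample.int(10, 50, replace = TRUE)),
                   go_id = sprintf("GO:%07d", sample.int(6, 50, replace = TRUE)),
                   evidence = "EXP", source = "S", stringsAsFactors = FALSE)
  db <- annotation_db(df)
  fam <- build_fam(db)
  tab <- hit_table("q", data.frame(subject = sample(db$proteins, 6L),
                                   evalue = 10^runif(6, -20, 1)))
  lo <- pfp_raw(tab, db, fam, pfp_config(fam_cutoff = 0.25))$scores
  hi <- pfp_raw(tab, db, fam, pfp_config(fam_cutoff = 0.9))$scores
  expect_true(all(names(hi) %in% names(lo)))
  expect_true(all(hi <= lo[names(hi)] + 1e-12))

  fewer <- hit_table("q", tab$hits[-1L, ])
  sub <- pfp_raw(fewer, db, fam, pfp_config(fam_cutoff = 0.25))$scores
  expect_true(all(names(sub) %in% names(lo)))
  expect_true(all(sub <= lo[names(sub)] + 1e-12))
})

test_that("parental transfer adds count-ratio shares of the raw score", {
  dag <- chain_dag()
  # closed counts: leaf 5, mid 20, root 20
  df <- rbind(data.frame(protein = sprintf("a%02d", 1:5), go_id = "GO:0000003"),
              data.frame(protein = sprintf("b%02d", 1:15), go_id = "GO:0000002"))
  df$evidence <- "EXP"; df$source <- "S"
  db <- annotation_db(df)
  raw <- scored_terms("q", c("GO:0000003" = 12), "raw")
  out <- pfp_parent_transfer(raw, dag, db)
  expect_equal(out$scores[["GO:0000002"]], 12 * 5 / 20)
  expect_equal(out$scores[["GO:0000003"]], 12)       # direct score retained
  expect_identical(out$stage, "propagated")

  # a term with no ancestors is unchanged
  root_only <- scored_terms("q", c("GO:0000001" = 4), "raw")
  expect_equal(pfp_parent_transfer(root_only, dag, db)$scores[["GO:0000001"]], 4)

  # additive contract: two children with ratios 0.5 each
  dag2 <- parse_obo(c("[Term]", "id: GO:0000001", "name: r",
                      "namespace: biological_process", "",
                      "[Term]", "id: GO:0000002", "name: c1",
                      "namespace: biological_process", "is_a: GO:0000001", "",
                      "[Term]", "id: GO:0000003", "name: c2",
                      "namespace: biological_process", "is_a: GO:0000001"))
  df2 <- rbind(data.frame(protein = sprintf("x%02d", 1:5), go_id = "GO:0000002"),
               data.frame(protein = sprintf("y%02d", 1:5), go_id = "GO:0000003"))
  df2$evidence <- "EXP"; df2$source <- "S"
  out2 <- pfp_parent_transfer(scored_terms("q", c("GO:0000002" = 10,
                                                  "GO:0000003" = 6), "raw"),
                              dag2, annotation_db(df2))
  expect_equal(out2$scores[["GO:0000001"]], 8)
})

test_that("confidence normalization rescales to a maximum of 1", {
  prop <- scored_terms("q", c(f = 16, g = 8), "propagated")
  conf <- pfp_confidence(prop)
  expect_equal(unname(conf$scores[c("f", "g")]), c(1, 0.5))
  expect_identical(conf$stage, "confidence")
  one <- pfp_confidence(scored_terms("q", c(f = 3), "propagated"))
  expect_equal(one$scores[["f"]], 1)
  flat <- pfp_confidence(scored_terms("q", c(a = 2, b = 2), "propagated"))
  expect_equal(unname(flat$scores), c(1, 1))
  expect_length(pfp_confidence(scored_terms("q", numeric(0), "propagated"))$scores, 0L)
})

test_that("the full PFP pipeline yields max-normalized confidences over the DAG", {
  spec <- fixture_spec(seed = 5, n_terms = 20, n_proteins = 25)
  dag <- synth_dag(spec)
  db <- synth_db(spec, dag)
  fam <- build_fam(db)
  tab <- synth_hits(spec, db, n_hits = 6L)
  pred <- pfp_predict(tab, db, fam, dag, pfp_config(fam_cutoff = 0.5))
  expect_identical(pred$stage, "confidence")
  expect_gt(length(pred$scores), 0L)
  expect_equal(max(pred$scores), 1)
  # root of every scored term is present via parental transfer
  expect_true(dag$roots %in% names(pred$scores))
})
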