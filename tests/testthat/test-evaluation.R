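test_that("Wang similarity reproduces hand-computed chain values", {
  ch3 <- ch3_ontology()
  cfg <- similarity_config(0.5)
  expect_equal(wang_similarity(ch3, "OBT:0003", "OBT:0003", cfg), 1)
  expect_equal(wang_similarity(ch3, "OBT:0003", "OBT:0002", cfg), 9 / 13)
  expect_equal(wang_similarity(ch3, "OBT:0003", "OBT:0001", cfg), 5 / 11)
  expect_error(wang_similarity(ch3, "OBT:0003", "NOPE", cfg),
               "unknown concept")
  expect_error(similarity_config(1), "\\(0, 1\\)")
})

test_that("Wang similarity matches the brute-force path oracle on random DAGs", {
  for (n in c(10L, 20L, 30L)) {
    onto <- generate_ontology(synth_config(n_concepts = n, max_parents = 3L,
                                           seed = n))
    cfg <- similarity_config(0.65)
    for (a in onto$concepts) {
      for (b in onto$concepts) {
        expect_equal(wang_similarity(onto, a, b, cfg),
                     oracle_wang(onto, a, b, 0.65), tolerance = 1e-9)
      }
    }
  }
})

test_that("Wang similarity is symmetric, 1 only on identity, decreasing up a chain", {
  onto <- generate_ontology(synth_config(n_concepts = 30L, max_parents = 2L,
                                         seed = 77L))
  cfg <- similarity_config()
  picks <- onto$concepts[seq(1L, 30L, by = 3L)]
  for (a in picks) {
    for (b in picks) {
      sab <- wang_similarity(onto, a, b, cfg)
      expect_equal(sab, wang_similarity(onto, b, a, cfg))
      expect_true(sab > 0 && sab <= 1)
      if (a != b) expect_lt(sab, 1)
    }
  }
  ch3 <- ch3_ontology()
  expect_gt(wang_similarity(ch3, "OBT:0003", "OBT:0002", cfg),
            wang_similarity(ch3, "OBT:0003", "OBT:0001", cfg))
})

test_that("scoring aggregates semantic and strict measures per mention", {
  ch3 <- ch3_ontology()
  cfg <- similarity_config(0.5)
  mk <- function(mention, concept) {
    structure(list(mention = mention, status = "ok",
                   ranking = data.frame(concept = concept, score = 1)),
              class = "concept_prediction")
  }
  # exact predictions everywhere
  preds <- list(mk("m1", "OBT:0003"), mk("m2", "OBT:0001"))
  refs <- list(m1 = "OBT:0003", m2 = "OBT:0001")
  rep1 <- score_predictions(preds, refs, ch3, cfg)
  expect_equal(rep1$semantic_score, 1)
  expect_equal(rep1$strict_score, 1)

  # an overgeneralized prediction earns partial semantic credit only
  rep2 <- score_predictions(list(mk("m1", "OBT:0002")),
                            list(m1 = "OBT:0003"), ch3, cfg)
  expect_equal(rep2$semantic_score, 9 / 13)
  expect_equal(rep2$strict_score, 0)

  # no-vector mentions score zero on both measures and are counted
  nv <- structure(list(mention = "m1", status = "no_vector",
                       ranking = data.frame(concept = character(),
                                            score = numeric())),
                  class = "concept_prediction")
  rep3 <- score_predictions(list(nv), list(m1 = "OBT:0003"), ch3, cfg)
  expect_equal(rep3$semantic_score, 0)
  expect_equal(rep3$strict_score, 0)
  expect_equal(rep3$n_no_vector, 1L)

  # multi-reference mentions take the best-matching reference
  rep4 <- score_predictions(list(mk("m1", "OBT:0002")),
                            list(m1 = c("OBT:0001", "OBT:0002")), ch3, cfg)
  expect_equal(rep4$semantic_score, 1)
  expect_equal(rep4$strict_score, 1)

  expect_error(score_predictions(preds, list(m1 = "OBT:0003"), ch3, cfg),
               "without a reference")
})

test_that("the default decay sweep emits 11 rows with strict <= semantic", {
  f <- synth_fixture()
  tab <- sweep_decay(f$onto, f$train_pairs, f$eval_pairs, f$emb)
  expect_equal(nrow(tab), 11L)
  expect_equal(tab$w, seq(0, 1, by = 0.1))
  expect_true(all(tab$strict_score <= tab$semantic_score))
  expect_true(all(tab$semantic_score >= 0 & tab$semantic_score <= 1))
  expect_error(sweep_decay(f$onto, f$train_pairs, f$eval_pairs, f$emb,
                           grid = c(0, 1.5)), "\\[0, 1\\]")
})

test_that("a planted zero-noise instance is solved perfectly at w = 1", {
  onto <- generate_ontology(synth_config(n_concepts = 20L, seed = 31L))
  sso <- build_decay_sso(onto, 1)
  pl <- generate_planted_instance(onto, sso,
                                  synth_config(n_concepts = 20L,
                                               embed_dim = 20L, seed = 31L))
  p <- fit_projection(pl$x, pl$concepts, sso, normalize_targets = FALSE)
  preds <- lapply(seq_along(pl$concepts), function(i) {
    predict_concepts(p, sso, pl$x[i, ], mention = pl$concepts[[i]])
  })
  refs <- stats::setNames(as.list(pl$concepts), pl$concepts)
  rep <- score_predictions(preds, refs, onto)
  expect_equal(rep$strict_score, 1)
  expect_equal(rep$semantic_score, 1)
})

test_that("reduction sweep returns one row per fraction with sane dimensions", {
  f <- synth_fixture()
  tab <- sweep_reduction(f$onto, f$train_pairs, f$eval_pairs, f$emb,
                         method = "svd", fractions = c(0, 0.3, 0.6, 0.9))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$target_dim, as.integer(ceiling((1 - tab$fraction) * 50)))
  expect_true(all(tab$strict_score <= tab$semantic_score))
  expect_error(
    sweep_reduction(f$onto, f$train_pairs, f$eval_pairs, f$emb,
                    fractions = c(0, 1)),
    "\\[0, 1\\)"
  )
})

test_that("evaluation reports serialize to TSV + JSON summary", {
  ch3 <- ch3_ontology()
  pred <- structure(list(mention = "m1", status = "ok",
                         ranking = data.frame(concept = "OBT:0002",
                                              score = 0.9)),
                    class = "concept_prediction")
  rep <- score_predictions(list(pred), list(m1 = "OBT:0003"), ch3,
                           similarity_config(0.5))
  path <- tempfile(fileext = ".tsv")
  write_report(rep, path)
  summ <- jsonlite::read_json(paste0(path, ".summary.json"),
                              simplifyVector = TRUE)
  expect_equal(summ$semantic_score, 9 / 13, tolerance = 1e-12)
  expect_equal(summ$contribution_factor, 0.5)
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(nrow(tab), 1L)
})

test_that("random-assignment baseline is reproducible and below a trained run", {
  f <- synth_fixture()
  held <- f$eval_pairs
  refs <- lapply(split(held$concept_id, held$mention_id), unique)
  b1 <- random_assignment_baseline(refs, f$onto, n_draws = 200L, seed = 9L)
  b2 <- random_assignment_baseline(refs, f$onto, n_draws = 200L, seed = 9L)
  expect_equal(b1$semantic_score, b2$semantic_score)
  expect_lt(b1$strict_score, 0.2)
})
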