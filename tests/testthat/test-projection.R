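test_that("least squares recovers a planted exact linear relation", {
  onto <- generate_ontology(synth_config(n_concepts = 20L, seed = 8L))
  sso <- build_decay_sso(onto, 0.5)
  set.seed(1)
  g <- qr.Q(qr(matrix(rnorm(20L * 20L), 20L)))  # invertible
  x <- sso$matrix %*% t(g)
  p <- fit_projection(x, rownames(sso$matrix), sso, loss = "least_squares",
                      normalize_targets = FALSE)
  expect_gt(p$training_meta$final_mean_cosine, 1 - 1e-6)
  for (i in c(1L, 7L, 20L)) {
    pred <- predict_concepts(p, sso, x[i, ])
    expect_equal(pred$ranking$concept[[1L]], rownames(sso$matrix)[[i]])
  }
})

test_that("a single pair is fitted exactly by minimum-norm least squares", {
  sso <- concept_space(matrix(c(2, 0), 1L, 2L, dimnames = list("C:1", NULL)),
                       meta = list(method = "onehot"))
  p <- fit_projection(matrix(1, 1L, 1L), "C:1", sso,
                      normalize_targets = FALSE)
  expect_equal(project(p, 1), c(2, 0), tolerance = 1e-9)
})

test_that("cosine-loss training reaches the least-squares oracle on a planted instance", {
  onto <- generate_ontology(synth_config(n_concepts = 15L, seed = 3L))
  sso <- build_decay_sso(onto, 0.5)
  set.seed(2)
  g <- qr.Q(qr(matrix(rnorm(15L * 15L), 15L)))
  x <- sso$matrix %*% t(g)
  p <- fit_projection(x, rownames(sso$matrix), sso, loss = "cosine")
  expect_gte(p$training_meta$final_mean_cosine, 0.99)
  expect_equal(p$training_meta$loss, "cosine")
})

test_that("project applies the affine map and validates dimensions", {
  p <- structure(
    list(map_matrix = diag(2), bias = c(0, 0),
         training_meta = list(loss = "least_squares")),
    class = "trained_projection"
  )
  expect_equal(project(p, c(3, 4)), c(3, 4))
  p$bias <- c(1, -1)
  expect_equal(project(p, c(0, 0)), c(1, -1))
  expect_error(project(p, c(1, 2, 3)), "dimension")
})

test_that("degenerate all-zero term vectors are rejected with a warning", {
  ch3 <- ch3_ontology()
  sso <- build_decay_sso(ch3, 1)
  x <- rbind(diag(3), 0)
  expect_warning(
    p <- fit_projection(x, c(ch3$concepts, "OBT:0001"), sso),
    "rejected"
  )
  expect_equal(p$training_meta$n_pairs, 3L)
  expect_equal(p$training_meta$n_rejected, 1L)
  expect_error(suppressWarnings(fit_projection(matrix(0, 1, 3), "OBT:0001", sso)),
               "no usable")
  expect_error(fit_projection(diag(3), c(ch3$concepts[-1], "NOPE:1"), sso),
               "NOPE:1")
})

test_that("prediction ranks by cosine, breaks ties lexicographically, flags no-vector", {
  sso <- concept_space(
    rbind("C:b" = c(1, 0), "C:a" = c(1, 0), "C:z" = c(0, 1)),
    meta = list(method = "onehot")
  )
  p <- structure(
    list(map_matrix = diag(2), bias = c(0, 0), training_meta = list()),
    class = "trained_projection"
  )
  pred <- predict_concepts(p, sso, c(1, 0), k = 3L)
  expect_equal(pred$ranking$concept, c("C:a", "C:b", "C:z"))
  expect_true(all(diff(pred$ranking$score) <= 0))

  nv <- predict_concepts(p, sso, c(0, 0))
  expect_equal(nv$status, "no_vector")
  expect_equal(nrow(nv$ranking), 0L)
  expect_error(predict_concepts(p, sso, c(1, 0), k = 4L), "k must be")
})

test_that("rankings are invariant to positive rescaling of the query", {
  onto <- generate_ontology(synth_config(n_concepts = 30L, seed = 14L))
  sso <- build_decay_sso(onto, 0.7)
  pl <- generate_planted_instance(onto, sso,
                                  synth_config(n_concepts = 30L,
                                               embed_dim = 10L,
                                               noise_sigma = 0.05, seed = 14L))
  p <- fit_projection(pl$x, pl$concepts, sso)
  for (i in c(2L, 9L)) {
    r1 <- predict_concepts(p, sso, pl$x[i, ], k = 5L)$ranking$concept
    r2 <- predict_concepts(p, sso, 37.5 * pl$x[i, ], k = 5L)$ranking$concept
    expect_equal(r1, r2)
  }
})

test_that("identity pairs in a shared space self-normalize to rank-1 self", {
  ch3 <- ch3_ontology()
  sso <- build_decay_sso(ch3, 1)
  p <- fit_projection(sso$matrix, rownames(sso$matrix), sso,
                      normalize_targets = TRUE)
  for (c_id in ch3$concepts) {
    expect_equal(predict_concepts(p, sso, sso$matrix[c_id, ])$ranking$concept[[1L]],
                 c_id)
  }
})

test_that("projections round-trip through TSV + JSON sidecar", {
  ch3 <- ch3_ontology()
  sso <- build_decay_sso(ch3, 0.5)
  # rectangular map: term dimension 2, concept dimension 3
  x <- matrix(c(1, 0, 0, 1, 1, 1), 3L, 2L, byrow = TRUE)
  p <- fit_projection(x, ch3$concepts, sso)
  path <- tempfile(fileext = ".tsv")
  write_projection(p, path)
  back <- read_projection(path)
  expect_equal(back$map_matrix, p$map_matrix, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$bias, p$bias, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$training_meta$loss, "least_squares")
  q <- c(0.3, -0.7)
  expect_equal(project(back, q), project(p, q), tolerance = 1e-12)
})
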