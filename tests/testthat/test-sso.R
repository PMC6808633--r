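test_that("decay space matches hand-evaluated w^d entries on the chain", {
  ch3 <- ch3_ontology()
  s1 <- build_decay_sso(ch3, 1)
  expect_equal(unname(s1$matrix),
               rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)))
  s0 <- build_decay_sso(ch3, 0)
  expect_equal(unname(s0$matrix), diag(3))
  s5 <- build_decay_sso(ch3, 0.5)
  expect_equal(unname(s5$matrix["OBT:0003", ]), c(0.25, 0.5, 1))
  expect_equal(s5$meta$method, "decay")
  expect_equal(s1$meta$method, "ancestry")
  expect_equal(s0$meta$method, "onehot")
  expect_error(build_decay_sso(ch3, 1.2), "\\[0, 1\\]")
})

test_that("decay rows have nonzeros exactly on ancestors, self entry 1, values in [0,1]", {
  onto <- generate_ontology(synth_config(n_concepts = 60L, max_parents = 3L,
                                         seed = 9L))
  for (w in c(0, 0.3, 0.7, 1)) {
    s <- build_decay_sso(onto, w)
    expect_true(all(s$matrix >= 0 & s$matrix <= 1))
    expect_equal(unname(diag(s$matrix)), rep(1, 60))
    for (c_id in sample(onto$concepts, 10L)) {
      nz <- colnames(s$matrix)[s$matrix[c_id, ] > 0]
      if (w > 0) {
        expect_setequal(nz, ancestors(onto, c_id))
      } else {
        expect_equal(nz, c_id)
      }
    }
  }
})

test_that("off-self decay entries grow strictly with the decay factor", {
  onto <- generate_ontology(synth_config(n_concepts = 40L, seed = 21L))
  s_lo <- build_decay_sso(onto, 0.4)$matrix
  s_hi <- build_decay_sso(onto, 0.8)$matrix
  off <- s_lo > 0 & row(s_lo) != col(s_lo)
  expect_true(all(s_lo[off] < s_hi[off]))
})

test_that("ancestor sets are reconstructible from the w = 1 matrix", {
  onto <- generate_ontology(synth_config(n_concepts = 40L, max_parents = 2L,
                                         seed = 13L))
  m <- build_decay_sso(onto, 1)$matrix
  for (c_id in onto$concepts) {
    expect_setequal(colnames(m)[m[c_id, ] == 1], ancestors(onto, c_id))
  }
})

test_that("graph-walk embeddings honour shape and determinism contracts", {
  onto <- generate_ontology(synth_config(n_concepts = 25L, seed = 2L))
  cfg <- graph_embed_config(dimension = 16L, seed = 7L)
  s1 <- build_node2vec_sso(onto, cfg)
  expect_equal(dim(s1$matrix), c(25L, 16L))
  expect_equal(rownames(s1$matrix), onto$concepts)
  s2 <- build_node2vec_sso(onto, cfg)
  expect_identical(s1$matrix, s2$matrix)
})

test_that("graph-walk embeddings place adjacent path concepts closer than distant ones", {
  # 30-node path graph; majority vote over 5 seeds
  n <- 30L
  ids <- sprintf("P:%02d", seq_len(n))
  parents <- stats::setNames(c(list(character()), as.list(ids[-n])), ids)
  onto <- ontology(labels = stats::setNames(ids, ids), parents = parents)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  wins <- 0L
  for (seed in 1:5) {
    m <- build_node2vec_sso(onto, graph_embed_config(seed = seed))$matrix
    adj <- mean(vapply(seq_len(n - 1L), function(i) {
      cosine(m[i, ], m[i + 1L, ])
    }, numeric(1L)))
    far_pairs <- which(outer(seq_len(n), seq_len(n), function(i, j) j - i >= 10L),
                       arr.ind = TRUE)
    far <- mean(vapply(seq_len(nrow(far_pairs)), function(k) {
      cosine(m[far_pairs[k, 1L], ], m[far_pairs[k, 2L], ])
    }, numeric(1L)))
    if (adj > far) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("isolated concepts still receive a graph-embedding vector", {
  onto <- ontology(labels = c(A = "a", B = "b", C = "c"),
                   parents = list(A = character(), B = "A", C = character()))
  m <- build_node2vec_sso(onto, graph_embed_config(dimension = 8L))$matrix
  expect_equal(dim(m), c(3L, 8L))
  expect_true(all(is.finite(m)))
})

test_that("full-rank SVD reduction preserves pairwise row cosines", {
  onto <- generate_ontology(synth_config(n_concepts = 20L, seed = 4L))
  s <- build_decay_sso(onto, 0.6)
  r <- reduce_dimensions(s, "svd", target_dim = qr(s$matrix)$rank)
  cosmat <- function(m) {
    n <- m / sqrt(rowSums(m^2))
    n %*% t(n)
  }
  expect_lt(max(abs(cosmat(s$matrix) - cosmat(r$matrix))), 1e-8)
})

test_that("reduction meta, shape, determinism and error contracts hold", {
  ch3 <- ch3_ontology()
  s <- build_decay_sso(ch3, 1)
  p <- reduce_dimensions(s, "pca", 2L)
  expect_equal(dim(p$matrix), c(3L, 2L))
  expect_equal(p$meta$reduction_fraction, 1 - 2 / 3)
  m1 <- reduce_dimensions(s, "mds", 2L, seed = 1L)
  m2 <- reduce_dimensions(s, "mds", 2L, seed = 1L)
  expect_identical(m1$matrix, m2$matrix)
  expect_error(reduce_dimensions(s, "svd", 4L), "target_dim")
  expect_error(reduce_dimensions(s, "tsne", 2L), "not supported")
})

test_that("concept spaces round-trip through TSV + JSON sidecar", {
  onto <- generate_ontology(synth_config(n_concepts = 12L, seed = 6L))
  s <- build_decay_sso(onto, 0.5)
  path <- tempfile(fileext = ".tsv")
  write_concept_space(s, path)
  back <- read_concept_space(path)
  expect_equal(back$matrix, s$matrix, tolerance = 1e-12)
  expect_equal(back$meta$method, "decay")
  expect_equal(back$meta$decay, 0.5)
})
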