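test_that("score functions satisfy their exact algebraic cases", {
  g <- toy_graph()
  k <- 4

  # TransE: l_t = l_h + l_r gives score exactly 0
  p <- hand_params(g$catalog, dim = k, model = "TransE")
  p$entities[3, ] <- p$entities[1, ] + p$relations[2, ]
  expect_equal(score_triple(p, 0, 1, 2), 0)

  # TransH with w_r orthogonal to both entities reduces to TransE
  ph <- hand_params(g$catalog, dim = k, model = "TransH")
  ph$entities[1, ] <- c(0.3, -0.2, 0, 0)
  ph$entities[3, ] <- c(-0.1, 0.4, 0, 0)
  ph$normals[2, ] <- c(0, 0, 1, 0)
  pe <- ph; pe$model <- "TransE"
  expect_equal(score_triple(ph, 0, 1, 2), score_triple(pe, 0, 1, 2))

  # TransR with identity projection equals TransE, both norms
  for (no in c(1, 2)) {
    pr <- hand_params(g$catalog, dim = k, model = "TransR", norm_order = no)
    pe2 <- hand_params(g$catalog, dim = k, model = "TransE", norm_order = no)
    expect_equal(score_triple(pr, 0, 3, 5), score_triple(pe2, 0, 3, 5))
  }

  # translation consistency: shifting h and t together leaves TransE alone
  p2 <- hand_params(g$catalog, dim = k, model = "TransE")
  s0 <- score_triple(p2, 0, 1, 2)
  p2$entities[1, ] <- p2$entities[1, ] + 0.37
  p2$entities[3, ] <- p2$entities[3, ] + 0.37
  expect_equal(score_triple(p2, 0, 1, 2), s0)

  expect_error(score_triple(p, -1, 0, 2), "out of range")
  expect_error(score_triple(p, 0, 9, 2), "out of range")
})

test_that("hyperplane projection is orthogonal, idempotent, and validated", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(3:16, 1)
    w <- rnorm(k); w <- w / sqrt(sum(w^2))
    e <- rnorm(k)
    pe <- project_hyperplane(e, w)
    expect_lt(abs(sum(w * pe)), 1e-6)
    expect_equal(project_hyperplane(pe, w), pe, tolerance = 1e-9)
  }
  w <- c(1, 0, 0)
  expect_equal(project_hyperplane(c(0, 2, 3), w), c(0, 2, 3))
  expect_equal(project_hyperplane(w, w), c(0, 0, 0))
  expect_error(project_hyperplane(c(1, 1, 1), c(1, 1, 1)), "unit")
})

test_that("negative sampling corrupts one slot, never the relation", {
  g <- toy_graph()
  tr <- list(head = 0, relation = 3, tail = 5)
  set.seed(4)
  n_head <- 0
  for (i in 1:2000) {
    neg <- negative_sample(tr, g$catalog)
    expect_equal(neg$relation, tr$relation)
    changed_head <- neg$head != tr$head
    changed_tail <- neg$tail != tr$tail
    expect_true(xor(changed_head, changed_tail))
    if (changed_head) {
      expect_true(neg$head %in% kgdx:::indicator_ids(g$catalog))
      n_head <- n_head + 1
    } else {
      expect_true(neg$tail %in% kgdx:::value_ids(g$catalog))
    }
  }
  # binomial check on the corruption side at 10k draws
  set.seed(8)
  sides <- replicate(10000, {
    neg <- negative_sample(tr, g$catalog)
    neg$head != tr$head
  })
  expect_equal(mean(sides), 0.5, tolerance = 0.04)

  # degenerate catalog: one indicator, one value entity
  tiny <- build_graph(list(reference_range("only", 1, 2, "U/L",
                                           grid_step = 5,
                                           span_factor = 1e-6)))$catalog
  expect_equal(sum(tiny$entity_kind == "value"), 1L)
  expect_error(negative_sample(list(head = 0, relation = 3, tail = 1), tiny),
               "cannot corrupt")
})

test_that("rank_triple matches exhaustive brute-force ranking", {
  g <- build_graph(list(
    reference_range("a", 1, 2, "U/L", grid_step = 0.5, span_factor = 1),
    reference_range("b", 5, 10, "U/L", grid_step = 2.5, span_factor = 1)
  ))
  expect_lte(length(g$catalog$entity_ids), 50)
  for (model in c("TransE", "TransH", "TransR")) {
    for (no in c(1, 2)) {
      p <- hand_params(g$catalog, dim = 6, model = model, norm_order = no,
                       seed = 31)
      if (model == "TransR") { # non-trivial projections
        set.seed(32)
        p$proj <- p$proj + array(rnorm(length(p$proj), sd = 0.2), dim(p$proj))
      }
      for (i in c(1, 4, nrow(g$triples))) {
        tr <- list(head = g$triples$head[i], relation = g$triples$relation[i],
                   tail = g$triples$tail[i])
        for (side in c("head", "tail")) {
          expect_equal(rank_triple(p, tr, g$catalog, side),
                       brute_force_rank(p, tr, g$catalog, side),
                       info = paste(model, "L", no, side))
        }
      }
    }
  }
})

test_that("rank ties and unique minima follow the optimistic rule", {
  g <- toy_graph()
  p <- hand_params(g$catalog, dim = 4, model = "TransE")
  tr <- list(head = 0, relation = 2, tail = 4)
  # unique minimum: true triple scores exactly zero
  p$entities[tr$tail + 1, ] <- p$entities[tr$head + 1, ] +
    p$relations[tr$relation + 1, ]
  expect_equal(rank_triple(p, tr, g$catalog, "head"), 1L)
  # exact ties everywhere: all entities identical
  p$entities <- matrix(0.1, nrow(p$entities), 4)
  expect_equal(rank_triple(p, tr, g$catalog, "head"), 1L)
  expect_equal(rank_triple(p, tr, g$catalog, "tail"), 1L)
})

test_that("evaluate_ranking computes MR and Hit@10 from ranks", {
  g <- toy_graph()
  p <- hand_params(g$catalog, dim = 4)
  # single triple engineered to rank 1
  tr <- g$triples[3, , drop = FALSE]
  p$entities[tr$tail + 1, ] <- p$entities[tr$head + 1, ] +
    p$relations[tr$relation + 1, ]
  res <- evaluate_ranking(p, tr, g$catalog, side = "head")
  expect_equal(res$mean_rank, 1)
  expect_equal(res$hit_at_10, 100)

  # multi-triple oracle equivalence and the MR/Hit@10 identities
  p2 <- hand_params(g$catalog, dim = 5, seed = 99)
  sub <- g$triples[1:12, ]
  res2 <- evaluate_ranking(p2, sub, g$catalog, side = "tail")
  oracle <- vapply(seq_len(12), function(i) {
    brute_force_rank(p2, as.list(sub[i, ]), g$catalog, "tail")
  }, integer(1))
  expect_equal(res2$per_triple_ranks, oracle)
  expect_equal(res2$mean_rank, mean(oracle))
  expect_equal(res2$hit_at_10, 100 * sum(oracle <= 10) / 12)

  expect_error(evaluate_ranking(p2, g$triples[0, ], g$catalog), "empty")
})

test_that("hit@10 is zero when a triple ranks eleventh or worse", {
  g <- toy_graph()
  p <- hand_params(g$catalog, dim = 4, seed = 12)
  tr <- as.list(g$triples[5, ])
  r <- rank_triple(p, tr, g$catalog, "tail")
  res <- evaluate_ranking(p, g$triples[5, , drop = FALSE], g$catalog, "tail")
  expect_equal(res$hit_at_10, if (r <= 10) 100 else 0)
})

test_that("training separates positive from corrupted scores", {
  g <- toy_graph()
  cfg <- trans_config(epochs = 200, batch_size = 32, seed = 17)
  for (model in c("TransE", "TransH")) {
    p <- train_trans(g$triples, g$catalog, model, dim = 16, config = cfg)
    pos <- vapply(seq_len(nrow(g$triples)), function(i) {
      score_triple(p, g$triples$head[i], g$triples$relation[i],
                   g$triples$tail[i])
    }, numeric(1))
    set.seed(5)
    neg <- vapply(seq_len(nrow(g$triples)), function(i) {
      nt <- negative_sample(as.list(g$triples[i, ]), g$catalog)
      score_triple(p, nt$head, nt$relation, nt$tail)
    }, numeric(1))
    expect_gt(mean(neg) - mean(pos), cfg$margin / 2)
  }

  # TransH keeps its constraints after training
  p <- train_trans(g$triples, g$catalog, "TransH", dim = 16, config = cfg)
  expect_true(all(abs(sqrt(rowSums(p$normals^2)) - 1) < 1e-8))
  expect_true(all(sqrt(rowSums(p$entities^2)) <= 1 + 1e-8))
})

test_that("training is deterministic and zero epochs is the identity", {
  g <- toy_graph()
  cfg0 <- trans_config(epochs = 0, seed = 23)
  p0 <- train_trans(g$triples, g$catalog, "TransE", dim = 8, config = cfg0)
  expect_identical(p0$entities,
                   init_trans_params(g$catalog, "TransE", 8, seed = 23)$entities)

  cfg <- trans_config(epochs = 30, seed = 23)
  p1 <- train_trans(g$triples, g$catalog, "TransH", dim = 8, config = cfg)
  p2 <- train_trans(g$triples, g$catalog, "TransH", dim = 8, config = cfg)
  expect_identical(p1$entities, p2$entities)
  expect_identical(p1$relations, p2$relations)
  expect_identical(p1$normals, p2$normals)

  expect_error(train_trans(g$triples[0, ], g$catalog, "TransE", dim = 4),
               "empty")
})

test_that("embeddings round-trip through the text directory format", {
  g <- toy_graph()
  for (model in c("TransE", "TransH", "TransR")) {
    p <- hand_params(g$catalog, dim = 5, model = model, seed = 41)
    dir <- withr::local_tempdir()
    write_embeddings(p, dir)
    q <- read_embeddings(dir)
    expect_equal(q$model, p$model)
    expect_equal(q$entities, p$entities)
    expect_equal(q$relations, p$relations)
    if (model == "TransH") expect_equal(q$normals, p$normals)
    if (model == "TransR") expect_equal(q$proj, p$proj)
  }
})
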