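## a small but trainable corpus shared by several blocks
small_training_docs <- function(seed = 1) {
  g <- generate_corpus(generator_spec(n_patients = 15, seed = seed))
  preprocess_corpus(g$corpus)
}

test_that("vocabulary honors min_count and vectors have the configured dimension", {
  docs <- token_docs(doc_id = c("a", "b"), patient_id = "p",
                     tokens = list(c("crisi", "scossa", "crisi", "braccio"),
                                   c("crisi", "scossa", "mano")))
  emb <- train_embedding(docs, embedding_params(dimension = 8, epochs = 5,
                                                min_count = 2, seed = 1))
  expect_true(all(c("crisi", "scossa") %in% emb$vocabulary))
  expect_false("mano" %in% emb$vocabulary)   # occurs once < min_count
  expect_false("braccio" %in% emb$vocabulary)
  expect_equal(ncol(emb$vectors), 8)
  expect_true(all(is.finite(emb$vectors)))
})

test_that("defaults give 100-dimensional vectors", {
  docs <- small_training_docs()
  emb <- train_embedding(docs, embedding_params(epochs = 2, seed = 0))
  expect_equal(ncol(emb$vectors), 100)
})

test_that("an empty post-min_count vocabulary is a configuration error", {
  docs <- token_docs(doc_id = "a", patient_id = "p",
                     tokens = list(c("uno", "due", "tre")))
  expect_error(train_embedding(docs, embedding_params(min_count = 2, epochs = 1)),
               "min_count")
})

test_that("training is bit-reproducible under a fixed seed", {
  docs <- small_training_docs()
  p <- embedding_params(dimension = 16, epochs = 5, seed = 42)
  e1 <- train_embedding(docs, p)
  e2 <- train_embedding(docs, p)
  expect_identical(e1$vectors, e2$vectors)
  e3 <- train_embedding(docs, embedding_params(dimension = 16, epochs = 5,
                                               seed = 43))
  expect_false(identical(e1$vectors, e3$vectors))
})

test_that("words with identical context distributions become close", {
  ## plant two words that co-occur with the same contexts, far above what
  ## random pairs share
  with_seed(5, {
    ctx <- sprintf("c%02d", 1:8)
    sent <- c(lapply(1:150, function(i) c("gemello", sample(ctx, 2))),
              lapply(1:150, function(i) c("sosia", sample(ctx, 2))),
              lapply(1:150, function(i) sample(sprintf("w%02d", 1:12), 3)))
    docs <- token_docs(doc_id = sprintf("d%03d", seq_along(sent)),
                       patient_id = "p", tokens = sent)
  })
  emb <- train_embedding(docs, embedding_params(dimension = 24, epochs = 40,
                                                min_count = 2, seed = 2))
  planted <- cosine_similarity(ezloc:::word_vector(emb, "gemello"),
                               ezloc:::word_vector(emb, "sosia"))
  others <- setdiff(emb$vocabulary, c("gemello", "sosia"))
  rand_pairs <- with_seed(9, t(replicate(200, sample(others, 2))))
  rand_sims <- apply(rand_pairs, 1, function(pr) {
    cosine_similarity(ezloc:::word_vector(emb, pr[1]),
                      ezloc:::word_vector(emb, pr[2]))
  })
  expect_gt(planted, quantile(rand_sims, 0.95))
})

test_that("the word2vec text format round-trips", {
  docs <- small_training_docs()
  emb <- train_embedding(docs, embedding_params(dimension = 12, epochs = 3,
                                                seed = 3))
  path <- withr::local_tempfile(fileext = ".txt")
  write_embedding(emb, path)
  back <- read_embedding(path)
  expect_identical(back$vocabulary, emb$vocabulary)
  expect_equal(unname(back$vectors), unname(emb$vectors))
  hdr <- readLines(path, n = 1)
  expect_equal(hdr, sprintf("%d %d", length(emb$vocabulary), 12))
})

test_that("idf follows the smoothed formula", {
  docs <- token_docs(doc_id = sprintf("d%d", 1:4), patient_id = "p",
                     tokens = list(c("raro", "comune"), c("comune"),
                                   c("comune"), c("comune")))
  idf <- compute_idf(docs)
  expect_equal(unname(idf$idf["raro"]), log(2.5) + 1)     # N=4, df=1
  expect_equal(unname(idf$idf["comune"]), 1)              # df = N
  expect_equal(idf$default_idf, log(5) + 1)               # unseen term
  expect_error(compute_idf(docs[0, , drop = FALSE]), "empty")
})

test_that("mean pooling averages in-vocabulary vectors with multiplicity", {
  emb <- fake_embedding(rbind(a = c(1, 0), b = c(0, 1)))
  expect_equal(pool_mean(c("a", "b"), emb), c(0.5, 0.5))
  expect_equal(pool_mean("a", emb), c(1, 0))
  expect_equal(pool_mean(c("a", "a", "b"), emb), c(2 / 3, 1 / 3))
  expect_warning(z <- pool_mean(c("zz"), emb), "no in-vocabulary")
  expect_equal(z, c(0, 0))
})

test_that("tfidf pooling is the weight-normalized average", {
  emb <- fake_embedding(rbind(a = c(1, 0), b = c(0, 1)))
  docs <- token_docs(doc_id = sprintf("d%d", 1:4), patient_id = "p",
                     tokens = list(c("a", "b"), c("a"), c("b"), c("a", "b")))
  idf <- compute_idf(docs)
  ## single distinct term: idf cancels
  expect_equal(pool_tfidf("a", emb, idf), c(1, 0))
  ## uniform idf (both df = 3 of 4) and distinct tokens: equals pool_mean
  expect_equal(pool_tfidf(c("a", "b"), emb, idf), pool_mean(c("a", "b"), emb),
               tolerance = 1e-12)
  ## raw tf weighting: "a" three times vs "b" once, uniform idf -> (0.75, 0.25)
  expect_equal(pool_tfidf(c("a", "a", "a", "b"), emb, idf), c(0.75, 0.25))
  expect_warning(z <- pool_tfidf("zz", emb, idf), "no in-vocabulary")
  expect_equal(z, c(0, 0))
})

test_that("pooled vectors stay in the coordinate-wise hull of their words", {
  with_seed(31, {
    vecs <- matrix(rnorm(40), 10, 4,
                   dimnames = list(sprintf("w%d", 1:10), NULL))
    emb <- fake_embedding(vecs)
    docs <- lapply(1:20, function(i) sample(rownames(vecs), sample(2:6, 1),
                                            replace = TRUE))
    fitd <- token_docs(doc_id = sprintf("d%d", 1:20), patient_id = "p",
                       tokens = docs)
    idf <- compute_idf(fitd)
    for (d in docs) {
      lo <- apply(vecs[unique(d), , drop = FALSE], 2, min)
      hi <- apply(vecs[unique(d), , drop = FALSE], 2, max)
      for (v in list(pool_mean(d, emb), pool_tfidf(d, emb, idf))) {
        expect_true(all(v >= lo - 1e-12 & v <= hi + 1e-12))
      }
    }
  })
})

test_that("the idf table is invariant to held-out documents", {
  docs <- small_training_docs()
  idf <- compute_idf(docs[1:20, , drop = FALSE])
  h <- object_digest(idf)
  emb <- fake_embedding(rbind(crisi = c(1, 0), scossa = c(0, 1)))
  invisible(suppressWarnings(
    pool_corpus(docs[21:30, , drop = FALSE], emb, "tfidf", idf)))
  expect_identical(object_digest(idf), h)
})
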