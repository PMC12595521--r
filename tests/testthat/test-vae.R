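test_that("closed-form KL is exact in hand-computable cases and matches a
           Monte-Carlo estimate", {
  # posterior equal to the prior
  expect_equal(klDivergence(rep(0, 4), rep(0, 4)), 0)
  # 0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2) evaluated by hand
  expect_equal(klDivergence(c(1, 0, 0, 0), rep(0, 4)), 0.5)
  expect_equal(klDivergence(c(1, 1, 0, 0), c(0, log(4), 0, 0)),
               0.5 * (1 + (1 + 4 - 1 - log(4))))

  # sampling oracle: KL = E_q[log q(z) - log p(z)] by simple Monte Carlo
  set.seed(19)
  for (i in 1:5) {
    d <- sample(2:5, 1)
    mu <- rnorm(d); lv <- rnorm(d, 0, 0.5)
    n <- 1e5
    z <- matrix(rnorm(n * d), n, d) * rep(exp(lv / 2), each = n) +
      rep(mu, each = n)
    logq <- rowSums(dnorm(z, rep(mu, each = n), rep(exp(lv / 2), each = n),
                          log = TRUE))
    logp <- rowSums(dnorm(z, log = TRUE))
    mc <- logq - logp
    se <- sd(mc) / sqrt(n)
    expect_lt(abs(klDivergence(mu, lv) - mean(mc)), 3 * se)
  }
})

test_that("training is seed-deterministic and the KL term never goes negative", {
  msa <- generateMsa(25, 20, truth = NULL, seed = 2)
  cfg <- vaeConfig(epochs = 40, seed = 7, encoder_widths = c(32, 16),
                   decoder_widths = c(16, 32))
  m1 <- trainVae(msa, config = cfg)
  m2 <- trainVae(msa, config = cfg)
  expect_identical(m1@params, m2@params)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_true(all(trainingHistory(m1)$kl >= 0))

  m3 <- trainVae(msa, config = vaeConfig(epochs = 40, seed = 8,
                                         encoder_widths = c(32, 16),
                                         decoder_widths = c(16, 32)))
  expect_false(identical(m1@params, m3@params))
})

test_that("training improves the ELBO and reconstructs the wildtype", {
  m <- fixture_model_unsup()
  h <- trainingHistory(m)
  expect_gte(h$elbo[nrow(h)], h$elbo[1])

  msa <- fixture_msa_small()
  wt <- wildtypeSequence(msa)
  emb <- latentEmbedding(m, stats::setNames(wt, "wt"))
  z <- as.matrix(emb[, paste0("z", 1:4)])
  recon <- decodeArgmax(decoderProbs(m, z))
  expect_identical(unname(recon), wt)
})

test_that("decoder outputs are valid per-position distributions for random
           latent draws", {
  m <- fixture_model_unsup()
  set.seed(6)
  z <- matrix(rnorm(50 * 4, 0, 2), 50, 4)
  p <- decoderProbs(m, z)
  sums <- apply(p, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(p >= 0))
})

test_that("the ELBO accessor decomposes total = reconstruction - kl_weight*kl", {
  m <- fixture_model_unsup()
  e <- vaeElbo(m, fixture_msa_small())
  expect_equal(e$total, e$reconstruction - m@config$kl_weight * e$kl)
  expect_gte(e$kl, 0)
})

test_that("full-batch training is insensitive to row order up to the
           reparameterization pairing", {
  msa <- generateMsa(25, 20, truth = NULL, seed = 2)
  cfg <- vaeConfig(epochs = 80, seed = 7, encoder_widths = c(32, 16),
                   decoder_widths = c(16, 32))
  m1 <- trainVae(msa, config = cfg)
  perm <- rev(seq_len(25))
  m2 <- trainVae(sequenceMatrix(msa)[perm, ], config = cfg)
  e1 <- tail(trainingHistory(m1)$elbo, 1)
  e2 <- tail(trainingHistory(m2)$elbo, 1)
  expect_equal(e1, e2, tolerance = 0.1)
})

test_that("lambda = 0 semi-supervision reduces exactly to the unsupervised run", {
  truth15 <- groundTruth(key_positions = 15L)
  msa <- generateMsa(25, 20, truth = truth15, seed = 2)
  tm <- trueTmax(alignedSequences(msa), truth15)
  lab <- data.frame(id = alignmentIds(msa), tmax = tm, active = 1)
  cfg0 <- vaeConfig(epochs = 40, seed = 7, encoder_widths = c(32, 16),
                    decoder_widths = c(16, 32), property_weight = 0)
  unsup <- trainVae(msa, config = cfg0)
  semi <- trainVae(msa, labels = lab, config = cfg0)
  for (part in c("enc", "mu", "lv", "dec", "out"))
    expect_identical(semi@params[[part]], unsup@params[[part]])
  expect_true(all(c("p1", "p2") %in% names(semi@params)))
})

test_that("all-missing labels are rejected as unsupervisable", {
  msa <- generateMsa(10, 15, seed = 4)
  lab <- data.frame(id = alignmentIds(msa), tmax = NA_real_, active = NA_real_)
  expect_error(trainVae(msa, labels = lab, config = vaeConfig(epochs = 5)),
               "no supervision")
})

test_that("embeddings are deterministic, complete, and purely functional", {
  m <- fixture_model_unsup()
  msa <- fixture_msa_small()
  e1 <- latentEmbedding(m, msa)
  e2 <- latentEmbedding(m, msa)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), length(alignmentIds(msa)))

  # two identical sequences embed identically
  wt <- wildtypeSequence(msa)
  twin <- latentEmbedding(m, c(a = wt, b = wt))
  expect_equal(unname(unlist(twin[1, -1])), unname(unlist(twin[2, -1])))

  untrained <- methods::new("RcaVae", params = list(), config = list(),
                            history = data.frame(), alphabet = rcaAlphabet(),
                            width = 1L, labelStats = c(mean = 0, sd = 1),
                            supervised = FALSE, trained = FALSE)
  expect_error(latentEmbedding(untrained, msa), "trained")
})

test_that("semi-supervision organizes the latent space by thermal tolerance
           (higher two-class silhouette than unsupervised)", {
  msa <- fixture_msa_small()
  truth <- fixture_truth()
  tm <- trueTmax(alignedSequences(msa), truth)
  lab <- data.frame(id = alignmentIds(msa), tmax = tm, active = 1)
  unsup <- fixture_model_unsup()
  semi <- trainVae(msa, labels = lab,
                   config = vaeConfig(epochs = 200, learning_rate = 2e-3,
                                      seed = 5))
  sil <- function(model) {
    z <- as.matrix(latentEmbedding(model, msa)[, paste0("z", 1:4)])
    cl <- as.integer(factor(tm))
    mean(cluster::silhouette(cl, dist(z))[, "sil_width"])
  }
  expect_gt(sil(semi), sil(unsup))
})

test_that("latent coordinate export writes one labeled row per sequence", {
  m <- fixture_model_unsup()
  msa <- fixture_msa_small()
  path <- tempfile(fileext = ".csv")
  tm <- trueTmax(alignedSequences(msa), fixture_truth())
  exportLatentCoordinates(m, msa, labels = setNames(tm, alignmentIds(msa)),
                          path = path)
  got <- read.csv(path)
  expect_equal(nrow(got), length(alignmentIds(msa)))
  expect_identical(names(got), c("id", paste0("z", 1:4), "label"))
  expect_equal(got$label, unname(tm))
})
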