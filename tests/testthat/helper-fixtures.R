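# Shared fixtures. Heavier objects (trained models) are built once per test
# run and memoized here so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture_truth <- function() groundTruth(key_positions = 25L, seed = 1L)

# noiseless truth for exact screening checks
fixture_truth_clean <- function() {
  groundTruth(key_positions = 25L, trace_noise_sd = 0, seed = 1L)
}

fixture_msa_small <- function() {
  memo("msa_small", generateMsa(60, 40, truth = fixture_truth(), seed = 42))
}

# the planted-signal fixture: 200 sequences, 1 key position, +8 C effect
fixture_msa_planted <- function() {
  memo("msa_planted", generateMsa(200, 120, truth = fixture_truth(), seed = 11))
}

fixture_model_unsup <- function() {
  memo("model_unsup",
       trainVae(fixture_msa_small(),
                config = vaeConfig(epochs = 200, learning_rate = 2e-3,
                                   seed = 5)))
}

# generative fixture: strong KL so the wildtype neighborhood decodes densely
fixture_model_sampler <- function() {
  memo("model_sampler",
       trainVae(fixture_msa_small(),
                config = vaeConfig(epochs = 200, learning_rate = 2e-3,
                                   kl_weight = 8, seed = 5)))
}

fixture_model_semisup <- function() {
  memo("model_semisup", {
    msa <- fixture_msa_small()
    tm <- trueTmax(alignedSequences(msa), fixture_truth())
    trainVae(msa,
             labels = data.frame(id = alignmentIds(msa), tmax = tm, active = 1),
             config = vaeConfig(epochs = 200, learning_rate = 2e-3,
                                kl_weight = 4, property_weight = 50, seed = 5))
  })
}

memo <- function(key, value) {
  if (!exists(key, envir = .fixture_env))
    assign(key, value, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# independent brute-force Hamming counter (oracle; kept separate from the
# package implementation on purpose)
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(ca)) if (ca[i] != cb[i]) n <- n + 1L
  n
}

random_msa <- function(n, L, alphabet = rcaAlphabet()) {
  m <- matrix(sample(alphabet, n * L, replace = TRUE), n, L)
  rownames(m) <- paste0("s", seq_len(n))
  m
}
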