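## Variational autoencoder over one-hot encoded alignments.
##
## Architecture: multilayer perceptron encoder and decoder on the flattened
## one-hot input (ReLU trunks; linear mu / log-variance heads; per-position
## softmax decoder output over the 21-symbol alphabet). The objective is the
## evidence lower bound — expected categorical log-likelihood of the input
## under the decoded distributions minus the closed-form KL divergence
## between the diagonal-Gaussian posterior and the standard-normal prior —
## optionally plus a semi-supervised property loss (squared error on
## standardized tmax, cross-entropy on the activity flag) computed on
## labeled rows only, from a small tanh head on the posterior mean.
## Optimization is full-batch Adam by default; the KL weight is linearly
## warmed up over the first 10% of epochs to avoid posterior collapse.

#' VAE training configuration
#'
#' @param latent_dim Latent dimensionality (the campaign used 4).
#' @param encoder_widths Hidden widths of the encoder trunk.
#' @param decoder_widths Hidden widths of the decoder trunk (default: the
#'   encoder reversed).
#' @param kl_weight Weight on the KL term after warm-up (>= 0).
#' @param property_weight Weight lambda on the semi-supervised property loss.
#' @param learning_rate Adam learning rate.
#' @param weight_decay Decoupled L2 decay on weight matrices (regularizes
#'   the over-parameterized trunks against label memorization).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size; \code{Inf} (default) trains full-batch.
#' @param property_hidden Hidden width of the property head.
#' @param seed Single global seed controlling initialization, shuffling and
#'   reparameterization draws.
#' @return A validated configuration list.
#' @export
vaeConfig <- function(latent_dim = 4L, encoder_widths = c(256L, 64L),
                      decoder_widths = rev(encoder_widths), kl_weight = 1,
                      property_weight = 1, learning_rate = 1e-3,
                      weight_decay = 1e-4, epochs = 300L, batch_size = Inf,
                      property_hidden = 16L, seed = 1L) {
  stopifnot(latent_dim >= 1L, kl_weight >= 0, property_weight >= 0,
            learning_rate > 0, weight_decay >= 0, epochs >= 1L)
  structure(list(latent_dim = as.integer(latent_dim),
                 encoder_widths = as.integer(encoder_widths),
                 decoder_widths = as.integer(decoder_widths),
                 kl_weight = kl_weight, property_weight = property_weight,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = batch_size,
                 property_hidden = as.integer(property_hidden),
                 seed = as.integer(seed)),
            class = "vae_config")
}

#' Closed-form KL divergence to the standard-normal prior
#'
#' Per-row divergence of a diagonal Gaussian \code{N(mu, diag(exp(logvar)))}
#' from \code{N(0, I)}: \code{0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)}.
#' Always nonnegative; zero iff the posterior equals the prior.
#'
#' @param mu Matrix of posterior means (rows = points) or a vector.
#' @param logvar Matrix/vector of posterior log-variances, same shape.
#' @return Numeric vector of per-row divergences (nats).
#' @export
#' @examples
#' klDivergence(c(1, 0, 0, 0), c(0, 0, 0, 0))  # 0.5
klDivergence <- function(mu, logvar) {
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1L)
  if (is.null(dim(logvar))) logvar <- matrix(logvar, nrow = 1L)
  stopifnot(all(dim(mu) == dim(logvar)))
  0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
}

## ---------------------------------------------------------------------------
## internals: layers, forward/backward, Adam
## ---------------------------------------------------------------------------

init_layer <- function(fan_in, fan_out, scale = sqrt(2 / fan_in)) {
  list(W = matrix(stats::rnorm(fan_in * fan_out, 0, scale), fan_in, fan_out),
       b = numeric(fan_out))
}

init_trunk <- function(dims) {
  lapply(seq_len(length(dims) - 1L),
         function(i) init_layer(dims[i], dims[i + 1L]))
}

## ReLU trunk forward; returns activations list (A[[1]] = input)
trunk_forward <- function(X, layers) {
  A <- vector("list", length(layers) + 1L)
  A[[1L]] <- X
  for (i in seq_along(layers)) {
    Z <- sweep(A[[i]] %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    A[[i + 1L]] <- Z * (Z > 0)
  }
  A
}

## backward through a ReLU trunk; returns list(grads, dX)
trunk_backward <- function(dA, A, layers) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    dZ <- dA * (A[[i + 1L]] > 0)
    grads[[i]] <- list(W = crossprod(A[[i]], dZ), b = colSums(dZ))
    dA <- dZ %*% t(layers[[i]]$W)
  }
  list(grads = grads, dX = dA)
}

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = "ANY")
}

## flatten/apply Adam over the nested params structure
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], s[[k]])
        out_p[[k]] <- r$p; out_s[[k]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    m <- beta1 * s$m + (1 - beta1) * g
    v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    # decoupled weight decay on weight matrices only, never biases
    decay <- if (is.matrix(p)) lr * weight_decay * p else 0
    list(p = p - lr * mhat / (sqrt(vhat) + eps) - decay,
         s = list(m = m, v = v))
  }
  walk(params, grads, state)
}

LV_CLAMP <- 8  # log-variance clamp bound for numerical stability

encoder_forward <- function(X, params) {
  A <- trunk_forward(X, params$enc)
  H <- A[[length(A)]]
  mu <- sweep(H %*% params$mu$W, 2L, params$mu$b, "+")
  lv_raw <- sweep(H %*% params$lv$W, 2L, params$lv$b, "+")
  lv <- pmin(pmax(lv_raw, -LV_CLAMP), LV_CLAMP)
  list(A = A, H = H, mu = mu, lv = lv, lv_raw = lv_raw)
}

decoder_forward <- function(z, params) {
  A <- trunk_forward(z, params$dec)
  G <- A[[length(A)]]
  logits <- sweep(G %*% params$out$W, 2L, params$out$b, "+")
  list(A = A, G = G, logits = logits)
}

## per-position log-softmax over the flattened n x (L*K) logits.
## Column-major layout means the same data reads as (n*L) x K for free.
logits_to_logprob <- function(logits, n, L, K) {
  M <- matrix(as.vector(logits), n * L, K)
  mx <- apply(M, 1L, max)
  lse <- mx + log(rowSums(exp(M - mx)))
  M - lse  # (n*L) x K log-probabilities
}

property_forward <- function(mu, params) {
  T1 <- tanh(sweep(mu %*% params$p1$W, 2L, params$p1$b, "+"))
  out <- sweep(T1 %*% params$p2$W, 2L, params$p2$b, "+")
  list(T1 = T1, out = out)
}

## ---------------------------------------------------------------------------
## training
## ---------------------------------------------------------------------------

#' Train the variational autoencoder
#'
#' Trains unsupervised when \code{labels} is \code{NULL}; otherwise trains
#' the semi-supervised model, adding a property head on the posterior mean
#' whose loss (squared error on standardized tmax; binary cross-entropy on
#' the activity flag) is computed over labeled rows only — missing labels are
#' masked, never imputed. With \code{property_weight = 0} the encoder and
#' decoder parameters match the unsupervised run at the same seed exactly
#' (the head is initialized from an independent random stream). Training is
#' deterministic given the configuration seed.
#'
#' @param msa An \code{\link{alignedSet}} or a one-hot array from
#'   \code{\link{encodeOneHot}}.
#' @param labels Optional data.frame with columns \code{id}, \code{tmax}
#'   (degrees C, \code{NA} where unmeasured) and optionally \code{active}
#'   (0/1, \code{NA} where unmeasured). At least one label must be present.
#' @param config A \code{\link{vaeConfig}}.
#' @return A trained \code{\linkS4class{RcaVae}}.
#' @export
trainVae <- function(msa, labels = NULL, config = vaeConfig()) {
  x <- if (is.array(msa) && length(dim(msa)) == 3L) msa else encodeOneHot(msa)
  n <- dim(x)[1L]; L <- dim(x)[2L]; K <- dim(x)[3L]
  if (n < 1L) stop("empty alignment")
  D <- L * K
  X <- matrix(x, n, D)
  ids <- dimnames(x)[[1L]]
  supervised <- !is.null(labels)

  y_t <- rep(NA_real_, n); y_a <- rep(NA_real_, n)
  label_stats <- c(mean = 0, sd = 1)
  if (supervised) {
    idx <- match(labels$id, ids)
    if (anyNA(idx)) stop("label ids not found in the alignment: ",
                         paste(labels$id[is.na(idx)][1:3], collapse = ", "))
    if ("tmax" %in% names(labels)) y_t[idx] <- labels$tmax
    if ("active" %in% names(labels)) y_a[idx] <- labels$active
    if (all(is.na(y_t)) && all(is.na(y_a)))
      stop("no supervision: every label is missing")
    if (any(!is.na(y_t))) {
      mt <- mean(y_t, na.rm = TRUE)
      st <- stats::sd(y_t, na.rm = TRUE)
      if (!is.finite(st) || st == 0) st <- 1
      label_stats <- c(mean = mt, sd = st)
      y_t <- (y_t - mt) / st
    }
  }
  mask_t <- !is.na(y_t); mask_a <- !is.na(y_a)
  n_t <- sum(mask_t); n_a <- sum(mask_a)

  cfg <- config
  d <- cfg$latent_dim
  lambda <- cfg$property_weight
  warm <- max(1L, ceiling(0.1 * cfg$epochs))

  history <- data.frame(epoch = integer(0), elbo = numeric(0),
                        reconstruction = numeric(0), kl = numeric(0),
                        property = numeric(0), beta = numeric(0))

  params <- NULL
  withr::with_seed(cfg$seed, {
    params <- list(
      enc = init_trunk(c(D, cfg$encoder_widths)),
      mu = init_layer(utils::tail(cfg$encoder_widths, 1L), d,
                      scale = sqrt(1 / utils::tail(cfg$encoder_widths, 1L))),
      lv = init_layer(utils::tail(cfg$encoder_widths, 1L), d,
                      scale = sqrt(1 / utils::tail(cfg$encoder_widths, 1L))),
      dec = init_trunk(c(d, cfg$decoder_widths)),
      out = init_layer(utils::tail(cfg$decoder_widths, 1L), D,
                       scale = sqrt(1 / utils::tail(cfg$decoder_widths, 1L))))
    if (supervised) {
      # independent stream so the head's initialization never perturbs the
      # encoder/decoder trajectory (lambda = 0 reduces to unsupervised)
      params[c("p1", "p2")] <- withr::with_seed(cfg$seed + 77777L, list(
        p1 = init_layer(d, cfg$property_hidden, scale = sqrt(1 / d)),
        p2 = init_layer(cfg$property_hidden, 2L,
                        scale = sqrt(1 / cfg$property_hidden))))
    }
    state <- adam_init(params)
    tstep <- 0L
    bs <- if (is.finite(cfg$batch_size)) as.integer(cfg$batch_size) else n

    for (epoch in seq_len(cfg$epochs)) {
      beta <- cfg$kl_weight * min(1, epoch / warm)
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      ep <- c(recon = 0, kl = 0, prop = 0); nbatch <- 0L
      for (start in seq(1L, n, by = bs)) {
        rows <- ord[start:min(start + bs - 1L, n)]
        nb <- length(rows)
        Xb <- X[rows, , drop = FALSE]
        ef <- encoder_forward(Xb, params)
        eps <- matrix(stats::rnorm(nb * d), nb, d)
        sig <- exp(ef$lv / 2)
        z <- ef$mu + sig * eps
        df <- decoder_forward(z, params)
        logP <- logits_to_logprob(df$logits, nb, L, K)
        Xm <- matrix(as.vector(Xb), nb * L, K)
        recon <- sum(Xm * logP) / nb           # mean per-sequence log-lik
        klv <- klDivergence(ef$mu, ef$lv)
        kl_mean <- mean(klv)

        prop_loss <- 0
        dz_prop <- matrix(0, nb, d)
        pf <- NULL
        if (supervised) {
          # the head is trained on the sampled latent z (posterior noise acts
          # as a regularizer against label memorization) and read out at the
          # posterior mean during inference
          pf <- property_forward(z, params)
          mt <- mask_t[rows]; ma <- mask_a[rows]
          dout <- matrix(0, nb, 2L)
          if (any(mt)) {
            rt <- pf$out[mt, 1L] - y_t[rows][mt]
            prop_loss <- prop_loss + sum(rt^2) / sum(mt)
            dout[mt, 1L] <- 2 * rt / sum(mt)
          }
          if (any(ma)) {
            p <- 1 / (1 + exp(-pf$out[ma, 2L]))
            a <- y_a[rows][ma]
            prop_loss <- prop_loss -
              sum(a * log(pmax(p, 1e-12)) +
                  (1 - a) * log(pmax(1 - p, 1e-12))) / sum(ma)
            dout[ma, 2L] <- (p - a) / sum(ma)
          }
          dout <- dout * lambda
          dT1 <- dout %*% t(params$p2$W)
          dZp <- dT1 * (1 - pf$T1^2)
          g_p2 <- list(W = crossprod(pf$T1, dout), b = colSums(dout))
          g_p1 <- list(W = crossprod(z, dZp), b = colSums(dZp))
          dz_prop <- dZp %*% t(params$p1$W)
        }

        loss <- -recon + beta * kl_mean + lambda * prop_loss
        if (!is.finite(loss))
          stop(sprintf("diverged: non-finite loss at epoch %d", epoch))

        ## --- backward ---
        dlogits <- matrix(as.vector(exp(logP) - Xm), nb, L * K) / nb
        g_out <- list(W = crossprod(df$G, dlogits), b = colSums(dlogits))
        bw_dec <- trunk_backward(dlogits %*% t(params$out$W), df$A, params$dec)
        dz <- bw_dec$dX + dz_prop
        dmu <- dz + beta * ef$mu / nb
        dlv <- dz * eps * 0.5 * sig + beta * 0.5 * (exp(ef$lv) - 1) / nb
        dlv[ef$lv_raw != ef$lv] <- 0   # clamp region
        g_mu <- list(W = crossprod(ef$H, dmu), b = colSums(dmu))
        g_lv <- list(W = crossprod(ef$H, dlv), b = colSums(dlv))
        dH <- dmu %*% t(params$mu$W) + dlv %*% t(params$lv$W)
        bw_enc <- trunk_backward(dH, ef$A, params$enc)

        grads <- list(enc = bw_enc$grads, mu = g_mu, lv = g_lv,
                      dec = bw_dec$grads, out = g_out)
        if (supervised) grads[c("p1", "p2")] <- list(p1 = g_p1, p2 = g_p2)

        tstep <- tstep + 1L
        upd <- adam_step(params, grads, state, cfg$learning_rate, tstep,
                         weight_decay = cfg$weight_decay)
        params <- upd$p; state <- upd$s
        ep <- ep + c(recon, kl_mean, prop_loss); nbatch <- nbatch + 1L
      }
      ep <- ep / nbatch
      history <- rbind(history, data.frame(
        epoch = epoch, elbo = ep[["recon"]] - cfg$kl_weight * ep[["kl"]],
        reconstruction = ep[["recon"]], kl = ep[["kl"]],
        property = ep[["prop"]], beta = beta))
    }
  })

  methods::new("RcaVae", params = params, config = unclass(cfg),
               history = history, alphabet = rcaAlphabet(),
               width = L, labelStats = label_stats,
               supervised = supervised, trained = TRUE)
}

## ---------------------------------------------------------------------------
## inference
## ---------------------------------------------------------------------------

check_trained <- function(model) {
  if (!methods::is(model, "RcaVae") || !model@trained)
    stop("model must be a trained RcaVae")
}

model_input <- function(model, msa) {
  x <- if (is.array(msa) && length(dim(msa)) == 3L) msa else encodeOneHot(msa)
  if (dim(x)[2L] != model@width)
    stop(sprintf("alignment width %d does not match the model (%d)",
                 dim(x)[2L], model@width))
  x
}

#' Evidence lower bound of a batch under a trained model
#'
#' Evaluated deterministically at the posterior mean (z = mu):
#' \code{reconstruction} is the mean per-sequence categorical log-likelihood
#' of the input under the decoded distributions, \code{kl} the mean
#' closed-form divergence from the prior, and
#' \code{total = reconstruction - kl_weight * kl}.
#'
#' @param model A trained \code{RcaVae}.
#' @param msa Alignment or one-hot array.
#' @return List with \code{total}, \code{reconstruction}, \code{kl}.
#' @export
vaeElbo <- function(model, msa) {
  check_trained(model)
  x <- model_input(model, msa)
  n <- dim(x)[1L]; L <- dim(x)[2L]; K <- dim(x)[3L]
  X <- matrix(x, n, L * K)
  ef <- encoder_forward(X, model@params)
  df <- decoder_forward(ef$mu, model@params)
  logP <- logits_to_logprob(df$logits, n, L, K)
  recon <- sum(matrix(as.vector(X), n * L, K) * logP) / n
  kl <- mean(klDivergence(ef$mu, ef$lv))
  list(total = recon - model@config$kl_weight * kl,
       reconstruction = recon, kl = kl)
}

#' Posterior latent embedding of sequences
#'
#' Returns the posterior mean and log-variance of every sequence under the
#' trained encoder — the coordinates plotted in latent-space maps where each
#' point is a sequence and color indicates its measured thermal tolerance.
#'
#' @param model A trained \code{RcaVae}.
#' @param msa Alignment or one-hot array.
#' @return data.frame with \code{id}, \code{z1..zd}, \code{logvar1..logvard}.
#' @export
latentEmbedding <- function(model, msa) {
  check_trained(model)
  x <- model_input(model, msa)
  n <- dim(x)[1L]
  ef <- encoder_forward(matrix(x, n, prod(dim(x)[2:3])), model@params)
  d <- ncol(ef$mu)
  out <- data.frame(id = dimnames(x)[[1L]] %||% paste0("seq", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(d)) out[[paste0("z", j)]] <- ef$mu[, j]
  for (j in seq_len(d)) out[[paste0("logvar", j)]] <- ef$lv[, j]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict measured properties from the latent representation
#'
#' Applies the semi-supervised property head to the posterior means,
#' returning the predicted maximum tolerated heat-shock temperature
#' (de-standardized to degrees C) and the predicted probability of
#' room-temperature activity.
#'
#' @param model A trained semi-supervised \code{RcaVae}.
#' @param msa Alignment or one-hot array.
#' @return data.frame with \code{id}, \code{tmax_pred}, \code{active_prob}.
#' @export
predictProperty <- function(model, msa) {
  check_trained(model)
  if (!model@supervised)
    stop("model has no property head; train with labels")
  x <- model_input(model, msa)
  n <- dim(x)[1L]
  ef <- encoder_forward(matrix(x, n, prod(dim(x)[2:3])), model@params)
  pf <- property_forward(ef$mu, model@params)
  data.frame(id = dimnames(x)[[1L]] %||% paste0("seq", seq_len(n)),
             tmax_pred = pf$out[, 1L] * model@labelStats[["sd"]] +
               model@labelStats[["mean"]],
             active_prob = 1 / (1 + exp(-pf$out[, 2L])),
             stringsAsFactors = FALSE)
}

#' Decoder output distributions for latent points
#'
#' Decodes latent vectors into per-position probability distributions over
#' the 21-symbol alphabet (each position sums to 1).
#'
#' @param model A trained \code{RcaVae}.
#' @param z Matrix of latent vectors (rows = points).
#' @return \code{n x width x 21} probability array.
#' @export
decoderProbs <- function(model, z) {
  check_trained(model)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  df <- decoder_forward(z, model@params)
  n <- nrow(z); L <- model@width; K <- length(model@alphabet)
  logP <- logits_to_logprob(df$logits, n, L, K)
  array(exp(logP), dim = c(n, L, K),
        dimnames = list(rownames(z), NULL, model@alphabet))
}

#' Export a latent coordinates table
#'
#' Writes the embedding as CSV (\code{id, z1..zd, label}) for latent-space
#' plots colored by measured tolerance.
#'
#' @param model A trained \code{RcaVae}.
#' @param msa Alignment or one-hot array.
#' @param labels Optional named vector of labels (e.g. tmax) indexed by id.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
exportLatentCoordinates <- function(model, msa, labels = NULL, path) {
  emb <- latentEmbedding(model, msa)
  emb <- emb[, !grepl("^logvar", names(emb))]
  emb$label <- if (is.null(labels)) NA else unname(labels[emb$id])
  utils::write.csv(emb, path, row.names = FALSE)
  invisible(path)
}
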