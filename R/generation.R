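## Latent-space variant generation: Gaussian sampling around the wildtype
## posterior, argmax decoding, and rejection of anything violating the
## Hamming budget — the campaign's "within 20 substitutions of wildtype"
## design rule.

#' Constraints on a design round
#'
#' @param max_hamming Maximum substitutions to the wildtype (default 20, the
#'   campaign's design budget).
#' @param n_candidates Number of accepted variants requested.
#' @param sigma_scale Multiplier on the wildtype's posterior standard
#'   deviation for the Gaussian sampler.
#' @param exclusion_ids Character vector of previously tested sequences
#'   (gapped sequence strings, or ids resolvable via \code{exclusion_seqs});
#'   proposed variants matching any of them are discarded.
#' @param seed Integer seed.
#' @return A validated constraints list.
#' @export
designConstraints <- function(max_hamming = 20L, n_candidates = 100L,
                              sigma_scale = 1.0, exclusion_ids = character(0),
                              seed = 1L) {
  stopifnot(max_hamming >= 0L, n_candidates >= 1L, sigma_scale >= 0)
  structure(list(max_hamming = as.integer(max_hamming),
                 n_candidates = as.integer(n_candidates),
                 sigma_scale = sigma_scale,
                 exclusion_ids = as.character(exclusion_ids),
                 seed = as.integer(seed)),
            class = "design_constraints")
}

#' Gaussian sampling in latent space
#'
#' Draws from a diagonal Gaussian centered at a posterior mean with standard
#' deviation \code{sigma_scale * exp(logvar / 2)}. As \code{sigma_scale}
#' approaches 0 all draws collapse onto the mean.
#'
#' @param mu Center (posterior mean vector).
#' @param logvar Posterior log-variance vector, same length.
#' @param n Number of draws.
#' @param sigma_scale Scale on the posterior standard deviation.
#' @param seed Integer seed.
#' @return \code{n x length(mu)} matrix of latent vectors.
#' @export
sampleLatent <- function(mu, logvar, n, sigma_scale = 1.0, seed = 1L) {
  stopifnot(length(mu) == length(logvar), n >= 1L)
  d <- length(mu)
  sd <- sigma_scale * exp(logvar / 2)
  withr::with_seed(as.integer(seed), {
    eps <- matrix(stats::rnorm(n * d), n, d)
    sweep(eps, 2L, sd, "*") + matrix(mu, n, d, byrow = TRUE)
  })
}

#' Propose Hamming-constrained synthetic variants
#'
#' Samples latent points around the wildtype embedding
#' (\code{\link{sampleLatent}}), decodes each by per-position argmax, and
#' discards any decoded sequence farther than \code{max_hamming}
#' substitutions from the wildtype, any duplicate, the wildtype itself, and
#' anything in the exclusion set. Sampling continues in batches until
#' \code{n_candidates} variants are accepted or an attempt cap of
#' \code{100 * n_candidates} draws is exhausted, in which case a
#' \code{"sampler starved"} error carries acceptance-rate diagnostics.
#'
#' @param model A trained \code{\linkS4class{RcaVae}}.
#' @param wildtype Gapped wildtype sequence at the model width.
#' @param constraints A \code{\link{designConstraints}}.
#' @param id_prefix Prefix for generated variant identifiers.
#' @return data.frame with \code{id}, \code{sequence},
#'   \code{hamming_to_wt}, latent coordinates \code{z1..zd}, and a
#'   \code{source} column set to \code{"synthetic"}.
#' @export
proposeVariants <- function(model, wildtype, constraints = designConstraints(),
                            id_prefix = "var") {
  check_trained(model)
  emb <- latentEmbedding(model, stats::setNames(wildtype, "wt"))
  d <- model@config$latent_dim
  mu <- as.numeric(emb[1L, paste0("z", seq_len(d))])
  lv <- as.numeric(emb[1L, paste0("logvar", seq_len(d))])
  wt_chars <- strsplit(wildtype, "", fixed = TRUE)[[1L]]
  excl <- unique(c(wildtype, constraints$exclusion_ids))

  cap <- 100L * constraints$n_candidates
  batch <- min(cap, max(1000L, constraints$n_candidates))
  attempted <- 0L
  accepted_seq <- character(0)
  accepted_z <- NULL
  accepted_h <- integer(0)
  draw <- 0L
  while (length(accepted_seq) < constraints$n_candidates && attempted < cap) {
    nb <- min(batch, cap - attempted)
    draw <- draw + 1L
    z <- sampleLatent(mu, lv, nb, constraints$sigma_scale,
                      seed = constraints$seed + draw)
    probs <- decoderProbs(model, z)
    m <- matrix(model@alphabet[max.col(
      matrix(as.vector(probs), nb * model@width, length(model@alphabet)),
      ties.method = "first")], nrow = nb)
    h <- hamming_matrix_to_ref(m, wt_chars)
    seqs <- apply(m, 1L, paste, collapse = "")
    keep <- h <= constraints$max_hamming & !(seqs %in% excl) &
      !(seqs %in% accepted_seq) & !duplicated(seqs)
    attempted <- attempted + nb
    if (any(keep)) {
      accepted_seq <- c(accepted_seq, seqs[keep])
      accepted_h <- c(accepted_h, h[keep])
      accepted_z <- rbind(accepted_z, z[keep, , drop = FALSE])
    }
  }
  n_acc <- length(accepted_seq)
  if (n_acc < constraints$n_candidates)
    stop(sprintf(
      "sampler starved: accepted %d/%d after %d attempts (acceptance rate %.4f)",
      n_acc, constraints$n_candidates, attempted, n_acc / max(1L, attempted)))
  take <- seq_len(constraints$n_candidates)
  out <- data.frame(id = sprintf("%s_%05d", id_prefix, take),
                    sequence = accepted_seq[take],
                    hamming_to_wt = accepted_h[take],
                    source = "synthetic", stringsAsFactors = FALSE)
  for (j in seq_len(d)) out[[paste0("z", j)]] <- accepted_z[take, j]
  out
}

#' Run one data-informed design round
#'
#' Proposes an oversampled pool of Hamming-constrained variants (excluding
#' everything already screened), ranks the pool by the property head's
#' predicted maximum tolerated temperature (descending; ties broken by fewer
#' mutations, then lexical id), and returns the top \code{n_candidates} with
#' a provenance round label.
#'
#' @param model A trained semi-supervised \code{\linkS4class{RcaVae}}.
#' @param wildtype Gapped wildtype sequence.
#' @param screen_history Optional data.frame of previously screened records
#'   with a \code{sequence} column; those sequences are excluded.
#' @param constraints A \code{\link{designConstraints}}.
#' @param round_label Provenance label attached to the output.
#' @param pool_factor Oversampling factor for the candidate pool.
#' @return data.frame as \code{\link{proposeVariants}}, plus
#'   \code{predicted_tmax} and \code{round}, ranked best-first.
#' @export
designRound <- function(model, wildtype, screen_history = NULL,
                        constraints = designConstraints(),
                        round_label = "design1", pool_factor = 10L) {
  check_trained(model)
  if (!model@supervised && !is.null(screen_history) && nrow(screen_history))
    stop("ranking on screen history requires a semi-supervised model")
  excl <- constraints$exclusion_ids
  if (!is.null(screen_history) && "sequence" %in% names(screen_history))
    excl <- unique(c(excl, screen_history$sequence))
  pool_con <- constraints
  pool_con$exclusion_ids <- excl
  pool_con$n_candidates <- constraints$n_candidates * as.integer(pool_factor)
  pool <- proposeVariants(model, wildtype, pool_con,
                          id_prefix = paste0(round_label, "_cand"))
  pred <- if (model@supervised) {
    predictProperty(model, stats::setNames(pool$sequence, pool$id))$tmax_pred
  } else {
    rep(0, nrow(pool))  # unsupervised baseline: arbitrary (stable) order
  }
  pool$predicted_tmax <- pred
  ord <- order(-pool$predicted_tmax, pool$hamming_to_wt, pool$id)
  out <- pool[ord[seq_len(min(constraints$n_candidates, nrow(pool)))], ,
              drop = FALSE]
  out$round <- round_label
  out$id <- sprintf("%s_%05d", round_label, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Write a design-round manifest
#'
#' Emits candidates as FASTA plus a CSV manifest (id, round, hamming_to_wt,
#' predicted_tmax, latent coordinates).
#'
#' @param candidates Output of \code{\link{designRound}} or
#'   \code{\link{proposeVariants}}.
#' @param fasta_path,manifest_path Output file paths.
#' @return \code{manifest_path}, invisibly.
#' @export
writeCandidates <- function(candidates, fasta_path, manifest_path) {
  seqs <- Biostrings::AAStringSet(stats::setNames(candidates$sequence,
                                                  candidates$id))
  Biostrings::writeXStringSet(seqs, filepath = fasta_path)
  man <- candidates[, setdiff(names(candidates), "sequence"), drop = FALSE]
  utils::write.csv(man, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}
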