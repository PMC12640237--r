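# Training objective and loop. The objective is
#   L = alpha * L_recon + beta * L_KL
# with L_recon the mean absolute error between the predicted foreground
# matrix and the binary target over unmasked entries, and L_KL the
# analytic KL divergence of the diagonal-Gaussian posterior from N(0, I),
# averaged over unmasked positions and latent dimensions (so beta's scale
# is length-invariant). Optimizer: AdamW with decoupled weight decay.

#' Loss weights
#'
#' @param alpha reconstruction weight (default 0.9).
#' @param beta KL weight (default 0.1); beta = 0 removes the variational
#'   regularizer and reduces the model to a deterministic transformer.
#' @return list of class \code{lossWeights}.
#' @export
lossWeights <- function(alpha = 0.9, beta = 0.1) {
  stopifnot(alpha >= 0, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "lossWeights")
}

#' KL divergence of the per-position posterior from the standard normal
#'
#' Computes -1/2 * mean(1 + logvar - mu^2 - exp(logvar)) over unmasked
#' positions and latent dimensions: the analytic KL of N(mu, sigma^2)
#' from N(0, I), elementwise nonnegative. Padded positions contribute
#' nothing.
#'
#' @param lat list with \code{mu}, \code{logvar} (L x d_latent).
#' @param pad_mask logical length-L vector (NULL = all valid).
#' @return nonnegative scalar.
#' @export
klLoss <- function(lat, pad_mask = NULL) {
  mu <- lat$mu; lv <- lat$logvar
  if (any(!is.finite(mu)) || any(!is.finite(lv)))
    stop("non-finite latent parameters")
  if (!is.null(pad_mask)) {
    mu <- mu[pad_mask, , drop = FALSE]
    lv <- lv[pad_mask, , drop = FALSE]
  }
  -0.5 * mean(1 + lv - mu^2 - exp(lv))
}

#' Reconstruction loss: masked mean absolute error
#'
#' @param pred predicted matrix (\linkS4class{PairProbabilityMatrix} or
#'   plain matrix).
#' @param target a \linkS4class{TargetMatrix} (its mask selects the valid
#'   entries).
#' @return nonnegative scalar.
#' @export
reconLoss <- function(pred, target) {
  p <- if (is(pred, "PairProbabilityMatrix")) probValues(pred) else pred
  if (!identical(dim(p), dim(target@values)))
    stop(sprintf("shape mismatch: prediction %dx%d vs target %dx%d",
                 nrow(p), ncol(p), nrow(target@values), ncol(target@values)))
  mean(abs(p[target@mask] - target@values[target@mask]))
}

#' Weighted total loss
#'
#' @param recon reconstruction loss value.
#' @param kl KL loss value.
#' @param w a \code{\link{lossWeights}}.
#' @return alpha * recon + beta * kl.
#' @export
totalLoss <- function(recon, kl, w = lossWeights()) {
  w$alpha * recon + w$beta * kl
}

#' Training configuration
#'
#' Optimizer defaults follow the AdamW settings used for the full-scale
#' model (learning rate 1e-4, beta1 0.9, beta2 0.999, weight decay 0.01,
#' batch size 4); \code{max_steps} defaults to a desk-scale 2000 rather
#' than the full-scale 400000.
#'
#' @param learning_rate AdamW step size.
#' @param adam_beta1,adam_beta2 AdamW moment decays.
#' @param weight_decay decoupled L2 decay on weight matrices.
#' @param label_smooth training-target smoothing c in [0, 0.5): pair
#'   entries train toward 1 - c and non-pair entries toward c. With a
#'   mean-absolute-error objective on a sigmoid output, hard 0/1 targets
#'   admit a saturated majority-class fixed point (every output driven to
#'   0, where the positive-pair gradient vanishes); smoothing places the
#'   per-entry optimum inside the sigmoid's responsive range. The
#'   downstream log-odds matcher thresholds at the background level, so
#'   calibration to [c, 1 - c] is inconsequential for decoding.
#' @param batch_size sequences per step.
#' @param max_steps optimizer steps.
#' @param kl_warmup_steps warm-start KL annealing (0 = off): the KL
#'   weight beta is held at 0 for the first \code{kl_warmup_steps} steps,
#'   then ramped linearly to its configured value over the same number of
#'   steps again. At short training budgets the KL pull empties the
#'   latent channel before the decoder learns to read it (posterior
#'   collapse), after which no reconstruction signal can revive it; the
#'   KL-free phase lets reconstruction claim the latent first.
#' @param adam_restart_every when > 0, the AdamW moment estimates are
#'   reset every this many steps (warm restarts). Under the bang-bang
#'   subgradients of the absolute-error objective the second-moment
#'   estimate settles at the oscillation amplitude and suppresses the
#'   small consistent gradient components; periodic resets give those
#'   components a window in which they move at full step size. 0 = off.
#' @param seed RNG seed controlling batching, noise and dropout.
#' @param checkpoint_every write a checkpoint every this many steps
#'   (0 = off; requires \code{checkpoint_path}).
#' @param checkpoint_path checkpoint file path.
#' @param log_path optional TSV loss-log path (step, recon, kl, total).
#' @return list of class \code{trainConfig}.
#' @export
trainConfig <- function(learning_rate = 1e-4, adam_beta1 = 0.9,
                        adam_beta2 = 0.999, weight_decay = 0.01,
                        label_smooth = 0.1, kl_warmup_steps = 0L,
                        adam_restart_every = 0L,
                        batch_size = 4L, max_steps = 2000L, seed = 1L,
                        checkpoint_every = 0L, checkpoint_path = NULL,
                        log_path = NULL) {
  stopifnot(learning_rate > 0, max_steps >= 1L, batch_size >= 1L,
            adam_beta1 >= 0, adam_beta1 < 1, adam_beta2 >= 0, adam_beta2 < 1,
            weight_decay >= 0, label_smooth >= 0, label_smooth < 0.5,
            kl_warmup_steps >= 0, adam_restart_every >= 0)
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, weight_decay = weight_decay,
                 label_smooth = label_smooth,
                 kl_warmup_steps = as.integer(kl_warmup_steps),
                 adam_restart_every = as.integer(adam_restart_every),
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps), seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_path = checkpoint_path, log_path = log_path),
            class = "trainConfig")
}

# loss + gradients for a batch of sequences. Elist: per-sequence valid
# rows; yList/mskList: the (possibly smoothed) target values and
# validity masks; epsList: noise matrices. Per-sequence losses are
# averaged; gradients are summed into one environment pre-scaled by
# 1/batch. A one-element batch is the single-sequence case.
batchLossGrad <- function(params, cfg, Elist, yList, mskList, epsList, w,
                          training = FALSE) {
  if (is.matrix(Elist)) {
    Elist <- list(Elist); yList <- list(yList); mskList <- list(mskList)
    epsList <- list(epsList)
  }
  B <- length(Elist)
  fwd <- tvaeForward(params, cfg, Elist, epsList, training = training,
                     withCache = TRUE)
  Pfg <- if (B == 1L) list(fwd$Pfg) else fwd$Pfg
  recon <- 0
  dPfgList <- vector("list", B)
  for (b in seq_len(B)) {
    y <- yList[[b]]; msk <- mskList[[b]]
    nRec <- sum(msk)
    recon <- recon + mean(abs(Pfg[[b]][msk] - y[msk])) / B
    # d recon / d Pfg, masked; the forced-zero diagonal has no gradient
    dP <- matrix(0, nrow(y), ncol(y))
    dP[msk] <- sign(Pfg[[b]][msk] - y[msk]) / nRec
    dP <- dP * (w$alpha / B)
    diag(dP) <- 0
    dPfgList[[b]] <- dP
  }
  # KL averaged per sequence over its own positions x dims, then over
  # the batch; dims are constant so the position-weighted mean per
  # segment does the same
  dz <- ncol(fwd$mu)
  lens <- vapply(Elist, nrow, integer(1))
  kl <- 0
  dMu <- matrix(0, nrow(fwd$mu), dz)
  dLv <- matrix(0, nrow(fwd$mu), dz)
  for (b in seq_len(B)) {
    rows <- fwd$segs[[b]]$rows
    mu <- fwd$mu[rows, , drop = FALSE]
    lv <- fwd$logvar[rows, , drop = FALSE]
    kl <- kl + (-0.5 * mean(1 + lv - mu^2 - exp(lv))) / B
    nKl <- lens[b] * dz
    dMu[rows, ] <- w$beta * mu / (nKl * B)
    dLv[rows, ] <- w$beta * 0.5 * (exp(lv) - 1) / (nKl * B)
  }
  genv <- tvaeBackward(params, cfg, fwd, dPfgList, dMu, dLv)
  list(recon = recon, kl = kl, total = totalLoss(recon, kl, w), genv = genv)
}

# single-sequence convenience used by the gradient tests
sequenceLossGrad <- function(params, cfg, E, y, msk, eps, w,
                             training = FALSE) {
  batchLossGrad(params, cfg, E, y, msk, eps, w, training)
}

#' Train the model
#'
#' Mini-batch AdamW on the weighted MAE + KL objective. Each step draws
#' \code{batch_size} items (with replacement), one latent noise matrix per
#' item, accumulates gradients and applies one decoupled-weight-decay Adam
#' update. Fully deterministic under \code{tc$seed} on one device. A
#' non-finite loss aborts with the last-good checkpoint retained (when
#' checkpointing is enabled).
#'
#' @param model a \linkS4class{TvaeModel}.
#' @param dataset list of items with elements \code{sequence} (or
#'   \code{embedding}) and \code{structure} (or \code{target}).
#' @param tc a \code{\link{trainConfig}}.
#' @param w a \code{\link{lossWeights}}.
#' @param verbose print progress every 100 steps.
#' @return list: \code{model} (trained), \code{trajectory} (data.frame
#'   step/recon/kl/total).
#' @export
trainTvae <- function(model, dataset, tc = trainConfig(),
                      w = lossWeights(), verbose = FALSE) {
  cfg <- model@config
  prep <- lapply(dataset, function(item) {
    E <- if (!is.null(item$embedding)) {
      item$embedding@values[item$embedding@padMask, , drop = FALSE]
    } else {
      emb <- oneHotEmbed(item$sequence)
      emb@values
    }
    tgt <- if (!is.null(item$target)) item$target
           else structureToMatrix(item$structure)
    stopifnot(nrow(E) == nrow(tgt@values))
    # smoothed training target; the zero diagonal stays zero (the head
    # pins the diagonal, so it must carry no gradient)
    soft <- tgt@values * (1 - 2 * tc$label_smooth) + tc$label_smooth
    diag(soft) <- 0
    list(E = E, soft = soft, mask = tgt@mask)
  })
  params <- model@params
  # flat views for the optimizer: one long vector per state, with index
  # ranges per parameter (vectorized AdamW is much cheaper than a loop
  # over ~150 arrays)
  pnames <- names(params)
  sizes <- vapply(params, length, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  names(offsets) <- pnames
  flat <- unlist(params, use.names = FALSE)
  mFlat <- numeric(length(flat))
  vFlat <- numeric(length(flat))
  decayMask <- rep(grepl("\\.W", pnames), sizes)  # weight matrices only
  gFlat <- numeric(length(flat))
  stepsSinceRestart <- 0L
  traj <- matrix(NA_real_, tc$max_steps, 4L)
  colnames(traj) <- c("step", "recon", "kl", "total")
  t0 <- model@step

  withSeed(tc$seed, {
    for (step in seq_len(tc$max_steps)) {
      wStep <- w
      if (tc$kl_warmup_steps > 0L) {
        gStep <- t0 + step
        wStep$beta <- w$beta *
          max(0, min(1, (gStep - tc$kl_warmup_steps) / tc$kl_warmup_steps))
      }
      idx <- sample.int(length(prep), tc$batch_size, replace = TRUE)
      gFlat[] <- 0
      items <- prep[idx]
      epsList <- lapply(items, function(it)
        matrix(stats::rnorm(nrow(it$E) * cfg$d_latent), nrow(it$E),
               cfg$d_latent))
      r <- batchLossGrad(params, cfg, lapply(items, `[[`, "E"),
                         lapply(items, `[[`, "soft"),
                         lapply(items, `[[`, "mask"), epsList, wStep,
                         training = TRUE)
      recon <- r$recon
      kl <- r$kl
      for (nm in ls(r$genv))
        axpy_at(gFlat, offsets[[nm]], r$genv[[nm]])

      total <- totalLoss(recon, kl, wStep)
      if (!is.finite(total)) {
        if (tc$checkpoint_every > 0L && !is.null(tc$checkpoint_path))
          message("non-finite loss; last-good checkpoint retained at ",
                  tc$checkpoint_path)
        stop(sprintf("non-finite loss at step %d; aborting", step))
      }
      traj[step, ] <- c(t0 + step, recon, kl, total)
      # AdamW update (decoupled decay on weight matrices), vectorized
      # over one flat parameter vector
      t <- t0 + step
      b1 <- tc$adam_beta1; b2 <- tc$adam_beta2
      if (tc$adam_restart_every > 0L &&
          step > 1L && (step - 1L) %% tc$adam_restart_every == 0L) {
        mFlat[] <- 0
        vFlat[] <- 0
        stepsSinceRestart <- 0L
      }
      stepsSinceRestart <- stepsSinceRestart + 1L
      # moment bias correction counts from the last (re)start: optimizer
      # state does not persist across checkpoints or restarts
      corr1 <- 1 - b1^stepsSinceRestart; corr2 <- 1 - b2^stepsSinceRestart
      adamw_step_inplace(flat, mFlat, vFlat, gFlat, decayMask,
                         tc$learning_rate, b1, b2, corr1, corr2,
                         tc$weight_decay, 1e-8, 1)
      for (nm in pnames) {
        o <- offsets[[nm]]
        params[[nm]][] <- flat[(o + 1L):(o + sizes[[nm]])]
      }
      if (verbose && step %% 100L == 0L)
        message(sprintf("step %d: recon %.4f kl %.4f total %.4f",
                        t, recon, kl, total))
      if (tc$checkpoint_every > 0L && !is.null(tc$checkpoint_path) &&
          step %% tc$checkpoint_every == 0L) {
        saveCheckpoint(new("TvaeModel", config = cfg, params = params,
                           step = as.integer(t)), tc$checkpoint_path)
      }
    }
  })
  out <- new("TvaeModel", config = cfg, params = params,
             step = as.integer(t0 + tc$max_steps))
  trajDf <- as.data.frame(traj)
  if (!is.null(tc$log_path))
    utils::write.table(trajDf, tc$log_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  list(model = out, trajectory = trajDf)
}

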