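# The transformer variational autoencoder. Encoder: input projection ->
# activation -> layer norm -> N post-norm transformer blocks with
# dynamic-span masked attention and learnable relative position bias.
# A per-position latent (mu, logvar) is read off the encoder states,
# sampled with the reparameterization trick, projected back to model
# width, refined by the decoder blocks, and scored pairwise by a
# symmetric sigmoid head emitting foreground and background L x L
# probability matrices.

#' Model configuration
#'
#' @param d_model hidden width (must divide by \code{n_heads}).
#' @param n_encoder_layers,n_decoder_layers transformer block counts.
#' @param n_heads attention heads.
#' @param d_feedforward FFN hidden width.
#' @param d_latent per-position latent width.
#' @param S_max maximum attention span (positions to each side).
#' @param growth_rate span growth per position:
#'   span(i) = min(S_max, floor(1 + growth_rate * i)), i 0-based.
#' @param max_relative_distance clip for the relative position bias table.
#' @param max_length longest sequence accepted in one forward pass.
#' @param dropout dropout rate (training mode only).
#' @param d_input embedding width D accepted by the projection layer
#'   (4 for one-hot, 640 for the pretrained adapter).
#' @return a validated config list of class \code{modelConfig}.
#' @export
modelConfig <- function(d_model = 256L, n_encoder_layers = 4L,
                        n_decoder_layers = 4L, n_heads = 8L,
                        d_feedforward = 512L, d_latent = 64L,
                        S_max = 64L, growth_rate = 0.5,
                        max_relative_distance = 64L, max_length = 512L,
                        dropout = 0.1, d_input = 4L) {
  cfg <- list(d_model = as.integer(d_model),
              n_encoder_layers = as.integer(n_encoder_layers),
              n_decoder_layers = as.integer(n_decoder_layers),
              n_heads = as.integer(n_heads),
              d_feedforward = as.integer(d_feedforward),
              d_latent = as.integer(d_latent),
              S_max = as.integer(S_max),
              growth_rate = growth_rate,
              max_relative_distance = as.integer(max_relative_distance),
              max_length = as.integer(max_length),
              dropout = dropout,
              d_input = as.integer(d_input))
  stopifnot(cfg$d_model >= 1L, cfg$n_heads >= 1L, cfg$S_max >= 1L,
            cfg$d_latent >= 1L, cfg$d_feedforward >= 1L,
            cfg$growth_rate >= 0, cfg$dropout >= 0, cfg$dropout < 1)
  if (cfg$d_model %% cfg$n_heads != 0L)
    stop("d_model must be divisible by n_heads")
  class(cfg) <- "modelConfig"
  cfg
}

#' Dynamic attention span at a position
#'
#' span(i) = min(S_max, floor(1 + growth_rate * i)) with 0-based i: early
#' positions attend locally, later positions see wider context, capped at
#' \code{S_max}. Never below 1.
#'
#' @param i 0-based position index (vectorized).
#' @param cfg a \code{\link{modelConfig}}.
#' @return integer span(s).
#' @export
dynamicSpan <- function(i, cfg) {
  if (any(i < 0)) stop("position index must be >= 0")
  pmax(1L, pmin(cfg$S_max, as.integer(floor(1 + cfg$growth_rate * i))))
}

#' Build the dynamic-span attention mask
#'
#' Row i (0-based) is TRUE exactly on columns
#' [i - span(i), i + span(i)] intersected with valid, unpadded positions;
#' the diagonal is always TRUE. The mask is generally asymmetric because
#' the span grows with i.
#'
#' @param L sequence length.
#' @param pad_mask logical length-L vector, TRUE for real residues
#'   (NULL = all real).
#' @param cfg a \code{\link{modelConfig}}.
#' @return L x L logical matrix.
#' @export
buildAttentionMask <- function(L, pad_mask = NULL, cfg) {
  if (L > cfg$max_length)
    stop(sprintf("L=%d exceeds max_length=%d", L, cfg$max_length))
  if (is.null(pad_mask)) pad_mask <- rep(TRUE, L)
  spans <- dynamicSpan(seq_len(L) - 1L, cfg)
  cols <- matrix(rep(seq_len(L), each = L), L, L)  # cols[i, j] = j
  lo <- pmax(1L, seq_len(L) - spans)
  hi <- pmin(L, seq_len(L) + spans)
  m <- cols >= lo & cols <= hi
  m[, !pad_mask] <- FALSE
  diag(m) <- TRUE
  m
}

xavierInit <- function(fanIn, fanOut) {
  a <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(fanIn * fanOut, -a, a), fanIn, fanOut)
}

initBlockParams <- function(prefix, cfg) {
  d <- cfg$d_model; dff <- cfg$d_feedforward
  R <- cfg$max_relative_distance
  p <- list()
  for (w in c("Wq", "Wk", "Wv", "Wo")) p[[w]] <- xavierInit(d, d)
  for (b in c("bq", "bk", "bv", "bo")) p[[b]] <- numeric(d)
  p$rb <- matrix(0, cfg$n_heads, 2L * R + 1L)
  p$ln1g <- rep(1, d); p$ln1b <- numeric(d)
  p$W1 <- xavierInit(d, dff); p$b1 <- numeric(dff)
  p$W2 <- xavierInit(dff, d); p$b2 <- numeric(d)
  p$ln2g <- rep(1, d); p$ln2b <- numeric(d)
  names(p) <- paste0(prefix, ".", names(p))
  p
}

initParams <- function(cfg) {
  d <- cfg$d_model; dz <- cfg$d_latent
  p <- list(
    "in.W" = xavierInit(cfg$d_input, d), "in.b" = numeric(d),
    "in.g" = rep(1, d), "in.beta" = numeric(d),
    "mu.W" = xavierInit(d, dz), "mu.b" = numeric(dz),
    # the log-variance head starts at sigma ~ exp(-2) = 0.14 so the latent
    # channel is high signal-to-noise from the first step; the KL term
    # re-inflates the posterior variance toward the prior during training
    # (guards against early posterior collapse at short training budgets)
    "lv.W" = xavierInit(d, dz), "lv.b" = rep(-4, dz),
    "z.W" = xavierInit(dz, d), "z.b" = numeric(d),
    "z.g" = rep(1, d), "z.beta" = numeric(d),
    # sparsity-aware head init: pairing is rare, so the foreground bias
    # starts negative; the background head starts at the exact 0.5 null
    "head.fg.wprod" = stats::rnorm(d, 0, 0.1),
    "head.fg.wsum" = stats::rnorm(d, 0, 0.1),
    "head.fg.b" = -2,
    "head.bg.wprod" = numeric(d),
    "head.bg.wsum" = numeric(d),
    "head.bg.b" = 0)
  for (l in seq_len(cfg$n_encoder_layers))
    p <- c(p, initBlockParams(sprintf("enc%d", l), cfg))
  for (l in seq_len(cfg$n_decoder_layers))
    p <- c(p, initBlockParams(sprintf("dec%d", l), cfg))
  p
}

#' Create (initialize) a transformer-VAE model
#'
#' @param cfg a \code{\link{modelConfig}}.
#' @param seed RNG seed for parameter initialization.
#' @return a \linkS4class{TvaeModel}.
#' @export
tvaeModel <- function(cfg = modelConfig(), seed = 1L) {
  params <- withSeed(seed, initParams(cfg))
  new("TvaeModel", config = unclass(cfg), params = params, step = 0L)
}

#' Total trainable parameter count
#'
#' @param model a \linkS4class{TvaeModel}.
#' @return integer.
#' @export
parameterCount <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

LOGVAR_CLAMP <- 10

# fixed bidirectional sinusoidal position features, added to the encoder
# and decoder inputs after their layer norms. Forward phases encode the
# distance from the 5' end, backward phases the distance from the 3'
# end; their sum gives every position a representation in which two
# positions mirrored about the center (the geometry of a helix closing
# a loop) have maximally-overlapping phase patterns — exactly what the
# multiplicative pairing head needs. Constant per position, so it adds
# nothing to the backward pass. Memoized per (L, d).
.peCache <- new.env(parent = emptyenv())

positionFeatures <- function(L, d) {
  key <- sprintf("%d|%d", L, d)
  hit <- .peCache[[key]]
  if (!is.null(hit)) return(hit)
  half <- d %/% 2L
  freq <- 1 / (10000^((seq_len(half) - 1L) / half))
  fwd <- outer(seq_len(L) - 1L, freq)
  bwd <- outer(L - seq_len(L), freq)
  pe <- matrix(0, L, d)
  pe[, seq_len(half)] <- 0.5 * (sin(fwd) + sin(bwd))
  pe[, half + seq_len(half)] <- 0.5 * (cos(fwd) + cos(bwd))
  .peCache[[key]] <- pe
  pe
}

# full forward pass. Elist: list of per-sequence embedding matrices
# (valid rows only); epsList: matching list of noise matrices (0 for the
# deterministic point prediction). All position-wise operations run over
# one stacked matrix; attention and the pairwise head are block-diagonal
# per sequence. A one-element list is the single-sequence path.
tvaeForward <- function(params, cfg, Elist, epsList, training = FALSE,
                        withCache = FALSE) {
  if (is.matrix(Elist)) Elist <- list(Elist)
  if (is.matrix(epsList) || length(epsList) == 1L && !is.list(epsList))
    epsList <- list(epsList)
  lens <- vapply(Elist, nrow, integer(1))
  ends <- cumsum(lens)
  segs <- lapply(seq_along(lens), function(b) {
    rows <- (ends[b] - lens[b] + 1L):ends[b]
    list(rows = rows, geom = attnGeometry(lens[b], cfg))
  })
  E <- if (length(Elist) == 1L) Elist[[1L]] else do.call(rbind, Elist)
  pe <- if (length(Elist) == 1L) positionFeatures(lens[1L], cfg$d_model)
        else do.call(rbind, lapply(lens, positionFeatures, d = cfg$d_model))
  eps <- if (length(epsList) == 1L) epsList[[1L]]
         else do.call(rbind, epsList)
  pre <- reluFwd(linFwd(E, params[["in.W"]], params[["in.b"]]))
  ln0 <- layerNormFwd(pre, params[["in.g"]], params[["in.beta"]])
  enc <- stackFwd(ln0$Y + pe, params, "enc", cfg$n_encoder_layers, segs, cfg,
                  training)
  H <- enc$Y
  mu <- linFwd(H, params[["mu.W"]], params[["mu.b"]])
  lvRaw <- linFwd(H, params[["lv.W"]], params[["lv.b"]])
  lv <- pmin(pmax(lvRaw, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  if (any(!is.finite(mu)) || any(!is.finite(lv)))
    stop("non-finite activations in the latent projection")
  Z <- mu + eps * exp(0.5 * lv)
  preD <- reluFwd(linFwd(Z, params[["z.W"]], params[["z.b"]]))
  lnD <- layerNormFwd(preD, params[["z.g"]], params[["z.beta"]])
  dec <- stackFwd(lnD$Y + pe, params, "dec", cfg$n_decoder_layers, segs, cfg,
                  training)
  # positional skip into the head: the bidirectional phase features make
  # the mirror-matching kernel sum_k pe_ik pe_jk directly expressible by
  # the multiplicative head instead of having to survive the decoder's
  # layer norms
  Hd <- dec$Y + pe
  fg <- lapply(segs, function(sg)
    pairHeadFwd(Hd[sg$rows, , drop = FALSE], params[["head.fg.wprod"]],
                params[["head.fg.wsum"]], params[["head.fg.b"]]))
  bg <- lapply(segs, function(sg)
    pairHeadFwd(Hd[sg$rows, , drop = FALSE], params[["head.bg.wprod"]],
                params[["head.bg.wsum"]], params[["head.bg.b"]]))
  single <- length(segs) == 1L
  out <- list(mu = mu, logvar = lv, Z = Z,
              Pfg = if (single) fg[[1L]]$P else lapply(fg, `[[`, "P"),
              Pbg = if (single) bg[[1L]]$P else lapply(bg, `[[`, "P"),
              segs = segs)
  if (withCache)
    out$cache <- list(E = E, segs = segs, pre = pre, ln0 = ln0, enc = enc,
                      H = H, lvRaw = lvRaw, eps = eps, preD = preD,
                      lnD = lnD, dec = dec, Hd = Hd, fg = fg, bg = bg)
  out
}

# backward pass: dPfgList is the per-sequence loss gradient on the
# foreground matrices (zero diagonals); dMu/dLv are direct gradients on
# the stacked latent parameters (the KL term). Returns the gradient
# environment.
tvaeBackward <- function(params, cfg, fwd, dPfgList, dMu = NULL,
                         dLv = NULL) {
  ca <- fwd$cache
  if (is.matrix(dPfgList)) dPfgList <- list(dPfgList)
  genv <- new.env(parent = emptyenv())
  dHd <- matrix(0, nrow(ca$Hd), ncol(ca$Hd))
  for (b in seq_along(ca$segs)) {
    rows <- ca$segs[[b]]$rows
    dHd[rows, ] <- pairHeadBwd(dPfgList[[b]], ca$fg[[b]]$P,
                               ca$Hd[rows, , drop = FALSE],
                               params[["head.fg.wprod"]],
                               params[["head.fg.wsum"]], genv, "head.fg")
  }
  dHd <- stackBwd(dHd, ca$dec$caches, params, "dec", cfg$n_decoder_layers,
                  ca$segs, cfg, genv)
  dPreD <- layerNormBwd(dHd, ca$lnD, params[["z.g"]], genv, "z.g", "z.beta")
  dPreD[ca$preD <= 0] <- 0
  dZ <- linBwd(dPreD, fwd$Z, params[["z.W"]], genv, "z.W", "z.b")
  dMuT <- dZ
  dLvT <- dZ * ca$eps * 0.5 * exp(0.5 * fwd$logvar)
  if (!is.null(dMu)) dMuT <- dMuT + dMu
  if (!is.null(dLv)) dLvT <- dLvT + dLv
  dLvT[abs(ca$lvRaw) >= LOGVAR_CLAMP] <- 0   # clamp gate
  dH <- linBwd(dMuT, ca$H, params[["mu.W"]], genv, "mu.W", "mu.b") +
        linBwd(dLvT, ca$H, params[["lv.W"]], genv, "lv.W", "lv.b")
  dH <- stackBwd(dH, ca$enc$caches, params, "enc", cfg$n_encoder_layers,
                 ca$segs, cfg, genv)
  dPre <- layerNormBwd(dH, ca$ln0, params[["in.g"]], genv, "in.g", "in.beta")
  dPre[ca$pre <= 0] <- 0
  linBwd(dPre, ca$E, params[["in.W"]], genv, "in.W", "in.b")
  genv
}

#' Encode a sequence to per-position latent parameters
#'
#' Runs the encoder half only: embedding projection, transformer blocks,
#' and the latent linear heads. The log-variance is clamped to [-10, 10]
#' for numerical stability. Padded positions return zero rows and are
#' flagged in the \code{padMask} attribute.
#'
#' @param model a \linkS4class{TvaeModel}.
#' @param emb an \linkS4class{EmbeddingMatrix} (or an
#'   \linkS4class{RnaSequence}, one-hot embedded automatically).
#' @return list with \code{mu} and \code{logvar} (both L_pad x d_latent)
#'   and attribute-free element \code{padMask}.
#' @export
encodeLatent <- function(model, emb) {
  emb <- asEmbedding(model, emb)
  cfg <- model@config
  valid <- emb@padMask
  E <- emb@values[valid, , drop = FALSE]
  L <- nrow(E)
  if (L > cfg$max_length)
    stop(sprintf("L=%d exceeds max_length=%d", L, cfg$max_length))
  segs <- list(list(rows = seq_len(L), geom = attnGeometry(L, cfg)))
  pe <- positionFeatures(L, cfg$d_model)
  pre <- reluFwd(linFwd(E, model@params[["in.W"]], model@params[["in.b"]]))
  ln0 <- layerNormFwd(pre, model@params[["in.g"]], model@params[["in.beta"]])
  H <- stackFwd(ln0$Y + pe, model@params, "enc", cfg$n_encoder_layers, segs,
                cfg)$Y
  mu <- linFwd(H, model@params[["mu.W"]], model@params[["mu.b"]])
  lv <- linFwd(H, model@params[["lv.W"]], model@params[["lv.b"]])
  lv <- pmin(pmax(lv, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  if (any(!is.finite(mu)) || any(!is.finite(lv)))
    stop("non-finite activations in the latent projection")
  Lp <- length(valid); dz <- cfg$d_latent
  muFull <- matrix(0, Lp, dz); lvFull <- matrix(0, Lp, dz)
  muFull[valid, ] <- mu; lvFull[valid, ] <- lv
  list(mu = muFull, logvar = lvFull, padMask = valid)
}

#' Reparameterization: Z = mu + eps * exp(0.5 * logvar)
#'
#' @param lat list with \code{mu}, \code{logvar} (equal shapes).
#' @param eps noise matrix of the same shape: standard-normal draws for
#'   sampling, or 0 for the deterministic point estimate Z = mu.
#' @return latent matrix Z.
#' @export
reparameterize <- function(lat, eps = 0) {
  if (length(eps) > 1L && !identical(dim(eps), dim(lat$mu)))
    stop("noise shape must match mu")
  lat$mu + eps * exp(0.5 * lat$logvar)
}

asEmbedding <- function(model, x) {
  if (is(x, "RnaSequence")) {
    if (model@config$d_input != 4L)
      stop("model expects precomputed embeddings (d_input != 4); pass an EmbeddingMatrix")
    oneHotEmbed(x)
  } else if (is(x, "EmbeddingMatrix")) {
    if (ncol(x@values) != model@config$d_input)
      stop(sprintf("embedding width %d does not match model d_input %d",
                   ncol(x@values), model@config$d_input))
    x
  } else stop("expected an RnaSequence or EmbeddingMatrix")
}

#' Deterministic point prediction of pairing probabilities
#'
#' Uses eps = 0 (Z = mu): the maximum a posteriori latent under the
#' diagonal Gaussian, giving a single deterministic probability matrix
#' pair.
#'
#' @param model a \linkS4class{TvaeModel}.
#' @param x an \linkS4class{RnaSequence} or \linkS4class{EmbeddingMatrix}.
#' @return list of \linkS4class{PairProbabilityMatrix}: \code{fg}, \code{bg}.
#' @export
predictMap <- function(model, x) {
  emb <- asEmbedding(model, x)
  E <- emb@values[emb@padMask, , drop = FALSE]
  cfg <- model@config
  if (nrow(E) > cfg$max_length)
    stop(sprintf("L=%d exceeds max_length=%d", nrow(E), cfg$max_length))
  fwd <- tvaeForward(model@params, cfg, E,
                     eps = matrix(0, nrow(E), cfg$d_latent))
  list(fg = PairProbabilityMatrix(symmetrize(fwd$Pfg), "foreground"),
       bg = PairProbabilityMatrix(symmetrize(fwd$Pbg), "background"))
}

symmetrize <- function(m) {
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Sample K probability-matrix pairs from the latent space
#'
#' Encodes once, then draws K independent standard-normal noise matrices
#' and decodes each Z = mu + eps * sigma. Deterministic under \code{seed}.
#'
#' @param model a \linkS4class{TvaeModel}.
#' @param x an \linkS4class{RnaSequence} or \linkS4class{EmbeddingMatrix}.
#' @param K number of draws (>= 1).
#' @param seed RNG seed.
#' @return list of K elements, each list(fg=, bg=) of
#'   \linkS4class{PairProbabilityMatrix}.
#' @export
sampleMatrices <- function(model, x, K, seed = 1L) {
  if (K < 1L) stop("K must be >= 1")
  emb <- asEmbedding(model, x)
  E <- emb@values[emb@padMask, , drop = FALSE]
  cfg <- model@config
  withSeed(seed, {
    lapply(seq_len(K), function(k) {
      eps <- matrix(stats::rnorm(nrow(E) * cfg$d_latent), nrow(E),
                    cfg$d_latent)
      fwd <- tvaeForward(model@params, cfg, E, eps)
      list(fg = PairProbabilityMatrix(symmetrize(fwd$Pfg), "foreground"),
           bg = PairProbabilityMatrix(symmetrize(fwd$Pbg), "background"))
    })
  })
}

#' Save / load model checkpoints
#'
#' The checkpoint is a single RDS container (config + weights + step
#' counter); a YAML sidecar \code{<path>.yml} echoes the config so
#' checkpoints are self-describing in plain text.
#'
#' @param model a \linkS4class{TvaeModel}.
#' @param path checkpoint file path.
#' @return \code{path} (save) or the model (load).
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params,
               step = model@step), path)
  yaml::write_yaml(c(model@config, list(step = model@step)),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  new("TvaeModel", config = x$config, params = x$params,
      step = as.integer(x$step))
}
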