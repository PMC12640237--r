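# Dense-layer / layer-norm / masked multi-head attention primitives with
# hand-written reverse-mode gradients. All tensors are plain numeric
# matrices (rows = positions); parameters live in a flat named list and
# gradients are accumulated into an environment under the same names.
# Correctness is pinned by a finite-difference gradient test.

addGrad <- function(genv, name, value) {
  if (is.null(genv[[name]])) genv[[name]] <- value
  else genv[[name]] <- genv[[name]] + value
  invisible(NULL)
}

linFwd <- function(X, W, b) {
  Y <- X %*% W
  Y + rep(b, each = nrow(Y))
}

linBwd <- function(dY, X, W, genv, nW, nb) {
  addGrad(genv, nW, crossprod(X, dY))
  addGrad(genv, nb, colSums(dY))
  tcrossprod(dY, W)
}

reluFwd <- function(X) {
  Y <- X
  Y[Y < 0] <- 0
  Y
}

LN_EPS <- 1e-5

layerNormFwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * invstd
  n <- nrow(X)
  list(Y = xhat * rep(g, each = n) + rep(b, each = n),
       xhat = xhat, invstd = invstd)
}

layerNormBwd <- function(dY, cache, g, genv, ng, nb) {
  xhat <- cache$xhat
  addGrad(genv, ng, colSums(dY * xhat))
  addGrad(genv, nb, colSums(dY))
  dxhat <- dY * rep(g, each = nrow(dY))
  (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$invstd
}

dropoutFwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(Y = X * mask, mask = mask)
}

dropoutBwd <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

rowSoftmaxMasked <- function(S, mask) {
  S[!mask] <- -Inf
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E[!mask] <- 0
  E / rowSums(E)
}

# geometry shared by every attention layer at one sequence length:
# the dynamic-span mask and the clipped relative-offset index matrix.
# Memoized per (L, config fingerprint) — it is pure geometry and gets
# recomputed for every forward pass otherwise.
.geomCache <- new.env(parent = emptyenv())

attnGeometry <- function(L, cfg, pad_mask = NULL) {
  key <- NULL
  if (is.null(pad_mask)) {
    key <- sprintf("%d|%d|%g|%d", L, cfg$S_max, cfg$growth_rate,
                   cfg$max_relative_distance)
    hit <- .geomCache[[key]]
    if (!is.null(hit)) return(hit)
  }
  mask <- buildAttentionMask(L, pad_mask, cfg)
  R <- cfg$max_relative_distance
  off <- outer(seq_len(L) - 1L, seq_len(L) - 1L, "-")  # i - j
  off <- pmin(pmax(off, -R), R) + R + 1L               # 1 .. 2R+1
  geom <- list(mask = mask, offIdx = off)
  if (!is.null(key)) .geomCache[[key]] <- geom
  geom
}

# segs: list of per-sequence segments, each list(rows = integer row
# range within the stacked matrix, geom = attnGeometry for that length).
# A one-element segs processes a single sequence; several segments stack
# a whole batch so every position-wise op runs as one BLAS call while
# attention stays block-diagonal.
attnFwd <- function(X, params, prefix, segs, cfg, training = FALSE) {
  p <- function(s) params[[paste0(prefix, ".", s)]]
  Q <- linFwd(X, p("Wq"), p("bq"))
  K <- linFwd(X, p("Wk"), p("bk"))
  V <- linFwd(X, p("Wv"), p("bv"))
  h <- cfg$n_heads
  dk <- cfg$d_model / h
  scale <- 1 / sqrt(dk)
  rb <- p("rb")                       # n_heads x (2R+1)
  O <- matrix(0, nrow(X), cfg$d_model)
  A <- vector("list", length(segs))
  for (b in seq_along(segs)) {
    rows <- segs[[b]]$rows
    geom <- segs[[b]]$geom
    L <- length(rows)
    Ab <- vector("list", h)
    for (hd in seq_len(h)) {
      cols <- ((hd - 1L) * dk + 1L):(hd * dk)
      S <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) * scale
      S <- S + matrix(rb[hd, geom$offIdx], L, L)
      Ab[[hd]] <- rowSoftmaxMasked(S, geom$mask)
      O[rows, cols] <- Ab[[hd]] %*% V[rows, cols, drop = FALSE]
    }
    A[[b]] <- Ab
  }
  out <- linFwd(O, p("Wo"), p("bo"))
  drp <- dropoutFwd(out, cfg$dropout, training)
  list(Y = drp$Y, cache = list(X = X, Q = Q, K = K, V = V, A = A, O = O,
                               dropMask = drp$mask))
}

attnBwd <- function(dY, cache, params, prefix, segs, cfg, genv) {
  p <- function(s) params[[paste0(prefix, ".", s)]]
  n <- function(s) paste0(prefix, ".", s)
  dY <- dropoutBwd(dY, cache$dropMask)
  dO <- linBwd(dY, cache$O, p("Wo"), genv, n("Wo"), n("bo"))
  h <- cfg$n_heads
  dk <- cfg$d_model / h
  scale <- 1 / sqrt(dk)
  dQ <- matrix(0, nrow(cache$X), cfg$d_model)
  dK <- matrix(0, nrow(cache$X), cfg$d_model)
  dV <- matrix(0, nrow(cache$X), cfg$d_model)
  drb <- matrix(0, nrow(p("rb")), ncol(p("rb")))
  for (b in seq_along(segs)) {
    rows <- segs[[b]]$rows
    geom <- segs[[b]]$geom
    offVec <- as.vector(geom$offIdx)
    for (hd in seq_len(h)) {
      cols <- ((hd - 1L) * dk + 1L):(hd * dk)
      A <- cache$A[[b]][[hd]]
      dOh <- dO[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, cache$V[rows, cols, drop = FALSE])
      dV[rows, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      # relative-bias gradient: sum dS over entries sharing one offset
      acc <- rowsum(as.vector(dS), offVec)
      drb[hd, as.integer(rownames(acc))] <-
        drb[hd, as.integer(rownames(acc))] + acc[, 1L]
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] * scale
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) *
        scale
    }
  }
  addGrad(genv, n("rb"), drb)
  dX <- linBwd(dQ, cache$X, p("Wq"), genv, n("Wq"), n("bq")) +
        linBwd(dK, cache$X, p("Wk"), genv, n("Wk"), n("bk")) +
        linBwd(dV, cache$X, p("Wv"), genv, n("Wv"), n("bv"))
  dX
}

ffnFwd <- function(X, params, prefix, cfg, training = FALSE) {
  p <- function(s) params[[paste0(prefix, ".", s)]]
  H <- reluFwd(linFwd(X, p("W1"), p("b1")))
  drp <- dropoutFwd(H, cfg$dropout, training)
  Y <- linFwd(drp$Y, p("W2"), p("b2"))
  list(Y = Y, cache = list(X = X, H = H, Hd = drp$Y, dropMask = drp$mask))
}

ffnBwd <- function(dY, cache, params, prefix, cfg, genv) {
  p <- function(s) params[[paste0(prefix, ".", s)]]
  n <- function(s) paste0(prefix, ".", s)
  dH <- linBwd(dY, cache$Hd, p("W2"), genv, n("W2"), n("b2"))
  dH <- dropoutBwd(dH, cache$dropMask)
  dH[cache$H <= 0] <- 0
  linBwd(dH, cache$X, p("W1"), genv, n("W1"), n("b1"))
}

# one post-norm transformer block: x -> LN1(x + Attn(x)) -> LN2(. + FFN(.))
blockFwd <- function(X, params, prefix, segs, cfg, training = FALSE) {
  p <- function(s) params[[paste0(prefix, ".", s)]]
  at <- attnFwd(X, params, prefix, segs, cfg, training)
  ln1 <- layerNormFwd(X + at$Y, p("ln1g"), p("ln1b"))
  ff <- ffnFwd(ln1$Y, params, prefix, cfg, training)
  ln2 <- layerNormFwd(ln1$Y + ff$Y, p("ln2g"), p("ln2b"))
  list(Y = ln2$Y, cache = list(at = at$cache, ln1 = ln1, ff = ff$cache,
                               ln2 = ln2))
}

blockBwd <- function(dY, cache, params, prefix, segs, cfg, genv) {
  p <- function(s) params[[paste0(prefix, ".", s)]]
  n <- function(s) paste0(prefix, ".", s)
  d2 <- layerNormBwd(dY, cache$ln2, p("ln2g"), genv, n("ln2g"), n("ln2b"))
  dFf <- ffnBwd(d2, cache$ff, params, prefix, cfg, genv)
  d1 <- layerNormBwd(d2 + dFf, cache$ln1, p("ln1g"), genv, n("ln1g"), n("ln1b"))
  dAt <- attnBwd(d1, cache$at, params, prefix, segs, cfg, genv)
  d1 + dAt
}

stackFwd <- function(X, params, prefix, nLayers, segs, cfg, training = FALSE) {
  caches <- vector("list", nLayers)
  for (l in seq_len(nLayers)) {
    b <- blockFwd(X, params, sprintf("%s%d", prefix, l), segs, cfg, training)
    X <- b$Y
    caches[[l]] <- b$cache
  }
  list(Y = X, caches = caches)
}

stackBwd <- function(dY, caches, params, prefix, nLayers, segs, cfg, genv) {
  for (l in rev(seq_len(nLayers)))
    dY <- blockBwd(dY, caches[[l]], params, sprintf("%s%d", prefix, l),
                   segs, cfg, genv)
  dY
}

# pairwise scoring head. For decoder states H (L x d) and channel weights
# (wprod, wsum, b): raw_ij = sum_k wprod_k H_ik H_jk + a_i + a_j with
# a = H wsum; logit_ij = raw_ij - mean(raw, off-diagonal) + b. Symmetric
# by construction; sigmoid, then zero diagonal.
#
# The centering matters: under a mean-absolute-error objective the
# majority (unpaired) entries exert a large uniform pressure on every
# logit. Without centering that pressure reaches all trunk parameters
# coherently and the optimizer implements it by aligning the decoder
# rows, wiping out the positional features the relational term needs.
# Centering confines the uniform mode to the scalar bias; the trunk sees
# zero-mean gradients and keeps its feature diversity.
pairHeadFwd <- function(H, wprod, wsum, b) {
  L <- nrow(H)
  Hw <- H * rep(wprod, each = L)
  a <- drop(H %*% wsum)
  raw <- tcrossprod(Hw, H) + outer(a, rep(1, L)) + outer(rep(1, L), a)
  off <- if (L > 1L) mean(raw[row(raw) != col(raw)]) else 0
  logits <- raw - off + b
  P <- 1 / (1 + exp(-logits))
  diag(P) <- 0
  list(P = P, logits = logits)
}

pairHeadBwd <- function(dP, P, H, wprod, wsum, genv, prefix) {
  # dP must already be zero on the diagonal
  dLog <- dP * P * (1 - P)
  addGrad(genv, paste0(prefix, ".b"), sum(dLog))
  # back through the off-diagonal centering: every off-diagonal raw entry
  # receives an equal share of -sum(dLog)
  L <- nrow(P)
  dRaw <- dLog
  if (L > 1L) {
    s <- sum(dLog) / (L * L - L)
    dRaw <- dLog - s
    diag(dRaw) <- diag(dLog)  # diagonal entries do not enter the mean
  }
  da <- rowSums(dRaw) + colSums(dRaw)
  Hw <- H * rep(wprod, each = L)
  M <- dRaw %*% H
  addGrad(genv, paste0(prefix, ".wprod"), colSums(M * H))
  addGrad(genv, paste0(prefix, ".wsum"), drop(crossprod(H, da)))
  # raw = Hw %*% t(H) with Hw = H diag(wprod):
  #   via the left factor Hw:  dHw = dRaw %*% H,  dH += dHw diag(wprod)
  #   via the right factor H:  dH += t(dRaw) %*% Hw
  dH <- M * rep(wprod, each = L) + crossprod(dRaw, Hw)
  dH + outer(da, wsum)
}
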