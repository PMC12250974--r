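# Independent loop-based reference implementations used as oracles.
# Deliberately slow and literal; they share no code with the package's
# compiled forward pass.

refConv1d <- function(x, W, b) {
  C <- nrow(x); L <- ncol(x); D <- dim(W)[1]; k <- dim(W)[3]; pad <- k %/% 2
  out <- matrix(0, L, D)
  for (t in seq_len(L)) {
    for (d in seq_len(D)) {
      acc <- b[d]
      for (j in seq_len(k)) {
        s <- t + (j - 1) - pad
        if (s >= 1 && s <= L) acc <- acc + sum(W[d, , j] * x[, s])
      }
      out[t, d] <- acc
    }
  }
  out
}

refPosEncoding <- function(L, D) {
  pe <- matrix(0, L, D)
  for (pos in 0:(L - 1)) {
    for (k in 0:(D / 2 - 1)) {
      arg <- pos / 10000^(2 * k / D)
      pe[pos + 1, 2 * k + 1] <- sin(arg)
      pe[pos + 1, 2 * k + 2] <- cos(arg)
    }
  }
  pe
}

refAttention <- function(O, w, nHeads) {
  L <- nrow(O); D <- ncol(O); dh <- D / nHeads
  addRow <- function(M, v) sweep(M, 2, v, `+`)
  Q <- addRow(O %*% w$Wq, w$bq)
  K <- addRow(O %*% w$Wk, w$bk)
  V <- addRow(O %*% w$Wv, w$bv)
  H <- matrix(0, L, D)
  A <- array(0, c(L, L, nHeads))
  for (h in seq_len(nHeads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    for (i in seq_len(L)) {
      e <- exp(S[i, ] - max(S[i, ]))
      A[i, , h] <- e / sum(e)
    }
    H[, cols] <- A[, , h] %*% V[, cols, drop = FALSE]
  }
  list(out = addRow(H %*% w$Wo, w$bo), attn = A)
}

refLayerNorm <- function(X, g, b, eps = 1e-5) {
  out <- X
  for (i in seq_len(nrow(X))) {
    mu <- mean(X[i, ])
    v <- mean((X[i, ] - mu)^2)
    out[i, ] <- (X[i, ] - mu) / sqrt(v + eps) * g + b
  }
  out
}

refFfn <- function(X, w) {
  h <- pmax(sweep(X %*% w$W1, 2, w$b1, `+`), 0)
  sweep(h %*% w$W2, 2, w$b2, `+`)
}

refBlock <- function(O, w, nHeads, standardBlock = FALSE) {
  oa <- refAttention(O, w, nHeads)$out
  if (standardBlock) {
    a1 <- refLayerNorm(O + oa, w$ln1g, w$ln1b)
    refLayerNorm(a1 + refFfn(a1, w), w$ln2g, w$ln2b)
  } else {
    refLayerNorm(oa + refFfn(oa, w), w$ln2g, w$ln2b)
  }
}

refConv2dSame <- function(img, K, bias) {
  L <- nrow(img); D <- ncol(img)
  ph <- nrow(K) %/% 2; pw <- ncol(K) %/% 2
  out <- matrix(bias, L, D)
  for (y in seq_len(L)) {
    for (x in seq_len(D)) {
      acc <- 0
      for (dy in -ph:ph) {
        for (dx in -pw:pw) {
          yy <- y + dy; xx <- x + dx
          if (yy >= 1 && yy <= L && xx >= 1 && xx <= D) {
            acc <- acc + K[dy + ph + 1, dx + pw + 1] * img[yy, xx]
          }
        }
      }
      out[y, x] <- out[y, x] + acc
    }
  }
  out
}

refGelu <- function(x) x * stats::pnorm(x)  # 0.5 x (1 + erf(x / sqrt(2)))

# trunk on a list of L x D feature maps (training-mode batch statistics)
refTrunk <- function(Zs, p, ch, nBlocks, eps = 1e-5) {
  B <- length(Zs)
  L <- nrow(Zs[[1]]); D <- ncol(Zs[[1]])
  conv <- list()
  for (bb in seq_len(B)) {
    conv[[bb]] <- lapply(seq_len(ch), function(c)
      refConv2dSame(Zs[[bb]], p$trunk_convW[, , c], p$trunk_convb[c]))
  }
  # batch norm per channel over batch x space, then ReLU
  act <- conv
  for (c in seq_len(ch)) {
    allv <- unlist(lapply(conv, function(s) s[[c]]))
    mu <- mean(allv)
    v <- mean((allv - mu)^2)
    for (bb in seq_len(B)) {
      xh <- (conv[[bb]][[c]] - mu) / sqrt(v + eps)
      act[[bb]][[c]] <- pmax(xh * p$trunk_bn_g[c] + p$trunk_bn_b[c], 0)
    }
  }
  # max pool 2x2 stride 2
  Lp <- L %/% 2; Dp <- D %/% 2
  pool <- lapply(act, function(s) lapply(s, function(m) {
    out <- matrix(0, Lp, Dp)
    for (y in seq_len(Lp)) for (x in seq_len(Dp)) {
      out[y, x] <- max(m[(2 * y - 1):(2 * y), (2 * x - 1):(2 * x)])
    }
    out
  }))
  cur <- pool
  for (j in seq_len(nBlocks)) {
    W <- p[[sprintf("cnx%d_W", j)]]
    bj <- p[[sprintf("cnx%d_b", j)]]
    lng <- p[[sprintf("cnx%d_lng", j)]]
    lnb <- p[[sprintf("cnx%d_lnb", j)]]
    nxt <- cur
    for (bb in seq_len(B)) {
      dw <- lapply(seq_len(ch), function(c)
        refConv2dSame(cur[[bb]][[c]], W[, , c], bj[c]))
      for (y in seq_len(Lp)) {
        for (x in seq_len(Dp)) {
          v <- vapply(dw, function(m) m[y, x], 1.0)
          mu <- mean(v); vv <- mean((v - mu)^2)
          gn <- refGelu((v - mu) / sqrt(vv + eps) * lng + lnb)
          for (c in seq_len(ch)) nxt[[bb]][[c]][y, x] <- cur[[bb]][[c]][y, x] + gn[c]
        }
      }
    }
    cur <- nxt
  }
  t(vapply(cur, function(s) unlist(lapply(s, as.vector)), numeric(ch * Lp * Dp)))
}

refSoftmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

refHead <- function(X, W1, b1, W2, b2) {
  h <- pmax(sweep(X %*% W1, 2, b1, `+`), 0)
  t(apply(sweep(h %*% W2, 2, b2, `+`), 1, refSoftmax))
}

# full forward pass of the dual-branch network (literal block form),
# mirroring the compiled implementation equation by equation
refForward <- function(p, cfg, eeg, emg) {
  B <- dim(eeg)[3]
  layerW <- function(pre, l) {
    nm <- function(part) p[[sprintf("%s_l%d_%s", pre, l, part)]]
    list(Wq = nm("Wq"), bq = nm("bq"), Wk = nm("Wk"), bk = nm("bk"),
         Wv = nm("Wv"), bv = nm("bv"), Wo = nm("Wo"), bo = nm("bo"),
         W1 = nm("W1"), b1 = nm("b1"), W2 = nm("W2"), b2 = nm("b2"),
         ln1g = nm("ln1g"), ln1b = nm("ln1b"), ln2g = nm("ln2g"), ln2b = nm("ln2b"))
  }
  branch <- function(X, pre) {
    W <- p[[paste0(pre, "_convW")]]
    b <- p[[paste0(pre, "_convb")]]
    lapply(seq_len(B), function(bb) {
      Z <- refConv1d(X[, , bb], W, b)
      if (cfg@useTransformer) {
        Z <- Z + refPosEncoding(nrow(Z), ncol(Z))
        for (l in seq_len(cfg@nLayers)) {
          Z <- refBlock(Z, layerW(pre, l), cfg@nHeads, cfg@standardBlock)
        }
      }
      Z
    })
  }
  Ze <- branch(eeg, "e")
  Zm <- branch(emg, "m")
  fe <- refTrunk(Ze, p, cfg@trunkChannels, cfg@nFusionBlocks)
  fm <- refTrunk(Zm, p, cfg@trunkChannels, cfg@nFusionBlocks)
  probs <- refHead(cbind(fe, fm), p$cls_W1, p$cls_b1, p$cls_W2, p$cls_b2)
  out <- list(probs = probs, fusedEeg = fe, fusedEmg = fm)
  if (!is.null(p$mod_W1)) {
    out$modalProbsEeg <- refHead(fe, p$mod_W1, p$mod_b1, p$mod_W2, p$mod_b2)
    out$modalProbsEmg <- refHead(fm, p$mod_W1, p$mod_b1, p$mod_W2, p$mod_b2)
  }
  out
}

# per-class tally oracle for accuracy / macro F1 from raw label vectors
refTallyMetrics <- function(truth, pred, nClasses = 3L) {
  acc <- mean(truth == pred)
  f1 <- numeric(nClasses)
  for (c in 0:(nClasses - 1L)) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c + 1L] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  list(acc = acc, macroF1 = mean(f1))
}

# small helper: random paired sample set
randomSampleSet <- function(C = 4, L = 16, n = 6, seed = 1) {
  set.seed(seed)
  pairedSampleSet(array(rnorm(C * L * n), c(C, L, n)),
                  array(rnorm(C * L * n), c(C, L, n)),
                  label = rep(0:2, length.out = n),
                  windowIndex = seq_len(n) - 1L)
}

# squared magnitude response (the zero-phase forward-backward amplitude gain)
# of a digital filter at frequency f, by direct polynomial evaluation
refFilterGain <- function(bf, f, fs) {
  z <- exp(-2i * pi * f / fs)
  hb <- sum(bf$b * z^(seq_along(bf$b) - 1))
  ha <- sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(hb / ha)^2
}
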