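# Minimal reverse-mode engine for the convolution/recurrent architectures.
#
# Activations are held either as 4-d arrays (height x time x maps x batch)
# or, after flatten/recurrent layers, as features x batch matrices. All
# heavy lifting is BLAS matrix multiplication via im2col patch extraction;
# convolutions are valid (no padding), pooling acts on the time axis only.
#
# Layer records (built by buildPlan) carry the resolved geometry:
#   conv:    f, h (NA = full height), m, strideH, act
#   gconv:   f, h, m, groupSize — independent filter bank per group of rows
#   maxpool: pw
#   bridge:  f — full-height 1-timestep conv collapsing space to 1 row
#   parallel: branches (list of layer lists), outputs stacked along height
#   flatten, asseq (channels become sequence features), rnn (lstm/blstm),
#   dense (units, act), dropout (rate)

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- im2col ------------------------------------------------------------
#
# Activations are laid out maps-first, (C, H, W, N), so a convolution's
# matmul result (f, Hout, Wout, N) is already in final layout.

# 1-based gather index matrix (patchlen x positions) for one sample
.convIdx <- function(C, H, W, h, m, strideH) {
  Hout <- (H - h) %/% strideH + 1L
  Wout <- W - m + 1L
  if (Hout < 1L || Wout < 1L)
    stop("incompatible shape: conv (", h, "x", m, ") on ", H, "x", W,
         call. = FALSE)
  cc <- rep.int(seq_len(C) - 1L, h * m)
  dh <- rep.int(rep(seq_len(h) - 1L, each = C), m)
  dw <- rep(seq_len(m) - 1L, each = C * h)
  off <- cc + C * (dh + H * dw)
  ho <- rep.int(seq_len(Hout) - 1L, Wout)
  wo <- rep(seq_len(Wout) - 1L, each = Hout)
  base <- C * (ho * strideH + H * wo)
  list(idx = outer(off, base, "+") + 1L, Hout = Hout, Wout = Wout)
}

# X: (C, H, W, N) -> list(out (f, Hout, Wout, N), cache)
.convForward <- function(X, Wmat, b, h, m, strideH, act = "relu") {
  d <- dim(X); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  ci <- .convIdx(C, H, W, h, m, strideH)
  Xm <- X; dim(Xm) <- c(C * H * W, N)
  P <- Xm[as.vector(ci$idx), , drop = FALSE]       # (plen*pos, N)
  dim(P) <- c(nrow(ci$idx), ci$Hout * ci$Wout * N) # cols: ho, wo, n
  Y <- Wmat %*% P + b
  if (act == "relu") { mask <- Y > 0; Y <- Y * mask } else mask <- NULL
  f <- nrow(Wmat)
  dim(Y) <- c(f, ci$Hout, ci$Wout, N)
  list(out = Y,
       cache = list(P = P, mask = mask, ci = ci, dimX = d, act = act))
}

.convBackward <- function(dOut, cache, Wmat, computeInput = TRUE) {
  ci <- cache$ci; d <- cache$dimX
  f <- nrow(Wmat); N <- d[4]
  dY <- dOut
  dim(dY) <- c(f, ci$Hout * ci$Wout * N)
  if (!is.null(cache$mask)) dY <- dY * cache$mask
  dW <- tcrossprod(dY, cache$P)
  db <- rowSums(dY)
  if (!computeInput)
    return(list(dX = NULL, dW = dW, db = db))
  dP <- crossprod(Wmat, dY)                        # (plen, pos*N)
  dim(dP) <- c(length(ci$idx), N)
  grp <- as.vector(ci$idx)
  agg <- rowsum(dP, group = grp)                   # ordered by sorted index
  dX <- matrix(0, d[1] * d[2] * d[3], N)
  dX[as.integer(rownames(agg)), ] <- agg
  dim(dX) <- d
  list(dX = dX, dW = dW, db = db)
}

# ---- layer dispatch ----------------------------------------------------

.initBank <- function(f, plen, seed = NULL) {
  lim <- sqrt(6 / (plen + f))
  list(W = matrix(runif(f * plen, -lim, lim), f, plen), b = numeric(f))
}

# walk layers computing shapes; optionally init params / count weights.
# shape: c(H, W, C) for 4-d stages, c(F) for matrix stages.
.walk <- function(layers, shape, params = NULL, count = FALSE) {
  total <- 0
  shapes <- list(shape)
  for (l in layers) {
    if (l$type == "conv") {
      h <- if (is.na(l$h)) shape[1] else l$h
      Hout <- (shape[1] - h) %/% l$strideH + 1L
      Wout <- shape[2] - l$m + 1L
      if (Hout < 1 || Wout < 1)
        stop("incompatible shape at ", l$id, call. = FALSE)
      plen <- h * l$m * shape[3]
      total <- total + l$f * plen + l$f
      if (!is.null(params)) params[[paste0(l$id, ".bank")]] <- .initBank(l$f, plen)
      shape <- c(Hout, Wout, l$f)
    } else if (l$type == "gconv") {
      if (shape[1] %% l$groupSize != 0)
        stop("incompatible shape at ", l$id, ": height ", shape[1],
             " not divisible by group size ", l$groupSize, call. = FALSE)
      nG <- shape[1] %/% l$groupSize
      hg <- l$groupSize - l$h + 1L
      plen <- l$h * l$m * shape[3]
      total <- total + nG * (l$f * plen + l$f)
      if (!is.null(params))
        for (g in seq_len(nG))
          params[[paste0(l$id, ".g", g)]] <- .initBank(l$f, plen)
      shape <- c(nG * hg, shape[2] - l$m + 1L, l$f)
    } else if (l$type == "bridge") {
      plen <- shape[1] * 1L * shape[3]
      total <- total + l$f * plen + l$f
      if (!is.null(params)) params[[paste0(l$id, ".bank")]] <- .initBank(l$f, plen)
      shape <- c(1L, shape[2], l$f)
    } else if (l$type == "maxpool") {
      Wout <- shape[2] %/% l$pw
      if (Wout < 1) stop("incompatible shape at ", l$id, call. = FALSE)
      shape <- c(shape[1], Wout, shape[3])
    } else if (l$type == "parallel") {
      outs <- lapply(l$branches, function(br) .walk(br, shape, NULL, TRUE))
      bshapes <- lapply(outs, function(o) o$shape)
      if (length(unique(vapply(bshapes, function(s) s[2], 1))) != 1 ||
          length(unique(vapply(bshapes, function(s) s[3], 1))) != 1)
        stop("branch outputs incompatible at ", l$id, call. = FALSE)
      total <- total + sum(vapply(outs, function(o) o$count, 1))
      if (!is.null(params))
        for (bi in seq_along(l$branches))
          params <- .walk(l$branches[[bi]], shape, params)$params
      shape <- c(sum(vapply(bshapes, function(s) s[1], 1)),
                 bshapes[[1]][2], bshapes[[1]][3])
    } else if (l$type == "flatten") {
      shape <- prod(shape)
    } else if (l$type == "asseq") {
      shape <- c(1L, shape[2], shape[1])     # channels become features
    } else if (l$type == "rnn") {
      F <- shape[3]; U <- l$units
      per <- F * 4 * U + U * 4 * U + 4 * U
      ndir <- if (l$kind == "blstm") 2L else 1L
      total <- total + ndir * per
      if (!is.null(params)) {
        dirs <- if (ndir == 2L) c("fwd", "bwd") else "fwd"
        for (dd in dirs) {
          lim <- sqrt(6 / (F + 4 * U)); limh <- sqrt(6 / (U + 4 * U))
          b <- numeric(4 * U); b[(U + 1):(2 * U)] <- 1   # forget-gate bias
          params[[paste0(l$id, ".", dd)]] <- list(
            Wx = matrix(runif(F * 4 * U, -lim, lim), F, 4 * U),
            Wh = matrix(runif(U * 4 * U, -limh, limh), U, 4 * U),
            b = b)
        }
      }
      shape <- ndir * U
    } else if (l$type == "dense") {
      Fin <- shape[1]
      total <- total + l$units * Fin + l$units
      if (!is.null(params)) {
        lim <- sqrt(6 / (Fin + l$units))
        params[[paste0(l$id, ".bank")]] <- list(
          W = matrix(runif(l$units * Fin, -lim, lim), l$units, Fin),
          b = numeric(l$units))
      }
      shape <- l$units
    } else if (l$type == "dropout") {
      # shape unchanged
    } else stop("unknown layer type: ", l$type, call. = FALSE)
    shapes[[length(shapes) + 1L]] <- shape
  }
  list(shape = shape, count = if (count) total else NULL,
       params = params, shapes = shapes)
}

# ---- forward / backward ------------------------------------------------

.forwardLayers <- function(layers, X, params, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type %in% c("conv", "bridge")) {
      bk <- params[[paste0(l$id, ".bank")]]
      h <- if (l$type == "bridge") dim(X)[2] else if (is.na(l$h)) dim(X)[2] else l$h
      m <- if (l$type == "bridge") 1L else l$m
      sH <- if (l$type == "bridge") 1L else l$strideH
      r <- .convForward(X, bk$W, bk$b, h, m, sH)
      caches[[i]] <- r$cache; X <- r$out
    } else if (l$type == "gconv") {
      nG <- dim(X)[2] %/% l$groupSize
      outs <- vector("list", nG); gc <- vector("list", nG)
      for (g in seq_len(nG)) {
        rows <- ((g - 1L) * l$groupSize + 1L):(g * l$groupSize)
        bk <- params[[paste0(l$id, ".g", g)]]
        r <- .convForward(X[, rows, , , drop = FALSE], bk$W, bk$b, l$h, l$m, 1L)
        outs[[g]] <- r$out; gc[[g]] <- r$cache
      }
      hg <- dim(outs[[1]])[2]
      Y <- array(0, c(dim(outs[[1]])[1], nG * hg, dim(outs[[1]])[3], dim(X)[4]))
      for (g in seq_len(nG))
        Y[, ((g - 1L) * hg + 1L):(g * hg), , ] <- outs[[g]]
      caches[[i]] <- list(gc = gc, hg = hg, groupSize = l$groupSize, nG = nG)
      X <- Y
    } else if (l$type == "maxpool") {
      d <- dim(X); Wout <- d[3] %/% l$pw
      Xt <- X[, , seq_len(l$pw * Wout), , drop = FALSE]
      dim(Xt) <- c(d[1], d[2], l$pw, Wout, d[4])
      out <- Xt[, , 1L, , , drop = FALSE]
      dim(out) <- c(d[1], d[2], Wout, d[4])
      if (l$pw > 1) for (k in 2:l$pw) {
        s <- Xt[, , k, , , drop = FALSE]; dim(s) <- dim(out)
        out <- pmax(out, s)
      }
      caches[[i]] <- list(Xt = Xt, out = out, dimX = d, Wout = Wout)
      X <- out
    } else if (l$type == "parallel") {
      bouts <- vector("list", length(l$branches))
      bcaches <- vector("list", length(l$branches))
      for (bi in seq_along(l$branches)) {
        r <- .forwardLayers(l$branches[[bi]], X, params, training)
        bouts[[bi]] <- r$out; bcaches[[bi]] <- r$caches
      }
      hs <- vapply(bouts, function(o) dim(o)[2], 1L)
      Y <- array(0, c(dim(bouts[[1]])[1], sum(hs), dim(bouts[[1]])[3], dim(X)[4]))
      at <- 0L
      for (bi in seq_along(bouts)) {
        Y[, (at + 1L):(at + hs[bi]), , ] <- bouts[[bi]]
        at <- at + hs[bi]
      }
      caches[[i]] <- list(bcaches = bcaches, hs = hs, dimX = dim(X))
      X <- Y
    } else if (l$type == "flatten") {
      d <- dim(X); caches[[i]] <- list(dimX = d)
      dim(X) <- c(prod(d[1:3]), d[4])
    } else if (l$type == "asseq") {
      caches[[i]] <- list(dimX = dim(X))
      X <- aperm(X, c(2, 1, 3, 4))       # (1,H,W,N) -> (H,1,W,N): rows -> maps
    } else if (l$type == "rnn") {
      d <- dim(X)                       # (F, 1, T, N)
      Xs <- aperm(X, c(4, 1, 3, 2)); dim(Xs) <- c(d[4], d[1], d[3])  # (N,F,T)
      fwd <- .lstmForward(Xs, params[[paste0(l$id, ".fwd")]])
      if (l$kind == "blstm") {
        Xr <- Xs[, , rev(seq_len(d[3])), drop = FALSE]
        bwd <- .lstmForward(Xr, params[[paste0(l$id, ".bwd")]])
        H <- cbind(fwd$h, bwd$h)
      } else { bwd <- NULL; H <- fwd$h }
      caches[[i]] <- list(fwd = fwd, bwd = bwd, dimX = d)
      X <- t(H)                         # features x N
    } else if (l$type == "dense") {
      bk <- params[[paste0(l$id, ".bank")]]
      Y <- bk$W %*% X + bk$b
      if (l$act == "relu") { mask <- Y > 0; Y <- Y * mask } else mask <- NULL
      caches[[i]] <- list(Xin = X, mask = mask)
      X <- Y
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        mask <- (matrix(runif(length(X)), nrow(X)) >= l$rate) / (1 - l$rate)
        caches[[i]] <- list(mask = mask)
        X <- X * mask
      } else caches[[i]] <- list(mask = NULL)
    }
  }
  list(out = X, caches = caches)
}

.backwardLayers <- function(layers, caches, dOut, params, needInput = FALSE) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]; ca <- caches[[i]]
    atInput <- (i == 1L) && !needInput   # input gradients unused upstream
    if (l$type %in% c("conv", "bridge")) {
      bk <- params[[paste0(l$id, ".bank")]]
      r <- .convBackward(dOut, ca, bk$W, computeInput = !atInput)
      grads[[paste0(l$id, ".bank")]] <- list(W = r$dW, b = r$db)
      dOut <- r$dX
    } else if (l$type == "gconv") {
      d <- NULL
      for (g in seq_len(ca$nG)) {
        rows <- ((g - 1L) * ca$hg + 1L):(g * ca$hg)
        bk <- params[[paste0(l$id, ".g", g)]]
        r <- .convBackward(dOut[, rows, , , drop = FALSE], ca$gc[[g]], bk$W,
                           computeInput = !atInput)
        grads[[paste0(l$id, ".g", g)]] <- list(W = r$dW, b = r$db)
        if (!atInput) {
          if (is.null(d)) {
            dimIn <- ca$gc[[g]]$dimX
            d <- array(0, c(dimIn[1], ca$nG * ca$groupSize, dimIn[3], dimIn[4]))
          }
          inRows <- ((g - 1L) * ca$groupSize + 1L):(g * ca$groupSize)
          d[, inRows, , ] <- r$dX
        }
      }
      dOut <- d
    } else if (l$type == "maxpool") {
      d <- ca$dimX
      dX <- array(0, d)
      dXt <- array(0, c(d[1], d[2], l$pw, ca$Wout, d[4]))
      rem <- dOut                    # gradient routed to first max; ties safe
      for (k in seq_len(l$pw)) {
        s <- ca$Xt[, , k, , , drop = FALSE]; dim(s) <- dim(ca$out)
        take <- rem * (s == ca$out)
        dXt[, , k, , ] <- take
        rem <- rem - take
      }
      dim(dXt) <- c(d[1], d[2], l$pw * ca$Wout, d[4])
      dX[, , seq_len(l$pw * ca$Wout), ] <- dXt
      dOut <- dX
    } else if (l$type == "parallel") {
      dIn <- if (atInput) NULL else array(0, ca$dimX)
      at <- 0L
      for (bi in seq_along(l$branches)) {
        r <- .backwardLayers(l$branches[[bi]], ca$bcaches[[bi]],
                             dOut[, (at + 1L):(at + ca$hs[bi]), , , drop = FALSE],
                             params, needInput = !atInput)
        grads <- c(grads, r$grads)
        if (!atInput) dIn <- dIn + r$dX
        at <- at + ca$hs[bi]
      }
      dOut <- dIn
    } else if (l$type == "flatten") {
      dim(dOut) <- ca$dimX
    } else if (l$type == "asseq") {
      dOut <- aperm(dOut, c(2, 1, 3, 4))
    } else if (l$type == "rnn") {
      d <- ca$dimX                       # (F, 1, T, N)
      U <- l$units
      dH <- t(dOut)                      # (N, ndir*U)
      pf <- params[[paste0(l$id, ".fwd")]]
      rf <- .lstmBackward(dH[, seq_len(U), drop = FALSE], ca$fwd, pf)
      grads[[paste0(l$id, ".fwd")]] <- rf$grads
      dXs <- rf$dXs
      if (l$kind == "blstm") {
        pb <- params[[paste0(l$id, ".bwd")]]
        rb <- .lstmBackward(dH[, U + seq_len(U), drop = FALSE], ca$bwd, pb)
        grads[[paste0(l$id, ".bwd")]] <- rb$grads
        dXs <- dXs + rb$dXs[, , rev(seq_len(d[3])), drop = FALSE]
      }
      dX <- aperm(dXs, c(2, 3, 1))       # (N,F,T) -> (F,T,N)
      dim(dX) <- d                       # (F,1,T,N): same linear order
      dOut <- dX
    } else if (l$type == "dense") {
      bk <- params[[paste0(l$id, ".bank")]]
      dY <- dOut
      if (!is.null(ca$mask)) dY <- dY * ca$mask
      grads[[paste0(l$id, ".bank")]] <- list(W = tcrossprod(dY, ca$Xin),
                                             b = rowSums(dY))
      dOut <- crossprod(bk$W, dY)
    } else if (l$type == "dropout") {
      if (!is.null(ca$mask)) dOut <- dOut * ca$mask
    }
  }
  list(dX = dOut, grads = grads)
}

# ---- LSTM --------------------------------------------------------------

.lstmForward <- function(Xs, p) {        # Xs: (N, F, T)
  N <- dim(Xs)[1]; T <- dim(Xs)[3]
  U <- nrow(p$Wh)
  h <- matrix(0, N, U); cc <- matrix(0, N, U)
  steps <- vector("list", T)
  bmat <- matrix(p$b, N, 4 * U, byrow = TRUE)
  iU <- seq_len(U)
  for (t in seq_len(T)) {
    Xt <- matrix(Xs[, , t], N)
    z <- Xt %*% p$Wx + h %*% p$Wh + bmat
    ig <- .sigmoid(z[, iU, drop = FALSE])
    fg <- .sigmoid(z[, U + iU, drop = FALSE])
    og <- .sigmoid(z[, 2 * U + iU, drop = FALSE])
    gg <- tanh(z[, 3 * U + iU, drop = FALSE])
    cNew <- fg * cc + ig * gg
    tc <- tanh(cNew)
    steps[[t]] <- list(Xt = Xt, hPrev = h, cPrev = cc,
                       i = ig, f = fg, o = og, g = gg, tc = tc)
    h <- og * tc; cc <- cNew
  }
  list(h = h, steps = steps, N = N, T = T, U = U, F = dim(Xs)[2])
}

.lstmBackward <- function(dH, fw, p) {
  U <- fw$U; T <- fw$T; N <- fw$N; F <- fw$F
  dWx <- matrix(0, F, 4 * U); dWh <- matrix(0, U, 4 * U); db <- numeric(4 * U)
  dc <- matrix(0, N, U)
  dXs <- array(0, c(N, F, T))
  for (t in rev(seq_len(T))) {
    s <- fw$steps[[t]]
    do <- dH * s$tc
    dct <- dc + dH * s$o * (1 - s$tc^2)
    di <- dct * s$g; dg <- dct * s$i; df <- dct * s$cPrev
    dz <- cbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                do * s$o * (1 - s$o), dg * (1 - s$g^2))
    dWx <- dWx + crossprod(s$Xt, dz)
    dWh <- dWh + crossprod(s$hPrev, dz)
    db <- db + colSums(dz)
    dXs[, , t] <- dz %*% t(p$Wx)
    dH <- dz %*% t(p$Wh)
    dc <- dct * s$f
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dXs = dXs)
}

# ---- loss & optimizer --------------------------------------------------

# logits (K, N), y integer class index 1..K
.softmaxCE <- function(logits, y) {
  z <- sweep(logits, 2L, apply(logits, 2L, max))
  ez <- exp(z)
  P <- sweep(ez, 2L, colSums(ez), "/")
  N <- ncol(logits)
  picked <- P[cbind(y, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dZ <- P
  dZ[cbind(y, seq_len(N))] <- dZ[cbind(y, seq_len(N))] - 1
  list(loss = loss, dZ = dZ / N, P = P)
}

.adamInit <- function(params) {
  flat <- .flattenParams(params)
  list(m = lapply(flat, function(x) x * 0), v = lapply(flat, function(x) x * 0),
       t = 0L)
}

.flattenParams <- function(params) {
  out <- list()
  for (nm in names(params))
    for (part in names(params[[nm]]))
      out[[paste0(nm, "::", part)]] <- params[[nm]][[part]]
  out
}

.unflattenInto <- function(params, flat) {
  for (key in names(flat)) {
    sp <- strsplit(key, "::", fixed = TRUE)[[1]]
    params[[sp[1]]][[sp[2]]] <- flat[[key]]
  }
  params
}

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  flatP <- .flattenParams(params)
  flatG <- .flattenParams(grads)
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t; b2t <- 1 - beta2^state$t
  for (key in names(flatG)) {
    g <- flatG[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / b1t
    vhat <- state$v[[key]] / b2t
    flatP[[key]] <- flatP[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = .unflattenInto(params, flatP), state = state)
}
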