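# Minimal 1-D convolutional network core: forward, backprop, Adam.
# Activations are (batch, time, channel) arrays; parameters live in a flat
# named list so the optimizer is generic. The im2col/col2im and pooling
# index shuffles are in C++ (src/conv1d.cpp); matrix products use BLAS.

# Convolution weights are stored as a (k * Cin) x Cout matrix whose rows are
# ordered channel-fastest within each kernel offset, matching the im2col
# column layout, so one matrix product implements the whole convolution.
conv1d_fwd <- function(x, W, b, pad, k) {
  d <- dim(x); B <- d[1L]; L <- d[2L]; Cin <- d[3L]
  Cout <- ncol(W)
  Lo <- L + 2L * pad - k + 1L
  Xc <- cpp_im2col(x, B, L, Cin, pad, k)
  out <- Xc %*% W
  out <- out + matrix(b, B * Lo, Cout, byrow = TRUE)
  dim(out) <- c(B, Lo, Cout)
  list(out = out, Xc = Xc, B = B, L = L, Cin = Cin)
}

conv1d_bwd <- function(dout, cache, W, pad, k) {
  d <- dim(dout); B <- d[1L]; Lo <- d[2L]; Cout <- d[3L]
  dout_m <- dout; dim(dout_m) <- c(B * Lo, Cout)
  dW <- crossprod(cache$Xc, dout_m)
  dXc <- dout_m %*% t(W)
  dx <- cpp_col2im(dXc, B, cache$L, cache$Cin, pad, k)
  list(dx = dx, dW = dW, db = colSums(dout_m))
}

poolk_fwd <- function(x, w) {
  d <- dim(x)
  cpp_poolk(x, d[1L], d[2L], d[3L], w)
}

poolk_bwd <- function(dout, L_in, w) {
  d <- dim(dout)
  cpp_poolk_bwd(dout, d[1L], L_in, d[3L], w)
}

# adaptive average pool to nb contiguous time bins
apool_fwd <- function(x, nb) {
  d <- dim(x); B <- d[1L]; L <- d[2L]; C <- d[3L]
  bnd <- floor(L * (0:nb) / nb)
  out <- array(0, c(B, nb, C))
  for (j in seq_len(nb)) {
    idx <- (bnd[j] + 1L):bnd[j + 1L]
    seg <- x[, idx, , drop = FALSE]
    out[, j, ] <- colSums(aperm(seg, c(2L, 1L, 3L))) / length(idx)
  }
  out
}

apool_bwd <- function(dout, L_in) {
  d <- dim(dout); B <- d[1L]; nb <- d[2L]; C <- d[3L]
  bnd <- floor(L_in * (0:nb) / nb)
  dx <- array(0, c(B, L_in, C))
  for (j in seq_len(nb)) {
    idx <- (bnd[j] + 1L):bnd[j + 1L]
    g <- dout[, j, , drop = FALSE] / length(idx)   # (B, 1, C)
    dx[, idx, ] <- aperm(array(g, c(B, C, length(idx))), c(1L, 3L, 2L))
  }
  dx
}

# architecture descriptor: branches (named by modality) each with an input
# decimation factor (front-end average pooling matched to the modality's
# bandwidth), conv channel widths, shared kernel/padding, pool bins, head
# layer sizes
make_arch <- function(modalities, input_length, kernel_size, padding,
                      channels, n_pool_bins, head_layers, embedding_dim,
                      decimation = NULL) {
  decim <- vapply(modalities, function(m)
    as.integer(decimation[m] %||% 1L), 0L)
  decim[is.na(decim)] <- 1L
  names(decim) <- modalities
  feat_per_branch <- n_pool_bins * channels[length(channels)]
  head_dims <- c(feat_per_branch * length(modalities), head_layers, embedding_dim)
  list(modalities = modalities, input_length = input_length,
       kernel_size = kernel_size, padding = padding, channels = channels,
       n_pool_bins = n_pool_bins, decimation = decim, head_dims = head_dims)
}

init_params <- function(arch, seed) {
  with_seed(seed, {
    params <- list()
    k <- arch$kernel_size
    for (m in arch$modalities) {
      cin <- 1L
      for (i in seq_along(arch$channels)) {
        cout <- arch$channels[i]
        sd <- sqrt(2 / (k * cin))
        params[[paste0(m, ".conv", i, ".W")]] <-
          matrix(stats::rnorm(k * cin * cout, 0, sd), k * cin, cout)
        params[[paste0(m, ".conv", i, ".b")]] <- numeric(cout)
        cin <- cout
      }
    }
    hd <- arch$head_dims
    for (i in seq_len(length(hd) - 1L)) {
      sd <- sqrt(2 / hd[i])
      params[[paste0("head", i, ".W")]] <-
        matrix(stats::rnorm(hd[i] * hd[i + 1L], 0, sd), hd[i], hd[i + 1L])
      params[[paste0("head", i, ".b")]] <- numeric(hd[i + 1L])
    }
    params
  })
}

# inputs: named list modality -> (B x input_length) matrix, already z-scored
net_forward <- function(arch, params, inputs, want_cache = FALSE) {
  B <- nrow(inputs[[1L]])
  feats <- list()
  cache <- list(branch = list())
  for (m in arch$modalities) {
    x <- array(inputs[[m]], c(B, arch$input_length, 1L))
    f <- arch$decimation[[m]]
    if (f > 1L) x <- poolk_fwd(x, f)
    L_decim <- dim(x)[2L]
    bc <- list()
    for (i in seq_along(arch$channels)) {
      cv <- conv1d_fwd(x, params[[paste0(m, ".conv", i, ".W")]],
                       params[[paste0(m, ".conv", i, ".b")]], arch$padding,
                       arch$kernel_size)
      a <- pmax(cv$out, 0)
      p <- poolk_fwd(a, 2L)
      if (want_cache) {
        cv$out <- NULL
        bc[[i]] <- list(conv = cv, mask = a > 0, L_conv = dim(a)[2L])
      }
      x <- p
    }
    L_last <- dim(x)[2L]
    pooled <- apool_fwd(x, arch$n_pool_bins)
    fm <- pooled; dim(fm) <- c(B, arch$n_pool_bins * dim(x)[3L])
    feats[[m]] <- fm
    if (want_cache) {
      cache$branch[[m]] <- list(blocks = bc, L_last = L_last,
                                L_decim = L_decim)
    }
  }
  h <- do.call(cbind, feats)
  nh <- length(arch$head_dims) - 1L
  hs <- list(h)
  for (i in seq_len(nh)) {
    z <- h %*% params[[paste0("head", i, ".W")]]
    z <- sweep(z, 2L, params[[paste0("head", i, ".b")]], "+")
    h <- if (i < nh) pmax(z, 0) else z
    hs[[i + 1L]] <- h
  }
  nrm <- sqrt(rowSums(h * h))
  nrm[nrm < 1e-12] <- 1e-12
  emb <- h / nrm
  if (!want_cache) return(list(emb = emb))
  cache$hs <- hs
  cache$nrm <- nrm
  cache$emb <- emb
  list(emb = emb, cache = cache)
}

net_backward <- function(arch, params, cache, demb) {
  grads <- list()
  # through L2 normalization
  emb <- cache$emb
  dz <- (demb - emb * rowSums(demb * emb)) / cache$nrm
  nh <- length(arch$head_dims) - 1L
  dh <- dz
  for (i in rev(seq_len(nh))) {
    if (i < nh) dh <- dh * (cache$hs[[i + 1L]] > 0)
    h_in <- cache$hs[[i]]
    grads[[paste0("head", i, ".W")]] <- crossprod(h_in, dh)
    grads[[paste0("head", i, ".b")]] <- colSums(dh)
    dh <- dh %*% t(params[[paste0("head", i, ".W")]])
  }
  # split the feature gradient across branches
  nmod <- length(arch$modalities)
  fpb <- ncol(dh) / nmod
  for (mi in seq_along(arch$modalities)) {
    m <- arch$modalities[mi]
    df <- dh[, ((mi - 1L) * fpb + 1L):(mi * fpb), drop = FALSE]
    bc <- cache$branch[[m]]
    C_last <- arch$channels[length(arch$channels)]
    dpool <- df; dim(dpool) <- c(nrow(df), arch$n_pool_bins, C_last)
    dx <- apool_bwd(dpool, bc$L_last)
    for (i in rev(seq_along(arch$channels))) {
      blk <- bc$blocks[[i]]
      da <- poolk_bwd(dx, blk$L_conv, 2L)
      dconv <- da * blk$mask
      bw <- conv1d_bwd(dconv, blk$conv, params[[paste0(m, ".conv", i, ".W")]],
                       arch$padding, arch$kernel_size)
      grads[[paste0(m, ".conv", i, ".W")]] <- bw$dW
      grads[[paste0(m, ".conv", i, ".b")]] <- bw$db
      dx <- bw$dx
    }
    # input-gradient through the front-end decimation is not needed
  }
  grads
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    dim(upd) <- dim(params[[nm]])
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}
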