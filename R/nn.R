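# Minimal convolutional network with analytic gradients.
#
# The patient-bag model needs a trainable patch embedder; this file
# implements the "desk"-scale backbone -- a 2x2 average-pool stem followed
# by three conv blocks (3x3 kernels, ReLU, 2x2 average pooling), global
# average pooling and a linear projection to the embedding -- plus the
# two-layer fully connected head, forward and backward, in base R matrix
# algebra. Convolutions run as batched im2col gathers over the whole patch
# batch, so each training step is a handful of BLAS calls; the backward
# scatter-add uses a precomputed sort-and-segment-sum, not hashing.

# Index tables for a stride-1, pad-1, 3x3 convolution over an H x W x Cin
# input, followed by 2x2 average pooling.
make_conv_shape <- function(H, W, Cin, Cout) {
  Hp <- H + 2L; Wp <- W + 2L
  HW <- H * W
  r <- rep(seq_len(H), W)          # row index, fastest (column-major)
  cc <- rep(seq_len(W), each = H)  # column index
  idx <- matrix(0L, HW, 9L * Cin)
  k <- 0L
  for (ch in seq_len(Cin)) for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1L
    idx[, k] <- (ch - 1L) * Hp * Wp + (cc + dc - 1L) * Hp + (r + dr)
  }
  center <- integer(HW * Cin)
  for (ch in seq_len(Cin))
    center[(ch - 1L) * HW + seq_len(HW)] <-
      (ch - 1L) * Hp * Wp + cc * Hp + (r + 1L)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  i <- rep(seq_len(Ho), Wo); j <- rep(seq_len(Wo), each = Ho)
  # col2im scatter-add as a sparse 0/1 matrix: one sparse matmul
  # accumulates the whole batch
  iv <- as.vector(idx)
  scatter <- Matrix::sparseMatrix(i = iv, j = seq_along(iv), x = 1,
                                  dims = c(Hp * Wp * Cin, length(iv)))
  list(H = H, W = W, HW = HW, Cin = Cin, Cout = Cout,
       npad = Hp * Wp * Cin, idx = idx, center = center,
       scatter = scatter,
       p1 = (2L * j - 2L) * H + (2L * i - 1L),
       p2 = (2L * j - 2L) * H + 2L * i,
       p3 = (2L * j - 1L) * H + (2L * i - 1L),
       p4 = (2L * j - 1L) * H + 2L * i)
}

# Batch-expanded index tables for B patches, cached per (layer, B).
get_batch_tables <- function(model, l, B) {
  key <- paste0(l, ":", B)
  env <- model$tab_env
  if (!is.null(env[[key]])) return(env[[key]])
  sh <- model$shapes[[l]]
  HWo <- sh$HW %/% 4L
  off_hw <- rep((seq_len(B) - 1L) * sh$HW, each = HWo)
  # PERM rearranges the (B*HW) x 9Cin gradient into one column per patch
  # (canonical im2col order) for the sparse scatter matmul; only needed
  # below the top layer
  PERM <- NULL
  if (l > 1) {
    nc <- 9L * sh$Cin
    i_ <- rep(seq_len(sh$HW), nc)
    j_ <- rep(seq_len(nc), each = sh$HW)
    perm1 <- (j_ - 1L) * (B * sh$HW) + i_   # patch-1 element positions
    PERM <- matrix(0L, sh$HW * nc, B)
    for (b in seq_len(B)) PERM[, b] <- perm1 + (b - 1L) * sh$HW
  }
  # full linear indices (rows x all columns) for the 2x2 pool, so pooling
  # and unpooling are single-vector gathers/assignments
  nr <- B * sh$HW
  col_off <- rep((seq_len(sh$Cout) - 1L) * nr, each = B * HWo)
  full <- function(p) col_off + rep(off_hw + p, sh$Cout)
  tabs <- list(
    IDXB = sh$idx[rep(seq_len(sh$HW), B), , drop = FALSE] +
      rep((seq_len(B) - 1L) * sh$npad, each = sh$HW),
    PERM = PERM,
    P1F = full(sh$p1), P2F = full(sh$p2),
    P3F = full(sh$p3), P4F = full(sh$p4))
  env[[key]] <- tabs
  tabs
}

he_init <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
}

#' Construct a patient-bag risk model
#'
#' The backbone maps an `input_px` x `input_px` RGB patch to an
#' `embed_dim`-vector: a 2x2 average-pool stem (the usual early
#' downsampling of residual image backbones), three conv blocks (3x3
#' kernels, ReLU, 2x2 average pooling), global average pooling, and a
#' linear projection. The head is a two-layer fully connected network
#' (`embed_dim` -> `head_hidden` -> `output_size`) with a ReLU between the
#' layers. `output_size = 1` yields an unbounded survival risk score;
#' `output_size = 2` yields class logits for the binary biomarker task.
#'
#' @param input_px patch side length; must be a multiple of `8 * stem_pool`.
#' @param output_size 1 (survival) or 2 (binary classification).
#' @param embed_dim patch embedding dimension (512 by default).
#' @param channels conv block output channels, length 3.
#' @param head_hidden hidden width of the head (128 by default).
#' @param stem_pool input downsampling factor of the stem (1 disables it).
#' @param seed seed for weight initialization (He normal).
#' @param custom_backbone optional function(patch_array) -> embedding
#'   vector, replacing the conv backbone (used for stubbed oracles).
#' @return object of class `risk_model`.
#' @export
risk_model <- function(input_px = 64, output_size = 1, embed_dim = 512,
                       channels = c(8, 16, 32), head_hidden = 128,
                       stem_pool = 2, seed = 1, custom_backbone = NULL) {
  if (!output_size %in% c(1, 2))
    stop("output_size must be 1 (survival) or 2 (binary)", call. = FALSE)
  if (!stem_pool %in% c(1, 2, 4))
    stop("stem_pool must be 1, 2 or 4", call. = FALSE)
  model <- list(input_px = input_px, output_size = output_size,
                embed_dim = embed_dim, channels = channels,
                head_hidden = head_hidden, stem_pool = stem_pool,
                custom_backbone = custom_backbone)
  if (is.null(custom_backbone)) {
    if (input_px %% (8 * stem_pool) != 0 || input_px < 8 * stem_pool)
      stop("input_px must be a positive multiple of ", 8 * stem_pool,
           call. = FALSE)
    stopifnot(length(channels) == 3)
  }
  with_seed(seed, {
    params <- list()
    if (is.null(custom_backbone)) {
      px0 <- input_px %/% stem_pool
      cin <- c(3, channels[1], channels[2])
      shapes <- list()
      for (l in 1:3) {
        h <- as.integer(px0 / 2^(l - 1))
        shapes[[l]] <- make_conv_shape(h, h, as.integer(cin[l]),
                                       as.integer(channels[l]))
        params[[paste0("conv", l, ".W")]] <- he_init(9 * cin[l], channels[l])
        params[[paste0("conv", l, ".b")]] <- numeric(channels[l])
      }
      model$shapes <- shapes
      params[["proj.W"]] <- he_init(channels[3], embed_dim)
      params[["proj.b"]] <- numeric(embed_dim)
    }
    params[["head1.W"]] <- he_init(embed_dim, head_hidden)
    params[["head1.b"]] <- numeric(head_hidden)
    params[["head2.W"]] <- he_init(head_hidden, output_size)
    params[["head2.b"]] <- numeric(output_size)
    model$params <- params
  })
  model$lr_group <- ifelse(grepl("^head", names(model$params)),
                           "head", "backbone")
  names(model$lr_group) <- names(model$params)
  model$tab_env <- new.env(parent = emptyenv())
  class(model) <- "risk_model"
  model
}

# Average-pool the whole patch batch (B x px x px x 3) down by stem_pool
# (a power of 2), one 2x2 halving at a time.
stem_downsample <- function(patches, stem_pool) {
  while (stem_pool > 1) {
    px <- dim(patches)[2]
    o <- seq(1, px, by = 2); e <- seq(2, px, by = 2)
    patches <- (patches[, o, o, , drop = FALSE] +
                patches[, e, o, , drop = FALSE] +
                patches[, o, e, , drop = FALSE] +
                patches[, e, e, , drop = FALSE]) / 4
    stem_pool <- stem_pool / 2
  }
  patches
}

# Forward a stack of patches (array B x px x px x 3, 0-255) through the
# backbone. Returns B x embed_dim embeddings and optionally the batched
# caches for the backward pass.
backbone_forward <- function(model, patches, keep_cache = FALSE) {
  B <- dim(patches)[1]
  if (!is.null(model$custom_backbone)) {
    emb <- t(vapply(seq_len(B),
                    function(i) model$custom_backbone(patches[i, , , ]),
                    numeric(model$embed_dim)))
    return(list(E = emb, cache = NULL))
  }
  p <- model$params
  down <- stem_downsample(patches, model$stem_pool) / 255 - 0.5
  px0 <- dim(down)[2]
  # xb: one column per patch, rows ordered pixel-within-channel
  xb <- matrix(aperm(down, c(2, 3, 4, 1)), px0 * px0 * 3, B)
  caches <- if (keep_cache) vector("list", 3) else NULL
  for (l in 1:3) {
    sh <- model$shapes[[l]]
    tabs <- get_batch_tables(model, l, B)
    xpad <- matrix(0, sh$npad, B)
    xpad[sh$center, ] <- xb
    xcol <- xpad[tabs$IDXB]
    dim(xcol) <- c(B * sh$HW, 9L * sh$Cin)
    y <- xcol %*% p[[paste0("conv", l, ".W")]]
    y <- y + rep(p[[paste0("conv", l, ".b")]], each = nrow(y))
    mask <- y > 0
    a <- y * mask
    HWo <- sh$HW %/% 4L
    pooled <- (a[tabs$P1F] + a[tabs$P2F] + a[tabs$P3F] + a[tabs$P4F]) * 0.25
    dim(pooled) <- c(HWo, B, sh$Cout)
    if (keep_cache) caches[[l]] <- list(xcol = xcol, mask = mask)
    xb <- aperm(pooled, c(1, 3, 2))
    dim(xb) <- c(HWo * sh$Cout, B)
  }
  hw3 <- (px0 %/% 8L)^2
  c3 <- model$channels[3]
  gap <- t(matrix(colMeans(matrix(xb, hw3, c3 * B)), c3, B))  # B x C3
  E <- gap %*% p[["proj.W"]] + rep(p[["proj.b"]], each = B)
  list(E = E, cache = if (keep_cache) list(convs = caches, gap = gap,
                                           B = B) else NULL)
}

# col2im scatter-add for the whole batch: rearrange the gradient to one
# column per patch and multiply by the sparse scatter matrix. Returns the
# gradient w.r.t. the layer input, one column per patch.
conv_input_grad <- function(dxcol, sh, tabs, B) {
  v <- dxcol[tabs$PERM]
  dim(v) <- dim(tabs$PERM)
  dxpad <- as.matrix(sh$scatter %*% v)
  dxpad[sh$center, , drop = FALSE]
}

# Backward through the backbone; dE is B x embed_dim. Returns parameter
# gradients summed over the batch.
backbone_backward <- function(model, cache, dE) {
  p <- model$params
  B <- cache$B
  g <- list()
  g[["proj.W"]] <- crossprod(cache$gap, dE)
  g[["proj.b"]] <- colSums(dE)
  dgap <- dE %*% t(p[["proj.W"]])            # B x C3
  px0 <- model$input_px %/% model$stem_pool
  hw3 <- (px0 %/% 8L)^2
  dpooled <- dgap[rep(seq_len(B), each = hw3), , drop = FALSE] / hw3
  for (l in 3:1) {
    sh <- model$shapes[[l]]
    tabs <- get_batch_tables(model, l, B)
    cc <- cache$convs[[l]]
    da <- matrix(0, B * sh$HW, sh$Cout)
    d4 <- as.vector(dpooled) * 0.25
    da[tabs$P1F] <- d4; da[tabs$P2F] <- d4
    da[tabs$P3F] <- d4; da[tabs$P4F] <- d4
    dy <- da * cc$mask
    g[[paste0("conv", l, ".W")]] <- crossprod(cc$xcol, dy)
    g[[paste0("conv", l, ".b")]] <- colSums(dy)
    if (l > 1) {
      dxcol <- dy %*% t(p[[paste0("conv", l, ".W")]])
      dxb <- conv_input_grad(dxcol, sh, tabs, B)
      # reshape (HW*Cin, B) columns into pooled-row order (B*HW) x Cin
      dpooled <- matrix(aperm(array(dxb, c(sh$HW, sh$Cin, B)), c(1, 3, 2)),
                        B * sh$HW, sh$Cin)
    }
  }
  g
}

head_forward <- function(model, P) {
  p <- model$params
  h1 <- P %*% p[["head1.W"]] + rep(p[["head1.b"]], each = nrow(P))
  mask <- h1 > 0
  a1 <- h1 * mask
  s <- a1 %*% p[["head2.W"]] + rep(p[["head2.b"]], each = nrow(P))
  list(scores = s, a1 = a1, mask = mask, P = P)
}

head_backward <- function(model, cache, dS) {
  p <- model$params
  g <- list()
  g[["head2.W"]] <- crossprod(cache$a1, dS)
  g[["head2.b"]] <- colSums(dS)
  dh1 <- (dS %*% t(p[["head2.W"]])) * cache$mask
  g[["head1.W"]] <- crossprod(cache$P, dh1)
  g[["head1.b"]] <- colSums(dh1)
  g$dP <- dh1 %*% t(p[["head1.W"]])
  g
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr_by_group, groups, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    if (is.null(params[[nm]])) next
    lr <- lr_by_group[[groups[[nm]]]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * grads[[nm]]
    st$v <- beta2 * st$v + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

cosine_lr <- function(lr0, step, max_steps) {
  lr0 * 0.5 * (1 + cos(pi * (step - 1) / max(1, max_steps)))
}
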