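## The encoder-decoder segmentation network. Heavy numerics run in
## single-precision C++ (im2col + GEMM); this file owns parameter
## initialisation, the forward/backward graph and the user-facing model
## surface. Feature maps travel between ops as external pointers to
## (channels x batch*H*W) float matrices, so nothing is copied back to R
## until the softmax output.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# ---- parameter initialisation ----------------------------------------------

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

mat_init <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)

add_conv3 <- function(w, name, M, N) {
  w[[paste0(name, "_W")]] <- mat_init(N, 9L * M, sqrt(2 / (9 * M)))
  w[[paste0(name, "_b")]] <- matrix(0, N, 1)
  w
}
add_conv1 <- function(w, name, M, N) {
  w[[paste0(name, "_W")]] <- mat_init(N, M, sqrt(2 / M))
  w[[paste0(name, "_b")]] <- matrix(0, N, 1)
  w
}
add_dw <- function(w, name, C) {
  w[[paste0(name, "_W")]] <- mat_init(C, 9L, sqrt(2 / 9))
  w[[paste0(name, "_b")]] <- matrix(0, C, 1)
  w
}
add_bn <- function(w, name, C) {
  w[[paste0(name, "_g")]] <- matrix(1, C, 1)
  w[[paste0(name, "_beta")]] <- matrix(0, C, 1)
  w[[paste0(name, "_rm")]] <- matrix(0, C, 1)
  w[[paste0(name, "_rv")]] <- matrix(1, C, 1)
  w
}
add_deconv <- function(w, name, C) {
  # start close to replication upsampling, with symmetry-breaking noise
  w[[paste0(name, "_W")]] <- matrix(1, C, 4) + mat_init(C, 4L, 0.05)
  w[[paste0(name, "_b")]] <- matrix(0, C, 1)
  w
}

add_conv_unit <- function(w, name, M, N, kind) {
  if (kind == "depthwise") {
    w <- add_conv1(w, paste0(name, "_pw"), M, N)
    w <- add_dw(w, paste0(name, "_dw"), N)
  } else {
    w <- add_conv3(w, name, M, N)
  }
  add_bn(w, paste0(name, "_bn"), N)
}

init_weights <- function(config) {
  plan <- conv_plan(config)
  A <- config$aspp_out_channels
  wtop <- config$widths[config$depth]
  with_local_seed(config$seed, {
    w <- list()
    for (i in seq_len(config$depth)) {
      pa <- plan[plan$stage == "encoder" & plan$block == i & plan$conv == "a", ]
      pb <- plan[plan$stage == "encoder" & plan$block == i & plan$conv == "b", ]
      w <- add_conv_unit(w, sprintf("enc%d_a", i), pa$M, pa$N, pa$kind)
      w <- add_conv3(w, sprintf("enc%d_b", i), pb$M, pb$N)
      w <- add_bn(w, sprintf("enc%d_b_bn", i), pb$N)
      w <- add_conv1(w, sprintf("enc%d_proj", i), pa$M, pb$N)
    }
    w <- add_conv1(w, "aspp_b0", wtop, A); w <- add_bn(w, "aspp_b0_bn", A)
    for (k in seq_along(config$aspp_rates)) {
      w <- add_conv3(w, sprintf("aspp_r%d", k), wtop, A)
      w <- add_bn(w, sprintf("aspp_r%d_bn", k), A)
    }
    w <- add_conv1(w, "aspp_pool", wtop, A)
    nb <- length(config$aspp_rates) + 2L
    w <- add_conv1(w, "aspp_fuse", nb * A, A); w <- add_bn(w, "aspp_fuse_bn", A)
    zc <- A
    for (i in rev(seq_len(config$depth))) {
      pa <- plan[plan$stage == "decoder" & plan$block == i & plan$conv == "a", ]
      pb <- plan[plan$stage == "decoder" & plan$block == i & plan$conv == "b", ]
      w <- add_deconv(w, sprintf("dec%d_up", i), zc)
      w <- add_conv1(w, sprintf("dec%d_fuse", i), zc + config$widths[i], pa$M)
      w <- add_bn(w, sprintf("dec%d_fuse_bn", i), pa$M)
      w <- add_conv_unit(w, sprintf("dec%d_a", i), pa$M, pa$N, pa$kind)
      w <- add_conv3(w, sprintf("dec%d_b", i), pb$M, pb$N)
      w <- add_bn(w, sprintf("dec%d_b_bn", i), pb$N)
      w <- add_conv1(w, sprintf("dec%d_proj", i), pa$M, pb$N)
      zc <- pb$N
    }
    w <- add_conv1(w, "head", config$in_channels, config$out_classes)
    w
  })
}

# ---- model construction ----------------------------------------------------

#' Build the segmentation network
#'
#' Constructs the U-shaped encoder-decoder: `depth` double-convolution
#' encoder blocks (each followed by 2x2 max pooling) with residual links,
#' a modified ASPP bottleneck (1x1 branch, one atrous 3x3 branch per
#' dilation rate, and a global-average-pool branch resized back to the
#' feature shape, fused by 1x1 convolution), and a mirrored decoder that
#' upsamples with per-channel (grouped) 2x2 transposed convolutions,
#' concatenates the encoder skip, and ends in a 1x1 convolution to the
#' two class maps. In the `ax_unet` variant the first convolution of
#' every double-conv block except the network's first layer is
#' depth-wise separable. Weight initialisation is Kaiming-style and
#' fully determined by `config$seed`.
#'
#' @param config An [model_config()] object.
#' @return An object of class `axunet_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "axunet_config"))
  if (config$out_classes != 2L)
    stop("the network is binary: out_classes must be 2", call. = FALSE)
  weights <- init_weights(config)
  params <- lapply(weights, ft_new)
  structure(list(config = config, params = params, plan = conv_plan(config)),
            class = "axunet_model")
}

#' @export
print.axunet_model <- function(x, ...) {
  np <- sum(vapply(get_weights(x), length, integer(1)))
  cat(sprintf("<axunet_model> %s, %s parameters\n", x$config$variant,
              format(np, big.mark = ",")))
  print(x$config)
  invisible(x)
}

#' Extract model weights as R arrays
#'
#' @param model An `axunet_model`.
#' @return A named list of numeric matrices (including batch-norm
#'   running statistics).
#' @export
get_weights <- function(model) lapply(model$params, ft_mat)

#' Replace model weights
#'
#' @param model An `axunet_model`.
#' @param weights A named list as returned by [get_weights()].
#' @return The model, invisibly.
#' @export
set_weights <- function(model, weights) {
  stopifnot(setequal(names(weights), names(model$params)))
  for (nm in names(weights)) ft_set(model$params[[nm]], weights[[nm]])
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are saved with R's native serialization and contain the
#' configuration plus all weights and batch-norm statistics.
#'
#' @param model An `axunet_model`.
#' @param path File path.
#' @return `load_checkpoint()` returns the rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, weights = get_weights(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- build_model(ck$config)
  set_weights(m, ck$weights)
  m
}

# ---- forward / backward ----------------------------------------------------

# conv3x3 + BN (+ optional ReLU)
unit_conv_fwd <- function(pm, nm, xp, C, H, W, B, dil = 1L, relu = TRUE,
                          training = TRUE) {
  cv <- conv3x3_fwd(xp, pm[[paste0(nm, "_W")]], pm[[paste0(nm, "_b")]],
                    C, H, W, B, dil)
  bn <- bn_fwd(cv$y, pm[[paste0(nm, "_bn_g")]], pm[[paste0(nm, "_bn_beta")]],
               pm[[paste0(nm, "_bn_rm")]], pm[[paste0(nm, "_bn_rv")]],
               training, .BN_MOMENTUM, .BN_EPS)
  y <- if (relu) relu_fwd(bn$y) else bn$y
  list(y = y, col = cv$col, bn = bn, relu = relu,
       dims = c(C, H, W, B, dil), training = training)
}

unit_conv_bwd <- function(pm, gr, nm, dy, cache, need_dx = TRUE) {
  d <- cache$dims
  if (cache$relu) dy <- relu_bwd(dy, cache$y)
  bb <- bn_bwd(dy, cache$bn$xhat, cache$bn$invstd, pm[[paste0(nm, "_bn_g")]],
               cache$training)
  acc_grad(gr, paste0(nm, "_bn_g"), bb$dgamma)
  acc_grad(gr, paste0(nm, "_bn_beta"), bb$dbeta)
  cb <- conv3x3_bwd2(bb$dx, cache$col, pm[[paste0(nm, "_W")]],
                     d[1], d[2], d[3], d[4], d[5], need_dx)
  acc_grad(gr, paste0(nm, "_W"), cb$dW)
  acc_grad(gr, paste0(nm, "_b"), cb$db)
  if (need_dx) cb$dx else NULL
}

# 1x1 pointwise + 3x3 depthwise + BN + ReLU
unit_dws_fwd <- function(pm, nm, xp, M, N, H, W, B, training = TRUE) {
  pw <- conv1x1_fwd(xp, pm[[paste0(nm, "_pw_W")]], pm[[paste0(nm, "_pw_b")]])
  dw <- dwconv3x3_fwd(pw, pm[[paste0(nm, "_dw_W")]], pm[[paste0(nm, "_dw_b")]],
                      N, H, W, B)
  bn <- bn_fwd(dw, pm[[paste0(nm, "_bn_g")]], pm[[paste0(nm, "_bn_beta")]],
               pm[[paste0(nm, "_bn_rm")]], pm[[paste0(nm, "_bn_rv")]],
               training, .BN_MOMENTUM, .BN_EPS)
  y <- relu_fwd(bn$y)
  list(y = y, x = xp, pw = pw, bn = bn, dims = c(M, N, H, W, B),
       training = training)
}

unit_dws_bwd <- function(pm, gr, nm, dy, cache) {
  d <- cache$dims
  dy <- relu_bwd(dy, cache$y)
  bb <- bn_bwd(dy, cache$bn$xhat, cache$bn$invstd, pm[[paste0(nm, "_bn_g")]],
               cache$training)
  acc_grad(gr, paste0(nm, "_bn_g"), bb$dgamma)
  acc_grad(gr, paste0(nm, "_bn_beta"), bb$dbeta)
  db <- dwconv3x3_bwd(bb$dx, cache$pw, pm[[paste0(nm, "_dw_W")]],
                      d[2], d[3], d[4], d[5])
  acc_grad(gr, paste0(nm, "_dw_W"), db$dW)
  acc_grad(gr, paste0(nm, "_dw_b"), db$db)
  pb <- conv1x1_bwd(db$dx, cache$x, pm[[paste0(nm, "_pw_W")]])
  acc_grad(gr, paste0(nm, "_pw_W"), pb$dW)
  acc_grad(gr, paste0(nm, "_pw_b"), pb$db)
  pb$dx
}

unit_a_fwd <- function(pm, nm, kind, xp, M, N, H, W, B, training) {
  if (kind == "depthwise") unit_dws_fwd(pm, nm, xp, M, N, H, W, B, training)
  else unit_conv_fwd(pm, nm, xp, M, H, W, B, 1L, TRUE, training)
}
unit_a_bwd <- function(pm, gr, nm, kind, dy, cache, need_dx = TRUE) {
  if (kind == "depthwise") unit_dws_bwd(pm, gr, nm, dy, cache)
  else unit_conv_bwd(pm, gr, nm, dy, cache, need_dx)
}

acc_grad <- function(gr, name, ptr) {
  if (is.null(gr[[name]])) gr[[name]] <- ptr else ft_accum(gr[[name]], ptr)
  invisible(NULL)
}

aspp_fwd <- function(pm, xp, C, h, w, B, rates, A, training) {
  hw <- h * w
  b0 <- conv1x1_fwd(xp, pm$aspp_b0_W, pm$aspp_b0_b)
  bn0 <- bn_fwd(b0, pm$aspp_b0_bn_g, pm$aspp_b0_bn_beta, pm$aspp_b0_bn_rm,
                pm$aspp_b0_bn_rv, training, .BN_MOMENTUM, .BN_EPS)
  y0 <- relu_fwd(bn0$y)
  ru <- vector("list", length(rates))
  for (k in seq_along(rates)) {
    ru[[k]] <- unit_conv_fwd(pm, sprintf("aspp_r%d", k), xp, C, h, w, B,
                             dil = rates[k], relu = TRUE, training = training)
  }
  gp <- gap_fwd(xp, hw, B)
  pc <- conv1x1_fwd(gp, pm$aspp_pool_W, pm$aspp_pool_b)
  pr <- relu_fwd(pc)
  pb <- broadcast_fwd(pr, hw, B)
  branches <- c(list(y0), lapply(ru, `[[`, "y"), list(pb))
  cat_ <- concat_many_fwd(branches)
  fu <- conv1x1_fwd(cat_, pm$aspp_fuse_W, pm$aspp_fuse_b)
  bnf <- bn_fwd(fu, pm$aspp_fuse_bn_g, pm$aspp_fuse_bn_beta, pm$aspp_fuse_bn_rm,
                pm$aspp_fuse_bn_rv, training, .BN_MOMENTUM, .BN_EPS)
  yf <- relu_fwd(bnf$y)
  list(y = yf, x = xp, b0 = b0, bn0 = bn0, y0 = y0, ru = ru, gp = gp, pc = pc,
       pr = pr, cat_ = cat_, bnf = bnf, dims = c(C, h, w, B, A),
       training = training)
}

aspp_bwd <- function(pm, gr, dy, cache, rates) {
  d <- cache$dims
  C <- d[1]; h <- d[2]; w <- d[3]; B <- d[4]; A <- d[5]
  hw <- h * w
  dy <- relu_bwd(dy, cache$y)
  bb <- bn_bwd(dy, cache$bnf$xhat, cache$bnf$invstd, pm$aspp_fuse_bn_g,
               cache$training)
  acc_grad(gr, "aspp_fuse_bn_g", bb$dgamma)
  acc_grad(gr, "aspp_fuse_bn_beta", bb$dbeta)
  fb <- conv1x1_bwd(bb$dx, cache$cat_, pm$aspp_fuse_W)
  acc_grad(gr, "aspp_fuse_W", fb$dW)
  acc_grad(gr, "aspp_fuse_b", fb$db)
  nb <- length(rates) + 2L
  parts <- split_rows(fb$dx, rep(A, nb))
  dx <- NULL
  # 1x1 branch
  d0 <- relu_bwd(parts[[1]], cache$y0)
  b0b <- bn_bwd(d0, cache$bn0$xhat, cache$bn0$invstd, pm$aspp_b0_bn_g,
                cache$training)
  acc_grad(gr, "aspp_b0_bn_g", b0b$dgamma)
  acc_grad(gr, "aspp_b0_bn_beta", b0b$dbeta)
  c0 <- conv1x1_bwd(b0b$dx, cache$x, pm$aspp_b0_W)
  acc_grad(gr, "aspp_b0_W", c0$dW)
  acc_grad(gr, "aspp_b0_b", c0$db)
  dx <- c0$dx
  # atrous branches
  for (k in seq_along(rates)) {
    dk <- unit_conv_bwd(pm, gr, sprintf("aspp_r%d", k), parts[[k + 1L]],
                        cache$ru[[k]])
    ft_accum(dx, dk)
  }
  # pooled branch
  dpb <- broadcast_bwd(parts[[nb]], hw, B)
  dpr <- relu_bwd(dpb, cache$pr)
  pcb <- conv1x1_bwd(dpr, cache$gp, pm$aspp_pool_W)
  acc_grad(gr, "aspp_pool_W", pcb$dW)
  acc_grad(gr, "aspp_pool_b", pcb$db)
  dgp <- gap_bwd(pcb$dx, hw, B)
  ft_accum(dx, dgp)
  dx
}

# full forward; returns foreground probabilities and the tape
model_forward <- function(model, xp, H, W, B, training = TRUE) {
  cfg <- model$config
  pm <- model$params
  if (H %% 2^cfg$depth != 0 || W %% 2^cfg$depth != 0)
    stop(sprintf("input %dx%d not divisible by 2^depth = %d", H, W, 2^cfg$depth),
         call. = FALSE)
  plan <- model$plan
  tape <- list(enc = vector("list", cfg$depth),
               dec = vector("list", cfg$depth), pooled = vector("list", cfg$depth))
  cur <- xp; h <- H; w <- W
  cin <- c(cfg$in_channels, cfg$widths)
  for (i in seq_len(cfg$depth)) {
    ka <- plan$kind[plan$stage == "encoder" & plan$block == i & plan$conv == "a"]
    a <- unit_a_fwd(pm, sprintf("enc%d_a", i), ka, cur, cin[i], cfg$widths[i],
                    h, w, B, training)
    b <- unit_conv_fwd(pm, sprintf("enc%d_b", i), a$y, cfg$widths[i], h, w, B,
                       1L, relu = FALSE, training = training)
    pj <- conv1x1_fwd(cur, pm[[sprintf("enc%d_proj_W", i)]],
                      pm[[sprintf("enc%d_proj_b", i)]])
    s <- add_fwd(b$y, pj)
    y <- relu_fwd(s)
    pl <- maxpool2_fwd(y, cfg$widths[i], h, w, B)
    tape$enc[[i]] <- list(a = a, b = b, x = cur, skip = y, pool = pl,
                          dims = c(cin[i], h, w, B))
    tape$pooled[[i]] <- pl$y
    cur <- pl$y
    h <- h %/% 2L; w <- w %/% 2L
  }
  tape$aspp <- aspp_fwd(pm, cur, cfg$widths[cfg$depth], h, w, B,
                        cfg$aspp_rates, cfg$aspp_out_channels, training)
  cur <- tape$aspp$y
  zc <- cfg$aspp_out_channels
  for (i in rev(seq_len(cfg$depth))) {
    up <- deconv2x2_fwd(cur, pm[[sprintf("dec%d_up_W", i)]],
                        pm[[sprintf("dec%d_up_b", i)]], zc, h, w, B)
    h <- h * 2L; w <- w * 2L
    cat_ <- concat_fwd(up, tape$enc[[i]]$skip)
    fu <- conv1x1_fwd(cat_, pm[[sprintf("dec%d_fuse_W", i)]],
                      pm[[sprintf("dec%d_fuse_b", i)]])
    bnf <- bn_fwd(fu, pm[[sprintf("dec%d_fuse_bn_g", i)]],
                  pm[[sprintf("dec%d_fuse_bn_beta", i)]],
                  pm[[sprintf("dec%d_fuse_bn_rm", i)]],
                  pm[[sprintf("dec%d_fuse_bn_rv", i)]],
                  training, .BN_MOMENTUM, .BN_EPS)
    f <- relu_fwd(bnf$y)
    ka <- plan$kind[plan$stage == "decoder" & plan$block == i & plan$conv == "a"]
    nout <- plan$N[plan$stage == "decoder" & plan$block == i & plan$conv == "b"]
    a <- unit_a_fwd(pm, sprintf("dec%d_a", i), ka, f, cfg$widths[i],
                    cfg$widths[i], h, w, B, training)
    b <- unit_conv_fwd(pm, sprintf("dec%d_b", i), a$y, cfg$widths[i], h, w, B,
                       1L, relu = FALSE, training = training)
    pj <- conv1x1_fwd(f, pm[[sprintf("dec%d_proj_W", i)]],
                      pm[[sprintf("dec%d_proj_b", i)]])
    s <- add_fwd(b$y, pj)
    y <- relu_fwd(s)
    tape$dec[[i]] <- list(up_in = cur, up = up, cat_ = cat_, bnf = bnf, f = f,
                          a = a, b = b, y = y, zc = zc,
                          dims = c(h, w, B), nout = nout)
    cur <- y
    zc <- nout
  }
  logits <- conv1x1_fwd(cur, pm$head_W, pm$head_b)
  sm <- softmax2_fwd(logits)
  tape$final <- cur
  tape$prob <- sm$p
  tape$B <- B; tape$H <- H; tape$W <- W
  list(prob = ft_mat(sm$p), tape = tape)
}

model_backward <- function(model, tape, dprob) {
  cfg <- model$config
  pm <- model$params
  gr <- new.env(parent = emptyenv())
  dp <- ft_new(dprob)
  dlog <- softmax2_bwd(dp, tape$prob)
  hb <- conv1x1_bwd(dlog, tape$final, pm$head_W)
  acc_grad(gr, "head_W", hb$dW)
  acc_grad(gr, "head_b", hb$db)
  dy <- hb$dx
  for (i in seq_len(cfg$depth)) {
    dc <- tape$dec[[i]]
    h <- dc$dims[1]; w <- dc$dims[2]; B <- dc$dims[3]
    dy <- relu_bwd(dy, dc$y)
    # residual: dy flows to conv_b chain and to proj
    pjb <- conv1x1_bwd(dy, dc$f, pm[[sprintf("dec%d_proj_W", i)]])
    acc_grad(gr, sprintf("dec%d_proj_W", i), pjb$dW)
    acc_grad(gr, sprintf("dec%d_proj_b", i), pjb$db)
    db_ <- unit_conv_bwd(pm, gr, sprintf("dec%d_b", i), dy, dc$b)
    ka <- model$plan$kind[model$plan$stage == "decoder" &
                            model$plan$block == i & model$plan$conv == "a"]
    df <- unit_a_bwd(pm, gr, sprintf("dec%d_a", i), ka, db_, dc$a)
    ft_accum(df, pjb$dx)
    df <- relu_bwd(df, dc$f)
    fb <- bn_bwd(df, dc$bnf$xhat, dc$bnf$invstd,
                 pm[[sprintf("dec%d_fuse_bn_g", i)]], TRUE)
    acc_grad(gr, sprintf("dec%d_fuse_bn_g", i), fb$dgamma)
    acc_grad(gr, sprintf("dec%d_fuse_bn_beta", i), fb$dbeta)
    cb <- conv1x1_bwd(fb$dx, dc$cat_, pm[[sprintf("dec%d_fuse_W", i)]])
    acc_grad(gr, sprintf("dec%d_fuse_W", i), cb$dW)
    acc_grad(gr, sprintf("dec%d_fuse_b", i), cb$db)
    sp <- concat_bwd(cb$dx, dc$zc)
    # skip gradient accumulates into the encoder block backward later
    tape$enc[[i]]$dskip <- sp$db
    ub <- deconv2x2_bwd(sp$da, dc$up_in, pm[[sprintf("dec%d_up_W", i)]],
                        dc$zc, h %/% 2L, w %/% 2L, B)
    acc_grad(gr, sprintf("dec%d_up_W", i), ub$dW)
    acc_grad(gr, sprintf("dec%d_up_b", i), ub$db)
    dy <- ub$dx
  }
  dy <- aspp_bwd(pm, gr, dy, tape$aspp, cfg$aspp_rates)
  for (i in rev(seq_len(cfg$depth))) {
    ec <- tape$enc[[i]]
    C <- ec$dims[1]; h <- ec$dims[2]; w <- ec$dims[3]; B <- ec$dims[4]
    dpool <- maxpool2_bwd(dy, ec$pool$idx, cfg$widths[i], h, w, B)
    if (!is.null(ec$dskip)) ft_accum(dpool, ec$dskip)
    dpool <- relu_bwd(dpool, ec$skip)
    pjb <- conv1x1_bwd(dpool, ec$x, pm[[sprintf("enc%d_proj_W", i)]])
    acc_grad(gr, sprintf("enc%d_proj_W", i), pjb$dW)
    acc_grad(gr, sprintf("enc%d_proj_b", i), pjb$db)
    db_ <- unit_conv_bwd(pm, gr, sprintf("enc%d_b", i), dpool, ec$b)
    ka <- model$plan$kind[model$plan$stage == "encoder" &
                            model$plan$block == i & model$plan$conv == "a"]
    dx <- unit_a_bwd(pm, gr, sprintf("enc%d_a", i), ka, db_, ec$a,
                     need_dx = i > 1L)
    if (i > 1L) {
      ft_accum(dx, pjb$dx)
      dy <- dx
    }
  }
  as.list(gr)
}

# ---- inference and activation maps -----------------------------------------

# images: list of (H, W, C) arrays already preprocessed
batch_to_ft <- function(images) {
  mats <- lapply(images, function(a) {
    C <- dim(a)[3]
    t(matrix(a, ncol = C))  # (C, HW), spatial order column-major
  })
  ft_new(do.call(cbind, mats))
}

#' Forward inference on preprocessed images
#'
#' @param model An `axunet_model`.
#' @param images A list of `(H, W, C)` arrays with values in `[0, 1]` and
#'   `C = config$in_channels`.
#' @param batch_size Images per forward pass.
#' @return A list of `H x W` foreground-probability matrices.
#' @export
infer_prob <- function(model, images, batch_size = 8L) {
  stopifnot(length(images) >= 1L)
  dims <- dim(images[[1]])
  H <- dims[1]; W <- dims[2]
  out <- vector("list", length(images))
  idx <- split(seq_along(images), ceiling(seq_along(images) / batch_size))
  for (ids in idx) {
    xp <- batch_to_ft(images[ids])
    fw <- model_forward(model, xp, H, W, length(ids), training = FALSE)
    for (j in seq_along(ids))
      out[[ids[j]]] <- matrix(fw$prob[1, ((j - 1) * H * W + 1):(j * H * W)], H, W)
  }
  out
}

#' Channel-reduced activation map at an encoder level
#'
#' Runs the encoder and reduces the feature stack after the `level`-th
#' pooling across channels by mean or max; the result is min-max rescaled
#' to `[0, 1]` for export, and has spatial size `input / 2^level`.
#'
#' @param model An `axunet_model`.
#' @param image An `(H, W, C)` array (preprocessed).
#' @param level Downsampling level, `1 <= level <= depth`.
#' @param mode `"mean"` or `"max"`.
#' @return A matrix of size `H/2^level x W/2^level`.
#' @export
activation_maps <- function(model, image, level, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  cfg <- model$config
  if (level < 1L || level > cfg$depth)
    stop("level out of range", call. = FALSE)
  dims <- dim(image)
  xp <- batch_to_ft(list(image))
  fw <- model_forward(model, xp, dims[1], dims[2], 1L, training = FALSE)
  v <- channel_reduce(fw$tape$pooled[[level]], mode)
  m <- matrix(v, dims[1] %/% 2^level, dims[2] %/% 2^level)
  rng <- range(m)
  if (rng[2] > rng[1]) m <- (m - rng[1]) / (rng[2] - rng[1]) else m[] <- 0
  m
}

# ---- standalone building-block ops -----------------------------------------

#' Depth-wise separable convolution block
#'
#' The Xception-style replacement for a normal 3x3 convolution: the input
#' is linearly transformed channel-by-channel by a 1x1 convolution from
#' `M` to `N` channels, and each resulting channel is then convolved by
#' exactly one 3x3x1 kernel. Parameters are freshly initialised from
#' `seed`; this standalone form exists for inspection and testing, the
#' trained network uses the same operation internally.
#'
#' @param input An `(H, W, M)` array.
#' @param M,N Input and output channel counts.
#' @param seed Seed for the block's random weights.
#' @return An `(H, W, N)` array.
#' @export
depthwise_separable_block <- function(input, M, N, seed = 1L) {
  d <- dim(input)
  if (length(d) != 3L || d[3] != M)
    stop(sprintf("input has %d channels, expected M = %d", d[3], M), call. = FALSE)
  w <- with_local_seed(seed, {
    w <- list()
    w <- add_conv1(w, "pw", M, N)
    add_dw(w, "dw", N)
  })
  xp <- batch_to_ft(list(input))
  pw <- conv1x1_fwd(xp, ft_new(w$pw_W), ft_new(w$pw_b))
  dw <- dwconv3x3_fwd(pw, ft_new(w$dw_W), ft_new(w$dw_b), N, d[1], d[2], 1L)
  array(t(ft_mat(dw)), dim = c(d[1], d[2], N))
}

#' Parameter counts for normal and depth-wise separable convolutions
#'
#' For a 3x3 convolution from `M` to `N` channels the normal form has
#' `3*3*M*N` parameters while the depth-wise separable form has
#' `3*3*M + 1*1*M*N` (a 3x3 kernel per input channel plus the pointwise
#' mixing weights).
#'
#' @param M,N Channel counts.
#' @return Parameter count (kernel weights, excluding biases).
#' @export
conv_param_count <- function(M, N) 9 * M * N

#' @rdname conv_param_count
#' @export
dws_param_count <- function(M, N) 9 * M + M * N

#' Standalone ASPP forward pass
#'
#' Applies a freshly initialised ASPP module to a feature map:
#' a 1x1 branch, one 3x3 atrous branch per dilation rate, and a
#' global-average-pool branch (1x1-projected, then resized back to the
#' feature shape), concatenated along channels and fused by a 1x1
#' convolution to `out_channels`. Output spatial size equals input
#' spatial size. A warning (not an error) is raised when a dilation rate
#' reaches the feature extent, where the atrous kernel degenerates
#' towards a 1x1 convolution.
#'
#' @param feature An `(H, W, C)` array.
#' @param rates Integer dilation rates.
#' @param out_channels Channels of the fused output.
#' @param seed Seed for the module's random weights.
#' @return An `(H, W, out_channels)` array.
#' @export
aspp_forward <- function(feature, rates = c(2L, 4L, 6L), out_channels = 256L,
                         seed = 1L) {
  d <- dim(feature)
  stopifnot(length(d) == 3L)
  if (any(rates >= min(d[1], d[2])))
    warning("dilation rate >= feature extent: atrous branch degenerates towards 1x1")
  C <- d[3]; A <- as.integer(out_channels)
  w <- with_local_seed(seed, {
    w <- list()
    w <- add_conv1(w, "aspp_b0", C, A); w <- add_bn(w, "aspp_b0_bn", A)
    for (k in seq_along(rates)) {
      w <- add_conv3(w, sprintf("aspp_r%d", k), C, A)
      w <- add_bn(w, sprintf("aspp_r%d_bn", k), A)
    }
    w <- add_conv1(w, "aspp_pool", C, A)
    w <- add_conv1(w, "aspp_fuse", (length(rates) + 2L) * A, A)
    add_bn(w, "aspp_fuse_bn", A)
  })
  pm <- lapply(w, ft_new)
  xp <- batch_to_ft(list(feature))
  out <- aspp_fwd(pm, xp, C, d[1], d[2], 1L, as.integer(rates), A,
                  training = FALSE)
  array(t(ft_mat(out$y)), dim = c(d[1], d[2], A))
}
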