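# Independent brute-force oracles used to pin expected values. These
# deliberately re-derive every quantity with plain scalar loops, never
# through the package's own vectorised code paths.

# scalar evaluation of the generalized Dice loss (two classes)
oracle_gdl <- function(pred, target, eps = 1e-5) {
  num <- 0; den <- 0
  for (cls in c(0, 1)) {
    y <- if (cls == 1) target else 1 - target
    p <- if (cls == 1) pred else 1 - pred
    sy <- 0
    for (v in y) sy <- sy + v
    w <- if (sy > 0) 1 / sy^2 else 0
    s1 <- 0; s2 <- 0
    for (i in seq_along(y)) {
      s1 <- s1 + y[i] * p[i]
      s2 <- s2 + y[i] + p[i]
    }
    num <- num + w * s1
    den <- den + w * s2
  }
  1 - 2 * num / (den + eps)
}

# scalar focal loss
oracle_focal <- function(pred, target, alpha = 0.25, gamma = 2, delta = 1e-7) {
  tot <- 0
  for (i in seq_along(pred)) {
    p <- min(max(pred[i], delta), 1 - delta)
    tot <- tot + if (target[i] == 1) -alpha * (1 - p)^gamma * log(p)
    else -(1 - alpha) * p^gamma * log(1 - p)
  }
  tot / length(pred)
}

# scalar Sobel magnitude map with replicate padding, normalized by max
oracle_sobel <- function(x) {
  Gx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  Gy <- matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3, byrow = TRUE)
  H <- nrow(x); W <- ncol(x)
  g <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    gx <- 0; gy <- 0
    for (dr in -1:1) for (dc in -1:1) {
      rr <- min(max(r + dr, 1), H); cc <- min(max(c + dc, 1), W)
      v <- x[rr, cc]
      gx <- gx + Gx[dr + 2, dc + 2] * v
      gy <- gy + Gy[dr + 2, dc + 2] * v
    }
    g[r, c] <- sqrt(gx^2 + gy^2)
  }
  m <- max(g)
  if (m > 0) g / m else g
}

# scalar contour-aware loss: cross-entropy of the normalized edge maps
# referenced to the target map's own entropy (binary KL divergence)
oracle_cal <- function(pred, target, delta = 1e-7) {
  ep <- oracle_sobel(pred)
  et <- oracle_sobel(target)
  tot <- 0
  for (i in seq_along(ep)) {
    p <- min(max(ep[i], delta), 1 - delta)
    tc <- min(max(et[i], delta), 1 - delta)
    ce <- -et[i] * log(p) - (1 - et[i]) * log(1 - p)
    h <- -et[i] * log(tc) - (1 - et[i]) * log(1 - tc)
    tot <- tot + ce - h
  }
  tot / length(ep)
}

# double-loop Hausdorff distance
oracle_hausdorff <- function(a, b) {
  dmax <- 0
  for (i in seq_len(nrow(a))) {
    dmin <- Inf
    for (j in seq_len(nrow(b)))
      dmin <- min(dmin, sqrt(sum((a[i, ] - b[j, ])^2)))
    dmax <- max(dmax, dmin)
  }
  for (j in seq_len(nrow(b))) {
    dmin <- Inf
    for (i in seq_len(nrow(a)))
      dmin <- min(dmin, sqrt(sum((a[i, ] - b[j, ])^2)))
    dmax <- max(dmax, dmin)
  }
  dmax
}

# double-loop co-occurrence counter (symmetric, angle-summed, normalized)
oracle_glcm <- function(img, mask, levels, distance = 1,
                        angles = c(0, 45, 90, 135)) {
  inside <- mask == 1
  vals <- img[inside]
  rng <- range(vals)
  H <- nrow(img); W <- ncol(img)
  q <- matrix(NA_integer_, H, W)
  for (r in 1:H) for (c in 1:W) if (inside[r, c]) {
    q[r, c] <- if (rng[2] > rng[1])
      min(floor((img[r, c] - rng[1]) / (rng[2] - rng[1]) * levels) + 1, levels)
    else 1L
  }
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0), `135` = c(-1, -1))
  P <- matrix(0, levels, levels)
  for (ang in angles) {
    o <- offs[[as.character(ang)]] * distance
    for (r in 1:H) for (c in 1:W) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      if (inside[r, c] && inside[r2, c2]) {
        P[q[r, c], q[r2, c2]] <- P[q[r, c], q[r2, c2]] + 1
        P[q[r2, c2], q[r, c]] <- P[q[r2, c2], q[r, c]] + 1
      }
    }
  }
  P / sum(P)
}

# scalar loops over all (i, j) for the GLCM-domain texture features
oracle_features <- function(P) {
  N <- nrow(P)
  S <- 0; E <- 0; GH <- 0; GD <- 0; C <- 0; Acu <- 0
  mu <- mean(P)
  for (i in 0:(N - 1)) for (j in 0:(N - 1)) {
    p <- P[i + 1, j + 1]
    if (p > 0) S <- S - p * log(p)
    E <- E + p^2
    GH <- GH + p / (1 + (i - j)^2)
    GD <- GD + p * abs(i - j)
    C <- C + p * (i - j)^2
    Acu <- Acu + (p - mu)^2
  }
  list(S = S, E = E, GH = GH, GD = GD, C = C, Acu = Acu)
}

# exact two-sided Mann-Whitney p by enumerating all labelings
oracle_mw_exact <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  ple <- mean(us <= u_obs)
  pge <- mean(us >= u_obs)
  min(1, 2 * min(ple, pge))
}

# small deterministic binary mask fixtures
fixture_masks <- function() {
  z <- matrix(0, 4, 4); y <- matrix(0, 4, 4)
  # |Z| = 4, |Y| = 6, |Z intersect Y| = 3
  z[1, 1:4] <- 1
  y[1, 1:3] <- 1; y[2, 1:3] <- 1
  list(z = z, y = y)
}

random_mask <- function(H = 12, W = 12, p = 0.3) {
  matrix(rbinom(H * W, 1, p), H, W)
}

tiny_model_config <- function(seed = 1L) {
  model_config(base_width = 4L, depth = 2L, aspp_rates = c(1L, 2L),
               seed = seed)
}
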