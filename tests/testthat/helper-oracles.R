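# Brute-force enumeration oracles for the texture machinery: plain nested
# loops over voxels, neighbor offsets, runs and zones, kept deliberately
# independent of the package's vectorized implementations.

oracle_offsets <- function() {
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    d <- c(dx, dy, dz)
    if (all(d == 0)) next
    # keep one representative per opposite pair: first nonzero positive
    nz <- d[d != 0]
    if (nz[1] > 0) offs[[length(offs) + 1]] <- d
  }
  offs
}

in_grid <- function(p, dims) all(p >= 1) && all(p <= dims)

oracle_glcm <- function(lev, ng = max(lev, na.rm = TRUE)) {
  dims <- dim(lev)
  C <- matrix(0, ng, ng)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    for (d in oracle_offsets()) {
      q <- c(x, y, z) + d
      if (!in_grid(q, dims)) next
      b <- lev[q[1], q[2], q[3]]
      if (is.na(b)) next
      C[a, b] <- C[a, b] + 1
      C[b, a] <- C[b, a] + 1
    }
  }
  C
}

oracle_glrlm <- function(lev, ng = max(lev, na.rm = TRUE)) {
  dims <- dim(lev)
  runs <- list()
  for (d in oracle_offsets()) {
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      a <- lev[x, y, z]
      if (is.na(a)) next
      prev <- c(x, y, z) - d
      prev_same <- in_grid(prev, dims) &&
        !is.na(lev[prev[1], prev[2], prev[3]]) &&
        lev[prev[1], prev[2], prev[3]] == a
      if (prev_same) next  # not a run start
      len <- 1
      q <- c(x, y, z) + d
      while (in_grid(q, dims) && !is.na(lev[q[1], q[2], q[3]]) &&
             lev[q[1], q[2], q[3]] == a) {
        len <- len + 1
        q <- q + d
      }
      runs[[length(runs) + 1]] <- c(a, len)
    }
  }
  maxlen <- max(vapply(runs, `[`, numeric(1), 2))
  R <- matrix(0, ng, maxlen)
  for (r in runs) R[r[1], r[2]] <- R[r[1], r[2]] + 1
  R
}

oracle_glszm <- function(lev, ng = max(lev, na.rm = TRUE)) {
  dims <- dim(lev)
  seen <- array(FALSE, dims)
  nbhd <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx || dy || dz) nbhd[[length(nbhd) + 1]] <- c(dx, dy, dz)
  }
  zones <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (seen[x, y, z] || is.na(lev[x, y, z])) next
    a <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (d in nbhd) {
        q <- p + d
        if (!in_grid(q, dims)) next
        if (seen[q[1], q[2], q[3]]) next
        b <- lev[q[1], q[2], q[3]]
        if (is.na(b) || b != a) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  maxsz <- max(vapply(zones, `[`, numeric(1), 2))
  Z <- matrix(0, ng, maxsz)
  for (zn in zones) Z[zn[1], zn[2]] <- Z[zn[1], zn[2]] + 1
  Z
}

oracle_ngtdm <- function(lev, ng = max(lev, na.rm = TRUE)) {
  dims <- dim(lev)
  s <- numeric(ng); n <- numeric(ng); n_valid <- 0
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (!dx && !dy && !dz) next
      q <- c(x + dx, y + dy, z + dz)
      if (!in_grid(q, dims)) next
      b <- lev[q[1], q[2], q[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    n_valid <- n_valid + 1
    n[a] <- n[a] + 1
    s[a] <- s[a] + abs(a - mean(nb))
  }
  list(s = s, n = n, n_valid = n_valid)
}

# --- loop-based feature formulas ------------------------------------------

olog2 <- function(v) if (v > 0) log(v, base = 2) else 0

oracle_glcm_features <- function(C) {
  ng <- nrow(C)
  P <- C / sum(C)
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + P[i, j]
  present <- which(px > 0); ngp <- length(present)
  mux <- 0; for (i in 1:ng) mux <- mux + i * px[i]
  sigx2 <- 0; for (i in 1:ng) sigx2 <- sigx2 + px[i] * (i - mux)^2
  pd <- numeric(ng); ps <- numeric(2 * ng)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j] <- ps[i + j] + P[i, j]
  }
  acc <- 0; clp <- 0; cls <- 0; clt <- 0; con <- 0; idv <- 0; idm <- 0
  idmn <- 0; idn <- 0; invvar <- 0; je <- 0; hxy <- 0; mp <- 0; ss <- 0
  hxy1 <- 0; hxy2 <- 0; cor_num <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    acc <- acc + p * i * j
    clp <- clp + p * (i + j - 2 * mux)^4
    cls <- cls + p * (i + j - 2 * mux)^3
    clt <- clt + p * (i + j - 2 * mux)^2
    con <- con + p * (i - j)^2
    idv <- idv + p / (1 + abs(i - j))
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + (i - j)^2 / ngp^2)
    idn <- idn + p / (1 + abs(i - j) / ngp)
    if (i != j) invvar <- invvar + p / (i - j)^2
    je <- je + p^2
    hxy <- hxy - p * olog2(p)
    if (p > mp) mp <- p
    ss <- ss + p * (i - mux)^2
    cor_num <- cor_num + p * i * j
    hxy1 <- hxy1 - p * olog2(px[i] * px[j])
    hxy2 <- hxy2 - px[i] * px[j] * olog2(px[i] * px[j])
  }
  da <- 0; for (k in 1:ng) da <- da + (k - 1) * pd[k]
  de <- 0; dv <- 0
  for (k in 1:ng) {
    de <- de - pd[k] * olog2(pd[k])
    dv <- dv + pd[k] * ((k - 1) - da)^2
  }
  sa <- 0; se <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * ps[k]
    se <- se - ps[k] * olog2(ps[k])
  }
  hx <- 0; for (i in 1:ng) hx <- hx - px[i] * olog2(px[i])
  corr <- if (sigx2 > 0) (cor_num - mux^2) / sigx2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  mcc <- if (ngp <= 1) 1 else {
    Q <- matrix(0, ngp, ngp)
    for (a in seq_len(ngp)) for (b in seq_len(ngp)) {
      for (k in seq_len(ngp)) {
        Q[a, b] <- Q[a, b] + P[present[a], present[k]] * P[present[b], present[k]] /
          (px[present[a]] * px[present[k]])
      }
    }
    ev <- sort(Re(eigen(Q)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  c(autocorrelation = acc, joint_average = mux, cluster_prominence = clp,
    cluster_shade = cls, cluster_tendency = clt, contrast = con,
    correlation = corr, difference_average = da, difference_entropy = de,
    difference_variance = dv, inverse_difference = idv,
    inverse_difference_moment = idm, idmn = idmn, idn = idn, imc1 = imc1,
    imc2 = imc2, inverse_variance = invvar, joint_energy = je,
    joint_entropy = hxy, mcc = mcc, maximum_probability = mp,
    sum_average = sa, sum_entropy = se, sum_squares = ss)
}

oracle_run_zone_features <- function(M, n_possible) {
  ng <- nrow(M); nl <- ncol(M)
  Nr <- sum(M)
  sre <- 0; lre <- 0; gln <- 0; rln <- 0; glv <- 0; rv <- 0; re <- 0
  lgl <- 0; hgl <- 0; srl <- 0; srh <- 0; lrl <- 0; lrh <- 0
  mu_i <- 0; mu_l <- 0
  for (i in 1:ng) for (l in 1:nl) {
    p <- M[i, l] / Nr
    mu_i <- mu_i + p * i; mu_l <- mu_l + p * l
  }
  for (i in 1:ng) {
    ri <- 0; for (l in 1:nl) ri <- ri + M[i, l]
    gln <- gln + ri^2
  }
  for (l in 1:nl) {
    rl <- 0; for (i in 1:ng) rl <- rl + M[i, l]
    rln <- rln + rl^2
  }
  for (i in 1:ng) for (l in 1:nl) {
    p <- M[i, l] / Nr
    sre <- sre + p / l^2; lre <- lre + p * l^2
    glv <- glv + p * (i - mu_i)^2; rv <- rv + p * (l - mu_l)^2
    re <- re - p * olog2(p)
    lgl <- lgl + p / i^2; hgl <- hgl + p * i^2
    srl <- srl + p / (i^2 * l^2); srh <- srh + p * i^2 / l^2
    lrl <- lrl + p * l^2 / i^2; lrh <- lrh + p * i^2 * l^2
  }
  c(sre, lre, gln / Nr, gln / Nr^2, rln / Nr, rln / Nr^2, Nr / n_possible,
    glv, rv, re, lgl, hgl, srl, srh, lrl, lrh)
}

oracle_ngtdm_features <- function(m) {
  nv <- m$n_valid
  ng <- length(m$n)
  p <- m$n / nv
  act <- which(p > 0); ngp <- length(act)
  pssum <- 0; for (i in act) pssum <- pssum + p[i] * m$s[i]
  coarse <- if (pssum > 0) 1 / pssum else 0
  contrast <- 0
  if (ngp > 1) {
    for (i in act) for (j in act) contrast <- contrast + p[i] * p[j] * (i - j)^2
    contrast <- contrast / (ngp * (ngp - 1)) * sum(m$s) / nv
  }
  bden <- 0
  for (i in act) for (j in act) bden <- bden + abs(i * p[i] - j * p[j])
  busy <- if (bden > 0) pssum / bden else 0
  cplx <- 0
  for (i in act) for (j in act) {
    cplx <- cplx + abs(i - j) * (p[i] * m$s[i] + p[j] * m$s[j]) / (p[i] + p[j])
  }
  cplx <- cplx / nv
  strength <- 0
  if (sum(m$s) > 0) {
    for (i in act) for (j in act) strength <- strength + (p[i] + p[j]) * (i - j)^2
    strength <- strength / sum(m$s)
  }
  c(coarseness = coarse, contrast = contrast, busyness = busy,
    complexity = cplx, strength = strength)
}

# All 61 texture features of a level grid, by brute force.
oracle_texture_features <- function(lev, ng = max(lev, na.rm = TRUE)) {
  nv <- sum(!is.na(lev))
  c(oracle_glcm_features(oracle_glcm(lev, ng)),
    oracle_run_zone_features(oracle_glrlm(lev, ng), 13 * nv),
    oracle_run_zone_features(oracle_glszm(lev, ng), nv),
    oracle_ngtdm_features(oracle_ngtdm(lev, ng)))
}

# Random small level grid with an irregular ROI, for property sweeps.
random_level_grid <- function(dims = c(4, 4, 4), n_levels = 4, na_frac = 0.2) {
  lev <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  drop_n <- floor(na_frac * prod(dims))
  if (drop_n > 0) lev[sample.int(prod(dims), drop_n)] <- NA
  if (sum(!is.na(lev)) < 2) lev[1:2] <- 1L
  lev
}
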