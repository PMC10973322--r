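# Independent brute-force oracles for the texture feature bank.
#
# Everything here is written as plain enumeration (explicit loops, rle),
# deliberately avoiding the package's accumulation kernels, so that
# agreement with the package is a genuine dual-route check.

# neighbour offset tables (re-derived here, not taken from the package)
oracleOffsets26 <- function() {
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
    if (dx || dy || dz) out <- rbind(out, c(dx, dy, dz))
  out
}

oracleDirs13 <- function() {
  o <- oracleOffsets26()
  o[o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
      (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0), , drop = FALSE]
}

oracleLevels <- function(hu, mask, binWidth) {
  lev <- array(0L, dim(hu))
  lev[mask] <- floor((hu[mask] - min(hu[mask])) / binWidth) + 1L
  lev
}

.inGrid <- function(p, d) all(p >= 1) && all(p <= d)

# --- GLCM --------------------------------------------------------------------

oracleGlcmMatrix <- function(lev, off) {
  d <- dim(lev)
  ng <- max(lev)
  M <- matrix(0, ng, ng)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    g1 <- lev[x, y, z]
    if (g1 == 0) next
    p2 <- c(x, y, z) + off
    if (!.inGrid(p2, d)) next
    g2 <- lev[p2[1], p2[2], p2[3]]
    if (g2 == 0) next
    M[g1, g2] <- M[g1, g2] + 1
    M[g2, g1] <- M[g2, g1] + 1
  }
  M
}

oracleGlcmFeaturesFromP <- function(P) {
  ng <- nrow(P)
  px <- rowSums(P)
  mux <- 0
  for (i in 1:ng) mux <- mux + i * px[i]
  sig2 <- 0
  for (i in 1:ng) sig2 <- sig2 + (i - mux)^2 * px[i]

  auto <- clusP <- clusS <- clusT <- contrast <- 0
  id <- idm <- idmn <- idn <- invVar <- energy <- 0
  hxy <- hxy1 <- 0
  maxp <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    auto <- auto + i * j * p
    clusP <- clusP + (i + j - 2 * mux)^4 * p
    clusS <- clusS + (i + j - 2 * mux)^3 * p
    clusT <- clusT + (i + j - 2 * mux)^2 * p
    contrast <- contrast + (i - j)^2 * p
    id <- id + p / (1 + abs(i - j))
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + ((i - j) / ng)^2)
    idn <- idn + p / (1 + abs(i - j) / ng)
    if (i != j) invVar <- invVar + p / (i - j)^2
    energy <- energy + p^2
    if (p > 0) {
      hxy <- hxy - p * log2(p)
      hxy1 <- hxy1 - p * log2(px[i] * px[j])
    }
    if (p > maxp) maxp <- p
  }
  hx <- 0
  for (i in 1:ng) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
  hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng)
    if (px[i] * px[j] > 0)
      hxy2 <- hxy2 - px[i] * px[j] * log2(px[i] * px[j])

  pxmy <- numeric(ng)         # k = 0 .. ng-1 at index k+1
  pxpy <- numeric(2 * ng - 1) # k = 2 .. 2ng at index k-1
  for (i in 1:ng) for (j in 1:ng) {
    pxmy[abs(i - j) + 1] <- pxmy[abs(i - j) + 1] + P[i, j]
    pxpy[i + j - 1] <- pxpy[i + j - 1] + P[i, j]
  }
  da <- sum((0:(ng - 1)) * pxmy)
  dvar <- sum(((0:(ng - 1)) - da)^2 * pxmy)
  dent <- -sum(pxmy[pxmy > 0] * log2(pxmy[pxmy > 0]))
  sa <- sum((2:(2 * ng)) * pxpy)
  sent <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  ss <- 0
  for (i in 1:ng) for (j in 1:ng) ss <- ss + (i - mux)^2 * P[i, j]

  present <- which(px > 0)
  mcc <- if (length(present) > 1) {
    np <- length(present)
    Q <- matrix(0, np, np)
    for (a in seq_len(np)) for (b in seq_len(np)) {
      s <- 0
      for (kk in present)
        s <- s + P[present[a], kk] * P[present[b], kk] /
          (px[present[a]] * px[kk])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(min(ev[2], 1), 0))
  } else 1

  c(Autocorrelation = auto, ClusterProminence = clusP,
    ClusterShade = clusS, ClusterTendency = clusT, Contrast = contrast,
    Correlation = if (sig2 > 0) (auto - mux^2) / sig2 else 1,
    DifferenceAverage = da, DifferenceEntropy = dent,
    DifferenceVariance = dvar, Id = id, Idm = idm, Idmn = idmn,
    Idn = idn,
    Imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    Imc2 = if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0,
    InverseVariance = invVar, JointAverage = mux, JointEnergy = energy,
    JointEntropy = hxy, MCC = mcc, MaximumProbability = maxp,
    SumAverage = sa, SumEntropy = sent, SumSquares = ss)
}

oracleGlcm <- function(lev) {
  dirs <- oracleDirs13()
  acc <- NULL
  used <- 0
  for (d in seq_len(nrow(dirs))) {
    M <- oracleGlcmMatrix(lev, dirs[d, ])
    if (sum(M) == 0) next
    f <- oracleGlcmFeaturesFromP(M / sum(M))
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1
  }
  out <- acc / used
  names(out) <- paste0("glcm_", names(out))
  out
}

# --- GLDM --------------------------------------------------------------------

oracleGldm <- function(lev, alpha = 0) {
  d <- dim(lev)
  ng <- max(lev)
  off <- oracleOffsets26()
  counts <- matrix(0, ng, nrow(off) + 1)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    g <- lev[x, y, z]
    if (g == 0) next
    dep <- 0
    for (k in seq_len(nrow(off))) {
      p2 <- c(x, y, z) + off[k, ]
      if (!.inGrid(p2, d)) next
      g2 <- lev[p2[1], p2[2], p2[3]]
      if (g2 > 0 && abs(g - g2) <= alpha) dep <- dep + 1
    }
    counts[g, dep + 1] <- counts[g, dep + 1] + 1
  }
  counts <- counts[, 1:max(which(colSums(counts) > 0)), drop = FALSE]
  Nz <- sum(counts)
  sde <- lde <- glv <- dv <- de <- lgl <- hgl <- 0
  sdl <- sdh <- ldl <- ldh <- 0
  mui <- muj <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    p <- counts[i, j] / Nz
    mui <- mui + i * p; muj <- muj + j * p
  }
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    p <- counts[i, j] / Nz
    sde <- sde + p / j^2; lde <- lde + p * j^2
    glv <- glv + p * (i - mui)^2; dv <- dv + p * (j - muj)^2
    if (p > 0) de <- de - p * log2(p)
    lgl <- lgl + p / i^2; hgl <- hgl + p * i^2
    sdl <- sdl + p / (i^2 * j^2); sdh <- sdh + p * i^2 / j^2
    ldl <- ldl + p * j^2 / i^2; ldh <- ldh + p * i^2 * j^2
  }
  gln <- sum(rowSums(counts)^2) / Nz
  dn <- sum(colSums(counts)^2) / Nz
  c(gldm_SmallDependenceEmphasis = sde,
    gldm_LargeDependenceEmphasis = lde,
    gldm_GrayLevelNonUniformity = gln,
    gldm_DependenceNonUniformity = dn,
    gldm_DependenceNonUniformityNormalized = dn / Nz,
    gldm_GrayLevelVariance = glv, gldm_DependenceVariance = dv,
    gldm_DependenceEntropy = de, gldm_LowGrayLevelEmphasis = lgl,
    gldm_HighGrayLevelEmphasis = hgl,
    gldm_SmallDependenceLowGrayLevelEmphasis = sdl,
    gldm_SmallDependenceHighGrayLevelEmphasis = sdh,
    gldm_LargeDependenceLowGrayLevelEmphasis = ldl,
    gldm_LargeDependenceHighGrayLevelEmphasis = ldh)
}

# --- GLRLM -------------------------------------------------------------------

# runs via rle over explicitly walked grid lines
oracleGlrlmMatrix <- function(lev, dir) {
  d <- dim(lev)
  ng <- max(lev)
  maxlen <- max(d)
  M <- matrix(0, ng, maxlen)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    pos <- c(x, y, z)
    prev <- pos - dir
    if (.inGrid(prev, d)) next  # not a line start
    seqLev <- integer()
    while (.inGrid(pos, d)) {
      seqLev <- c(seqLev, lev[pos[1], pos[2], pos[3]])
      pos <- pos + dir
    }
    r <- rle(seqLev)
    for (k in seq_along(r$values))
      if (r$values[k] > 0)
        M[r$values[k], r$lengths[k]] <- M[r$values[k], r$lengths[k]] + 1
  }
  M
}

oracleRunFeatures <- function(M, np, prefix, zoneWords) {
  Nr <- sum(M)
  ng <- nrow(M); nl <- ncol(M)
  f <- setNames(numeric(16), zoneWords)
  mui <- muj <- 0
  for (i in 1:ng) for (j in 1:nl) {
    p <- M[i, j] / Nr
    mui <- mui + i * p; muj <- muj + j * p
  }
  for (i in 1:ng) for (j in 1:nl) {
    p <- M[i, j] / Nr
    f[1] <- f[1] + p / j^2
    f[2] <- f[2] + p * j^2
    f[8] <- f[8] + p * (i - mui)^2
    f[9] <- f[9] + p * (j - muj)^2
    if (p > 0) f[10] <- f[10] - p * log2(p)
    f[11] <- f[11] + p / i^2
    f[12] <- f[12] + p * i^2
    f[13] <- f[13] + p / (i^2 * j^2)
    f[14] <- f[14] + p * i^2 / j^2
    f[15] <- f[15] + p * j^2 / i^2
    f[16] <- f[16] + p * i^2 * j^2
  }
  f[3] <- sum(rowSums(M)^2) / Nr
  f[4] <- f[3] / Nr
  f[5] <- sum(colSums(M)^2) / Nr
  f[6] <- f[5] / Nr
  f[7] <- Nr / np
  names(f) <- paste0(prefix, names(f))
  f
}

oracleGlrlm <- function(lev) {
  np <- sum(lev > 0)
  dirs <- oracleDirs13()
  words <- c("ShortRunEmphasis", "LongRunEmphasis",
             "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
             "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
             "RunPercentage", "GrayLevelVariance", "RunVariance",
             "RunEntropy", "LowGrayLevelRunEmphasis",
             "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
             "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
             "LongRunHighGrayLevelEmphasis")
  acc <- NULL
  for (d in seq_len(nrow(dirs))) {
    M <- oracleGlrlmMatrix(lev, dirs[d, ])
    M <- M[, 1:max(which(colSums(M) > 0)), drop = FALSE]
    f <- oracleRunFeatures(M, np, "glrlm_", words)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(dirs)
}

# --- GLSZM -------------------------------------------------------------------

oracleZones <- function(lev) {
  d <- dim(lev)
  off <- oracleOffsets26()
  seen <- array(FALSE, d)
  zones <- NULL
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (seen[x, y, z] || lev[x, y, z] == 0) next
    g <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(off))) {
        p2 <- v + off[k, ]
        if (!.inGrid(p2, d)) next
        if (!seen[p2[1], p2[2], p2[3]] && lev[p2[1], p2[2], p2[3]] == g) {
          seen[p2[1], p2[2], p2[3]] <- TRUE
          queue <- c(queue, list(p2))
        }
      }
    }
    zones <- rbind(zones, c(g, size))
  }
  zones
}

oracleGlszm <- function(lev) {
  np <- sum(lev > 0)
  ng <- max(lev)
  zones <- oracleZones(lev)
  M <- matrix(0, ng, max(zones[, 2]))
  for (r in seq_len(nrow(zones)))
    M[zones[r, 1], zones[r, 2]] <- M[zones[r, 1], zones[r, 2]] + 1
  words <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
             "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
             "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
             "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
             "ZoneEntropy", "LowGrayLevelZoneEmphasis",
             "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
             "SmallAreaHighGrayLevelEmphasis",
             "LargeAreaLowGrayLevelEmphasis",
             "LargeAreaHighGrayLevelEmphasis")
  oracleRunFeatures(M, np, "glszm_", words)
}

# --- NGTDM -------------------------------------------------------------------

oracleNgtdm <- function(lev) {
  d <- dim(lev)
  ng <- max(lev)
  off <- oracleOffsets26()
  si <- numeric(ng)
  ni <- numeric(ng)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    g <- lev[x, y, z]
    if (g == 0) next
    neigh <- c()
    for (k in seq_len(nrow(off))) {
      p2 <- c(x, y, z) + off[k, ]
      if (!.inGrid(p2, d)) next
      g2 <- lev[p2[1], p2[2], p2[3]]
      if (g2 > 0) neigh <- c(neigh, g2)
    }
    if (length(neigh)) {
      ni[g] <- ni[g] + 1
      si[g] <- si[g] + abs(g - mean(neigh))
    }
  }
  N <- sum(ni)
  p <- ni / N
  present <- which(p > 0)
  ngp <- length(present)
  coars <- if (sum(p * si) > 0) 1 / sum(p * si) else 1e6
  contr <- 0
  if (ngp > 1) {
    for (a in present) for (b in present)
      contr <- contr + p[a] * p[b] * (a - b)^2
    contr <- contr / (ngp * (ngp - 1)) * sum(si) / N
  }
  denB <- 0
  for (a in present) for (b in present)
    denB <- denB + abs(a * p[a] - b * p[b])
  busy <- if (denB > 0) sum(p * si) / denB else 0
  compl <- 0
  for (a in present) for (b in present)
    compl <- compl + abs(a - b) * (p[a] * si[a] + p[b] * si[b]) /
      (p[a] + p[b])
  compl <- compl / N
  stren <- 0
  if (sum(si) > 0) {
    for (a in present) for (b in present)
      stren <- stren + (p[a] + p[b]) * (a - b)^2
    stren <- stren / sum(si)
  }
  c(ngtdm_Coarseness = coars, ngtdm_Contrast = contr,
    ngtdm_Busyness = busy, ngtdm_Complexity = compl,
    ngtdm_Strength = stren)
}

oracleTexture <- function(hu, mask, binWidth = 1) {
  lev <- oracleLevels(hu, mask, binWidth)
  c(oracleGlcm(lev), oracleGldm(lev), oracleGlrlm(lev),
    oracleGlszm(lev), oracleNgtdm(lev))
}

# --- other oracles -----------------------------------------------------------

# Mann-Whitney pair-count AUC
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# random ROI generator for oracle-equivalence checks
randomLevelVolume <- function(maxSide = 8, nLevels = 4, fill = 0.7) {
  d <- sample(2:maxSide, 3, replace = TRUE)
  hu <- array(sample.int(nLevels, prod(d), replace = TRUE), d)
  mask <- array(runif(prod(d)) < fill, d)
  while (sum(mask) < 8) mask <- array(runif(prod(d)) < fill, d)
  list(volume = ctVolume(hu, spacing = c(1, 1, 1)),
       mask = muscleMask(mask, spacing = c(1, 1, 1)),
       hu = hu, m = mask)
}
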