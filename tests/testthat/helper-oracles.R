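# Independent brute-force oracles. These deliberately share no code with
# the package: pairs are enumerated voxel by voxel, statistics are written
# as explicit double loops, and p-values come from full enumeration.

# GLCM by explicit pair enumeration over a quantized 3D array (NA outside
# the VOI), in-plane offset per axial slice.
bruteGLCM <- function(q, distance, direction, L, symmetric = TRUE) {
  d <- dim(q)
  counts <- matrix(0, L, L)
  dx <- direction[1] * distance
  dy <- direction[2] * distance
  for (z in seq_len(d[3])) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        i2 <- i + dx; j2 <- j + dy
        if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2]) next
        a <- q[i, j, z]; b <- q[i2, j2, z]
        if (is.na(a) || is.na(b)) next
        counts[a, b] <- counts[a, b] + 1
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

# The 25 co-occurrence statistics as literal double loops.
bruteGLCMStats <- function(P) {
  L <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:L) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:L) { sx2 <- sx2 + (i - mux)^2 * px[i]
                   sy2 <- sy2 + (i - muy)^2 * py[i] }
  psum <- rep(0, 2 * L); pdiff <- rep(0, L)
  s <- list(autocorrelation = 0, joint_average = mux, cluster_prominence = 0,
            cluster_shade = 0, cluster_tendency = 0, contrast = 0,
            correlation = 0, difference_average = 0, difference_entropy = 0,
            difference_variance = 0, joint_energy = 0, joint_entropy = 0,
            imc1 = 0, imc2 = 0, idm = 0, idmn = 0, id = 0, idn = 0,
            inverse_variance = 0, maximum_probability = 0, sum_average = 0,
            sum_entropy = 0, sum_squares = 0, dissimilarity = 0,
            homogeneity = 0)
  HXY <- 0; HXY1 <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
    s$autocorrelation <- s$autocorrelation + i * j * p
    s$cluster_prominence <- s$cluster_prominence + (i + j - mux - muy)^4 * p
    s$cluster_shade <- s$cluster_shade + (i + j - mux - muy)^3 * p
    s$cluster_tendency <- s$cluster_tendency + (i + j - mux - muy)^2 * p
    s$contrast <- s$contrast + (i - j)^2 * p
    s$joint_energy <- s$joint_energy + p^2
    if (p > 0) HXY <- HXY - p * log2(p)
    if (p > 0 && px[i] * py[j] > 0)
      HXY1 <- HXY1 - p * log2(px[i] * py[j])
    s$idm <- s$idm + p / (1 + (i - j)^2)
    s$idmn <- s$idmn + p / (1 + ((i - j) / L)^2)
    s$id <- s$id + p / (1 + abs(i - j))
    s$idn <- s$idn + p / (1 + abs(i - j) / L)
    if (i != j) s$inverse_variance <- s$inverse_variance + p / (i - j)^2
    s$maximum_probability <- max(s$maximum_probability, p)
    s$sum_squares <- s$sum_squares + (i - mux)^2 * p
    s$dissimilarity <- s$dissimilarity + abs(i - j) * p
    s$homogeneity <- s$homogeneity + p / (1 + abs(i - j))
  }
  s$joint_entropy <- HXY
  cor_num <- s$autocorrelation - mux * muy
  s$correlation <- if (sx2 * sy2 > 0) cor_num / sqrt(sx2 * sy2) else 1
  for (k in 2:(2 * L)) {
    s$sum_average <- s$sum_average + k * psum[k]
    if (psum[k] > 0) s$sum_entropy <- s$sum_entropy - psum[k] * log2(psum[k])
  }
  da <- 0
  for (k in 0:(L - 1)) da <- da + k * pdiff[k + 1]
  s$difference_average <- da
  for (k in 0:(L - 1)) {
    s$difference_variance <- s$difference_variance + (k - da)^2 * pdiff[k + 1]
    if (pdiff[k + 1] > 0)
      s$difference_entropy <- s$difference_entropy -
        pdiff[k + 1] * log2(pdiff[k + 1])
  }
  HX <- 0; HY <- 0
  for (i in 1:L) {
    if (px[i] > 0) HX <- HX - px[i] * log2(px[i])
    if (py[i] > 0) HY <- HY - py[i] * log2(py[i])
  }
  HXY2 <- 0
  for (i in 1:L) for (j in 1:L)
    if (px[i] * py[j] > 0)
      HXY2 <- HXY2 - px[i] * py[j] * log2(px[i] * py[j])
  s$imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  s$imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  unlist(s)
}

# AUC by explicit concordant/discordant pair counting (ties half).
bruteAUC <- function(values, labels) {
  pos <- values[labels == 1]; neg <- values[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Exact two-sided Wilcoxon signed-rank p by full 2^n sign enumeration
# (assumes no ties among |d| and no zero differences).
bruteSignedRankP <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  Wall <- as.matrix(signs) %*% r
  pW <- table(Wall) / 2^n
  mu <- n * (n + 1) / 4
  sum(pW[abs(as.numeric(names(pW)) - mu) >= abs(W - mu) - 1e-9])
}

# Fisher 2x2 two-sided p by hypergeometric enumeration.
bruteFisherP <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  p0 <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Small deterministic quantized phantom with NA border, for GLCM tests.
randomQuantized <- function(dims, L, seed, naFrac = 0.2) {
  set.seed(seed)
  q <- array(sample.int(L, prod(dims), replace = TRUE), dim = dims)
  q[runif(prod(dims)) < naFrac] <- NA_integer_
  q
}

smallCohortConfig <- function(n = 6, seed = 1, timepoints = c("BL", "C2", "C4"),
                              ...) {
  cohortConfig(nPatients = n, timepoints = timepoints, seed = seed, ...)
}
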