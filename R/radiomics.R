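#' Gray-level quantization parameters
#'
#' @param nLevels Number of gray levels (>= 2); default 32, the common
#'   radiomics choice. Bins are equal width over the VOI min-max range.
#' @return A list of class `QuantizationParams`.
#' @export
quantizationParams <- function(nLevels = 32L) {
  if (nLevels < 2) stop("nLevels must be >= 2")
  structure(list(nLevels = as.integer(nLevels), mode = "fixed_bin_count",
                 rangeSource = "voi_min_max"), class = "QuantizationParams")
}

.glcmStatNames <- c(
  "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "joint_energy",
  "joint_entropy", "imc1", "imc2", "idm", "idmn", "id", "idn",
  "inverse_variance", "maximum_probability", "sum_average", "sum_entropy",
  "sum_squares", "dissimilarity", "homogeneity")

#' GLCM configuration
#'
#' Defaults give 25 statistics x 3 distances x 4 in-plane directions = 300
#' texture features, each offset reported separately. Co-occurrence is
#' accumulated per axial slice (in-plane), reflecting protocols whose slice
#' thickness is much larger than the in-plane resolution.
#'
#' @param distances Integer voxel distances (default 1:3).
#' @param directions List of in-plane `(drow, dcol)` unit offsets.
#' @param symmetric Count each pair in both orders (default `TRUE`).
#' @param statistics Character vector of statistic names (subset of the 25
#'   supported; default all).
#' @return A list of class `GLCMConfig`.
#' @export
glcmConfig <- function(distances = 1:3,
                       directions = list(c(1, 0), c(0, 1), c(1, 1), c(1, -1)),
                       symmetric = TRUE, statistics = .glcmStatNames) {
  bad <- setdiff(statistics, .glcmStatNames)
  if (length(bad)) stop("unknown GLCM statistics: ", paste(bad, collapse = ", "))
  structure(list(distances = as.integer(distances), directions = directions,
                 symmetric = isTRUE(symmetric), statistics = statistics),
            class = "GLCMConfig")
}

#' First-order (histogram) features of a VOI
#'
#' The ten first-order features: minimum, maximum, mean, standard deviation
#' (n-1 denominator), skewness (standardized third moment), kurtosis
#' (Fisher excess; normal gives 0), and the 1st, 5th, 95th and 99th
#' percentiles (linear interpolation between order statistics). Constant
#' input yields sd = 0 and skewness/kurtosis 0 by convention; empty input
#' yields a named all-`NA` vector rather than an error.
#'
#' @param intensities Numeric vector of VOI voxel values.
#' @return Named numeric vector of length 10 (`fo_minimum` ... `fo_p99`).
#' @export
firstOrderFeatures <- function(intensities) {
  nm <- c("fo_minimum", "fo_maximum", "fo_mean", "fo_sd", "fo_skewness",
          "fo_kurtosis", "fo_p1", "fo_p5", "fo_p95", "fo_p99")
  x <- intensities[is.finite(intensities)]
  n <- length(x)
  if (n == 0L) return(setNames(rep(NA_real_, 10L), nm))
  m <- mean(x)
  m2 <- mean((x - m)^2)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 - 3 else 0
  q <- quantile(x, c(0.01, 0.05, 0.95, 0.99), names = FALSE, type = 7)
  setNames(c(min(x), max(x), m, if (n > 1) sd(x) else 0, skew, kurt, q), nm)
}

#' Quantize a volume over a VOI
#'
#' Equal-width binning of the VOI intensities into `1..nLevels`, spanning
#' the VOI min-max range; the maximum maps to `nLevels`. A constant VOI
#' maps entirely to level 1 and the result carries attribute
#' `constant = TRUE`.
#'
#' @param volume 3D scalar array.
#' @param voi [VOIMask-class] (nonempty).
#' @param params A [quantizationParams()].
#' @return Integer 3D array with levels inside the VOI and `NA` outside.
#' @export
quantizeVolume <- function(volume, voi, params = quantizationParams()) {
  m <- maskArray(voi)
  if (!any(m)) stop("VOI is empty")
  L <- params$nLevels
  v <- volume[m]
  lo <- min(v); hi <- max(v)
  q <- array(NA_integer_, dim = dim(volume))
  if (hi == lo) {
    q[m] <- 1L
    attr(q, "constant") <- TRUE
  } else {
    q[m] <- pmin(L, as.integer(floor((v - lo) / (hi - lo) * L)) + 1L)
    attr(q, "constant") <- FALSE
  }
  attr(q, "nLevels") <- L
  q
}

#' Gray-level co-occurrence matrix at one offset
#'
#' Pairs are accumulated per axial slice at the given in-plane offset; both
#' voxels of a pair must lie inside the VOI (be non-`NA`). The matrix is
#' normalized to sum 1; with `symmetric = TRUE` each pair counts in both
#' orders and the matrix equals its transpose.
#'
#' @param quantized Output of [quantizeVolume()] (levels with `NA` outside
#'   the VOI).
#' @param distance Integer voxel distance.
#' @param direction In-plane `(drow, dcol)` unit offset.
#' @param symmetric Symmetrize the pair counts.
#' @param nLevels Number of levels; taken from the quantized array's
#'   attribute when absent.
#' @return `nLevels x nLevels` matrix summing to 1, or an all-zero matrix
#'   with attribute `empty = TRUE` when no valid pair exists.
#' @export
glcmMatrix <- function(quantized, distance = 1L, direction = c(1, 0),
                       symmetric = TRUE, nLevels = attr(quantized, "nLevels")) {
  if (is.null(nLevels)) nLevels <- max(quantized, na.rm = TRUE)
  L <- as.integer(nLevels)
  d <- dim(quantized)
  dx <- direction[1] * distance
  dy <- direction[2] * distance
  counts <- numeric(L * L)
  r1 <- max(1L, 1L - dx):min(d[1], d[1] - dx)
  c1 <- max(1L, 1L - dy):min(d[2], d[2] - dy)
  if (length(r1) && length(c1) && r1[1] <= r1[length(r1)]) {
    for (z in seq_len(d[3])) {
      sl <- quantized[, , z]
      if (all(is.na(sl))) next
      a <- sl[r1, c1, drop = FALSE]
      b <- sl[r1 + dx, c1 + dy, drop = FALSE]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) next
      counts <- counts + tabulate((a[ok] - 1L) * L + b[ok], nbins = L * L)
    }
  }
  P <- matrix(counts, nrow = L, ncol = L, byrow = TRUE)
  if (symmetric) P <- P + t(P)
  tot <- sum(P)
  if (tot == 0) {
    attr(P, "empty") <- TRUE
    return(P)
  }
  P <- P / tot
  attr(P, "empty") <- FALSE
  P
}

## Cached index grids per level count (I+J and |I-J| groupings).
.glcmGridCache <- new.env(parent = emptyenv())
glcmGrids <- function(L) {
  key <- as.character(L)
  g <- .glcmGridCache[[key]]
  if (!is.null(g)) return(g)
  I <- matrix(rep(seq_len(L), L), nrow = L)
  J <- t(I)
  g <- list(I = I, J = J, S = I + J, D = abs(I - J))
  .glcmGridCache[[key]] <- g
  g
}

#' Haralick-style statistics of a normalized GLCM
#'
#' Computes the 25 supported co-occurrence statistics by their textbook
#' formulas (logarithms base 2). Degenerate matrices take analytic limits:
#' a single-level matrix has correlation 1 (by convention) and information
#' measures 0. An empty (flagged) matrix yields all-`NA`.
#'
#' @param P Normalized GLCM from [glcmMatrix()].
#' @param statistics Names to compute (default all 25).
#' @return Named numeric vector.
#' @export
glcmStatistics <- function(P, statistics = .glcmStatNames) {
  if (isTRUE(attr(P, "empty")))
    return(setNames(rep(NA_real_, length(statistics)), statistics))
  L <- nrow(P)
  g <- glcmGrids(L)
  I <- g$I; J <- g$J
  px <- rowSums(P); py <- colSums(P)
  lev <- seq_len(L)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  ## p_{x+y}(k), k = 2..2L and p_{x-y}(k), k = 0..L-1
  pv <- as.vector(P)
  psum <- as.vector(rowsum(pv, as.vector(g$S)))        # groups 2..2L, sorted
  pdiff <- as.vector(rowsum(pv, as.vector(g$D)))       # groups 0..L-1, sorted
  ksum <- 2:(2 * L)
  kdiff <- 0:(L - 1)
  log2p <- function(p) { o <- p > 0; sum(p[o] * log2(p[o])) }
  HXY <- -log2p(P)
  HX <- -log2p(px); HY <- -log2p(py)
  ## the cross entropies collapse to the marginal entropies:
  ## -sum p(i,j) log2(px(i)py(j)) = HX + HY, and likewise for px*py weights
  HXY1 <- HX + HY
  HXY2 <- HX + HY
  DA <- sum(kdiff * pdiff)
  offdiag <- g$D > 0
  vals <- c(
    autocorrelation = sum(I * J * P),
    joint_average = mux,
    cluster_prominence = sum((I + J - mux - muy)^4 * P),
    cluster_shade = sum((I + J - mux - muy)^3 * P),
    cluster_tendency = sum((I + J - mux - muy)^2 * P),
    contrast = sum((I - J)^2 * P),
    correlation = if (sx * sy > 0) (sum(I * J * P) - mux * muy) / (sx * sy) else 1,
    difference_average = DA,
    difference_entropy = -log2p(pdiff),
    difference_variance = sum((kdiff - DA)^2 * pdiff),
    joint_energy = sum(P^2),
    joint_entropy = HXY,
    imc1 = if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0,
    imc2 = sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY)))),
    idm = sum(P / (1 + (I - J)^2)),
    idmn = sum(P / (1 + ((I - J) / L)^2)),
    id = sum(P / (1 + abs(I - J))),
    idn = sum(P / (1 + abs(I - J) / L)),
    inverse_variance = sum(P[offdiag] / (g$D[offdiag]^2)),
    maximum_probability = max(P),
    sum_average = sum(ksum * psum),
    sum_entropy = -log2p(psum),
    sum_squares = sum((I - mux)^2 * P),
    dissimilarity = sum(abs(I - J) * P),
    homogeneity = sum(P / (1 + abs(I - J))))
  vals[statistics]
}

dirCode <- function(v) paste0(gsub("-", "m", as.character(v)), collapse = "")

#' Feature names emitted by the extractor
#'
#' @param quantization,glcm Parameter objects (defaults).
#' @return Character vector: 10 first-order names followed by
#'   `glcm_<statistic>_d<distance>_a<direction>` for every offset.
#' @export
radiomicFeatureNames <- function(quantization = quantizationParams(),
                         glcm = glcmConfig()) {
  fo <- names(firstOrderFeatures(c(0, 1)))
  gl <- character(0)
  for (d in glcm$distances)
    for (dir in glcm$directions)
      gl <- c(gl, sprintf("glcm_%s_d%d_a%s", glcm$statistics, d, dirCode(dir)))
  c(fo, gl)
}

#' Extract the full radiomic feature vector for one study VOI
#'
#' 10 first-order plus (by default) 300 GLCM features, from the DCE
#' early-subtraction volume (`sequence = "DCE"`) or the b=800 DWI volume
#' (`"DWI"`). An empty VOI yields an all-`NA` vector (with attribute
#' `emptyVOI = TRUE`), never an error.
#'
#' @param study An [MRIStudy-class].
#' @param voi A [VOIMask-class].
#' @param sequence `"DCE"` or `"DWI"`.
#' @param quantization A [quantizationParams()].
#' @param glcm A [glcmConfig()].
#' @return Named numeric vector (length 310 under defaults).
#' @export
extractFeatureVector <- function(study, voi, sequence = c("DCE", "DWI"),
                                 quantization = quantizationParams(),
                                 glcm = glcmConfig()) {
  sequence <- match.arg(sequence)
  vol <- studyVolume(study, if (sequence == "DCE") "dce" else "dwi_b800")
  if (is.null(vol)) stop("required volume absent from study")
  nm <- radiomicFeatureNames(quantization, glcm)
  m <- maskArray(voi)
  if (!identical(dim(m), dim(vol))) stop("VOI and volume shapes differ")
  if (!any(m)) {
    out <- setNames(rep(NA_real_, length(nm)), nm)
    attr(out, "emptyVOI") <- TRUE
    return(out)
  }
  fo <- firstOrderFeatures(vol[m])
  q <- quantizeVolume(vol, voi, quantization)
  ## co-occurrence only sees VOI voxels: crop to the bounding box for speed
  bb <- maskBbox(!is.na(q), dim(q))
  L <- attr(q, "nLevels")
  q <- q[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  attr(q, "nLevels") <- L
  gl <- numeric(0)
  for (d in glcm$distances) {
    for (dir in glcm$directions) {
      P <- glcmMatrix(q, d, dir, glcm$symmetric, quantization$nLevels)
      s <- glcmStatistics(P, glcm$statistics)
      names(s) <- sprintf("glcm_%s_d%d_a%s", glcm$statistics, d, dirCode(dir))
      gl <- c(gl, s)
    }
  }
  out <- c(fo, gl)
  attr(out, "patientId") <- patientId(study)
  attr(out, "timepoint") <- timepoint(study)
  attr(out, "sequence") <- sequence
  out
}
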