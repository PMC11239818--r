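# Internal helpers: deterministic substreams, RNG hygiene, array filters,
# connected components. Nothing here is exported.

#' @importFrom methods new is slot validObject
#' @importFrom stats var sd quantile rnorm runif cor median coef
#'   wilcox.test fisher.test predict setNames pnorm
#' @importFrom utils head write.csv read.csv packageVersion
NULL

## Stable 31-adic string hash into [1, 2^31 - 2]; used to derive independent
## per-patient / per-timepoint RNG substreams from one global seed so that
## adding patients never reshuffles existing ones.
stableHash <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "\r")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483629
  as.integer(h + 1L)
}

## Evaluate expr under a local RNG seeded with `seed`, restoring the caller's
## RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

## Separable Gaussian smoothing of a 3D array (sigma in voxels per axis).
gaussSmooth3D <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-((-half:half)^2) / (2 * s^2))
    k <- k / sum(k)
    a <- convolveAxis(a, k, axis)
  }
  a
}

## Zero-padded convolution along one axis of a 3D array, vectorised as
## shifted slab adds over the (short) kernel.
convolveAxis <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  half <- (length(k) - 1L) %/% 2L
  out <- array(0, dim = d)
  for (j in seq_along(k)) {
    off <- j - half - 1L           # source index = target index + off
    t <- max(1L, 1L - off):min(n, n - off)
    if (t[1] > t[length(t)]) next
    s <- t + off
    if (axis == 1L)
      out[t, , ] <- out[t, , ] + k[j] * a[s, , ]
    else if (axis == 2L)
      out[, t, ] <- out[, t, ] + k[j] * a[, s, ]
    else
      out[, , t] <- out[, , t] + k[j] * a[, , s]
  }
  out
}

## Expand an index-range bounding box by `pad` voxels, clamped to the grid.
expandBbox <- function(bb, pad, d) {
  lapply(1:3, function(k)
    max(1L, min(bb[[k]]) - pad):min(d[k], max(bb[[k]]) + pad))
}

## Smooth unit-variance Gaussian random field on a grid (white noise passed
## through a Gaussian filter, then standardised).
smoothNoiseField <- function(dimv, sigma) {
  f <- gaussSmooth3D(array(rnorm(prod(dimv)), dim = dimv), sigma)
  s <- sd(as.vector(f))
  if (s == 0) return(f)
  (f - mean(f)) / s
}

## Shift a 3D array by an integer offset, filling exposed cells with `fill`.
shiftArray3D <- function(a, off, fill = Inf) {
  d <- dim(a)
  out <- array(fill, dim = d)
  rng <- lapply(1:3, function(k) {
    t <- max(1L, 1L + off[k]):min(d[k], d[k] + off[k])
    if (t[1] > t[length(t)]) integer(0) else t
  })
  if (any(!lengths(rng))) return(out)
  out[rng[[1]], rng[[2]], rng[[3]]] <-
    a[rng[[1]] - off[1], rng[[2]] - off[2], rng[[3]] - off[3]]
  out
}

## 26-connected components of a logical 3D array; returns integer labels
## (0 = background). Vectorised minimum-label flooding over the foreground
## voxel list, using a zero-padded linear index so neighbor lookups are
## plain vector reads.
labelComponents3D <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  out <- array(0L, dim = d)
  if (!length(idx)) return(out)
  co <- arrayInd(idx, d)
  dp <- d + 2L
  lin <- (co[, 3]) * (dp[1] * dp[2]) + (co[, 2]) * dp[1] + co[, 1] + 1L
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  offs <- nb[, 3] * (dp[1] * dp[2]) + nb[, 2] * dp[1] + nb[, 1]
  labPad <- rep(Inf, prod(dp))
  labPad[lin] <- seq_along(lin)
  cur <- labPad[lin]
  repeat {
    m <- cur
    for (o in offs) m <- pmin(m, labPad[lin + o])
    if (identical(m, cur)) break
    cur <- m
    labPad[lin] <- m
  }
  out[idx] <- as.integer(factor(cur))
  out
}

## Bounding box (list of index ranges) of the TRUE/non-NA region.
maskBbox <- function(keep, d) {
  idx <- which(keep)
  co <- arrayInd(idx, d)
  lapply(1:3, function(k) min(co[, k]):max(co[, k]))
}

## Drop connected components below a voxel-count floor. Labeling runs on
## the mask's bounding box only.
pruneSmallComponents <- function(mask, minVoxels) {
  if (minVoxels <= 1L || !any(mask)) return(mask)
  bb <- maskBbox(mask, dim(mask))
  sub <- mask[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  lab <- labelComponents3D(sub)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minVoxels)
  out <- array(FALSE, dim = dim(mask))
  out[bb[[1]], bb[[2]], bb[[3]]] <- array(lab %in% keep & sub, dim = dim(sub))
  out
}
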