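## Internal image utilities: 8-connected labelling, geodesic dilation,
## rigid warping, correlation scores.

## Shift a matrix by (dr, dc), padding with `fill`.
shiftMat <- function(m, dr, dc, fill = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## 8-connected component labelling. EBImage::bwlabel is 4-connected, so
## labels that touch diagonally are merged with a union-find pass.
label8 <- function(mask) {
  mode(mask) <- "numeric"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  pairs <- NULL
  # the two diagonal adjacency directions (down-right, down-left)
  diag1a <- lab[-nrow(lab), -ncol(lab)]; diag1b <- lab[-1, -1]
  diag2a <- lab[-nrow(lab), -1];         diag2b <- lab[-1, -ncol(lab)]
  for (ab in list(list(diag1a, diag1b), list(diag2a, diag2b))) {
    a <- ab[[1]]; b <- ab[[2]]
    keep <- a > 0L & b > 0L & a != b
    if (any(keep)) pairs <- rbind(pairs, cbind(a[keep], b[keep]))
  }
  if (is.null(pairs)) return(lab)
  pairs <- unique(pairs)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, 1L)
  relab <- integer(n)
  relab[sort(unique(root))] <- seq_along(unique(root))
  map <- relab[root]
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

## Binary dilation with a disc of the given radius (EBImage, odd brush).
dilateDisc <- function(mask, radius) {
  size <- 2L * as.integer(ceiling(radius)) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  out <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask)), brush)
  matrix(out > 0, nrow(mask), ncol(mask))
}

## Geodesic dilation: grow `seed` within `support` by iterated 3x3 (disc
## r=1) dilation, `radius` iterations. Never leaves support ∪ seed.
geodesicDilate <- function(seed, support, radius) {
  cur <- seed
  allowed <- support | seed
  for (i in seq_len(as.integer(ceiling(radius)))) {
    nxt <- dilateDisc(cur, 1.5) & allowed
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

## Bilinear sampling of image `img` at (rows, cols) coordinate vectors.
## Out-of-range coordinates take value `fill`.
bilinearSample <- function(img, rows, cols, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  val <- numeric(length(rows))
  ok <- r0 >= 1 & c0 >= 1 & r0 <= h - 1 & c0 <= w - 1
  # clamp the exact boundary rows/cols
  edge <- rows >= 1 & cols >= 1 & rows <= h & cols <= w & !ok
  val[!ok & !edge] <- fill
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok])
    v00 <- img[i00]
    v10 <- img[cbind(r0[ok] + 1, c0[ok])]
    v01 <- img[cbind(r0[ok], c0[ok] + 1)]
    v11 <- img[cbind(r0[ok] + 1, c0[ok] + 1)]
    frk <- fr[ok]; fck <- fc[ok]
    val[ok] <- v00 * (1 - frk) * (1 - fck) + v10 * frk * (1 - fck) +
      v01 * (1 - frk) * fck + v11 * frk * fck
  }
  if (any(edge)) {
    val[edge] <- img[cbind(pmin(pmax(round(rows[edge]), 1), h),
                           pmin(pmax(round(cols[edge]), 1), w))]
  }
  val
}

## Apply the inverse of a rigid transform to sample `img` on the output
## grid: out(x) = img(R^-1 (x - c - t) + c). `angle` in degrees, rotation
## about the image centre.
warpRigid <- function(img, angle, tx, ty, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  th <- angle * pi / 180
  co <- cos(th); si <- sin(th)
  rows <- rep(seq_len(h), times = w) - cr - tx
  cols <- rep(seq_len(w), each = h) - cc - ty
  srcR <- co * rows + si * cols + cr
  srcC <- -si * rows + co * cols + cc
  matrix(bilinearSample(img, srcR, srcC, fill = fill), h, w)
}

## Map points (n x 2, row/col) forward through a RigidTransform defined on
## an image of dimensions `dm`.
transformPoints <- function(pts, transform, dm) {
  cr <- (dm[1] + 1) / 2; cc <- (dm[2] + 1) / 2
  th <- transform@angle * pi / 180
  co <- cos(th); si <- sin(th)
  r <- pts[, 1] - cr; c <- pts[, 2] - cc
  cbind(co * r - si * c + cr + transform@tx,
        si * r + co * c + cc + transform@ty)
}

## Block-mean downsampling by integer factor f (anti-aliased reduction).
downsampleMean <- function(m, f) {
  n1 <- nrow(m) %/% f; n2 <- ncol(m) %/% f
  m <- m[seq_len(n1 * f), seq_len(n2 * f)]
  arr <- array(m, c(f, n1, f * n2))
  s1 <- colMeans(arr)                      # n1 x (f*n2)
  arr2 <- array(t(matrix(s1, n1, f * n2)), c(f, n2, n1))
  t(colMeans(arr2))                        # n1 x n2
}

## Pearson correlation of two equal-size matrices (0 if degenerate).
nccScore <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  stats::cor(a, b)
}

## Cosine similarity of two binary masks (1 for identical non-empty masks).
maskMatchScore <- function(a, b) {
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  sum(a & b) / sqrt(na * nb)
}

## Deterministic sub-seed derivation (keeps results independent of the
## order in which plate-days are rendered). Kept below 2^31.
subSeed <- function(seed, ...) {
  ids <- c(...)
  x <- as.double(seed %% 2147483647L)
  for (i in ids) {
    x <- (x * 48271 + as.double(i) * 10007 + 12345) %% 2147483647
  }
  as.integer(x %% 2000000000)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Linear indices -> (row, col) matrix.
idxToRowCol <- function(idx, dm) {
  cbind((idx - 1L) %% dm[1] + 1L, (idx - 1L) %/% dm[1] + 1L)
}

## (row, col) matrix -> linear indices.
rowColToIdx <- function(rc, dm) {
  (rc[, 2] - 1L) * dm[1] + rc[, 1]
}
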