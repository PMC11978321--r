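# Image-processing primitives (no imaging package for these exists in the
# dependency set, so they are implemented here): grayscale morphology with a
# disk, separable Gaussian smoothing, Otsu threshold, Zhang-Suen thinning,
# connected-component labelling, hole filling. Images are numeric matrices
# indexed [row, col].

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2 + 1e-9, , drop = FALSE]
}

# shift a matrix by (dy, dx), padding with `fill`
shift_mat <- function(m, dy, dx, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 + dy):min(nr, nr + dy)
  sc <- max(1, 1 + dx):min(nc, nc + dx)
  out[sr, sc] <- m[sr - dy, sc - dx, drop = FALSE]
  out
}

grey_erode <- function(img, radius) {
  off <- disk_offsets(radius)
  out <- img
  for (i in seq_len(nrow(off)))
    out <- pmin(out, shift_mat(img, off$dy[i], off$dx[i], Inf))
  out
}

grey_dilate <- function(img, radius) {
  off <- disk_offsets(radius)
  out <- img
  for (i in seq_len(nrow(off)))
    out <- pmax(out, shift_mat(img, off$dy[i], off$dx[i], -Inf))
  out
}

# morphological opening: the "rolling ball" background surface
grey_open <- function(img, radius) grey_dilate(grey_erode(img, radius), radius)

binary_dilate <- function(mask, radius) {
  off <- disk_offsets(radius)
  out <- mask
  for (i in seq_len(nrow(off)))
    out <- out | shift_mat(mask, off$dy[i], off$dx[i], FALSE)
  out
}

binary_erode <- function(mask, radius) !binary_dilate(!mask, radius)

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with renormalized (replicate-equivalent) borders:
# a constant image is preserved exactly.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  smooth_axis <- function(m) {
    n <- nrow(m)
    r <- (length(k) - 1L) %/% 2L
    S <- matrix(0, n, n)
    for (j in seq_along(k)) {
      d <- j - r - 1L
      idx <- seq_len(n) + d
      ok <- idx >= 1L & idx <= n
      S[cbind(which(ok), idx[ok])] <- S[cbind(which(ok), idx[ok])] + k[j]
    }
    S <- S / rowSums(S)
    S %*% m
  }
  t(smooth_axis(t(smooth_axis(img))))
}

# Otsu's threshold on a 256-bin histogram; errors on constant images.
otsu_threshold <- function(img) {
  v <- as.numeric(img)
  rng <- range(v)
  if (rng[1L] == rng[2L])
    stop("cannot auto-threshold a constant image; supply a manual threshold")
  nb <- 256L
  br <- seq(rng[1L], rng[2L], length.out = nb + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nb)
  mids <- (br[-1L] + br[-(nb + 1L)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

# Three-class Otsu (exhaustive over a 128-bin histogram). Returns the two
# class boundaries; the lower one separates background from structures when
# a small very bright class (the cortical ring) would otherwise capture a
# two-class split.
multiotsu_thresholds <- function(img, nb = 128L) {
  v <- as.numeric(img)
  rng <- range(v)
  if (rng[1L] == rng[2L])
    stop("cannot auto-threshold a constant image; supply a manual threshold")
  br <- seq(rng[1L], rng[2L], length.out = nb + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nb)
  mids <- (br[-1L] + br[-(nb + 1L)]) / 2
  W <- cumsum(h)
  M <- cumsum(h * mids)
  csum <- function(i, j) {  # class weight and sum over bins (i+1)..j
    w <- W[j] - if (i >= 1L) W[i] else 0
    s <- M[j] - if (i >= 1L) M[i] else 0
    c(w, s)
  }
  best <- -Inf; best_t <- c(NA, NA)
  for (t1 in 1L:(nb - 2L)) {
    c1 <- csum(0L, t1)
    if (c1[1L] == 0) next
    for (t2 in (t1 + 1L):(nb - 1L)) {
      c2 <- csum(t1, t2); c3 <- csum(t2, nb)
      if (c2[1L] == 0 || c3[1L] == 0) next
      m1 <- c1[2L] / c1[1L]; m2 <- c2[2L] / c2[1L]; m3 <- c3[2L] / c3[1L]
      mt <- M[nb] / W[nb]
      bc <- c1[1L] * (m1 - mt)^2 + c2[1L] * (m2 - mt)^2 + c3[1L] * (m3 - mt)^2
      if (bc > best) { best <- bc; best_t <- c(t1, t2) }
    }
  }
  c(mids[best_t[1L]], mids[best_t[2L]])
}

neighbor_stack <- function(m) {
  # clockwise 8-neighborhood starting north: p2..p9 (Zhang-Suen convention)
  list(p2 = shift_mat(m, -1, 0, FALSE), p3 = shift_mat(m, -1, 1, FALSE),
       p4 = shift_mat(m, 0, 1, FALSE), p5 = shift_mat(m, 1, 1, FALSE),
       p6 = shift_mat(m, 1, 0, FALSE), p7 = shift_mat(m, 1, -1, FALSE),
       p8 = shift_mat(m, 0, -1, FALSE), p9 = shift_mat(m, -1, -1, FALSE))
}

# Zhang-Suen topological thinning to a 1-px-wide, 8-connected skeleton.
thin_mask <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p <- neighbor_stack(m)
      B <- p$p2 + p$p3 + p$p4 + p$p5 + p$p6 + p$p7 + p$p8 + p$p9
      seqn <- list(p$p2, p$p3, p$p4, p$p5, p$p6, p$p7, p$p8, p$p9, p$p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (!seqn[[i]] & seqn[[i + 1L]])
      if (pass == 1L) {
        c1 <- !(p$p2 & p$p4 & p$p6)
        c2 <- !(p$p4 & p$p6 & p$p8)
      } else {
        c1 <- !(p$p2 & p$p4 & p$p8)
        c2 <- !(p$p2 & p$p6 & p$p8)
      }
      del <- m & B >= 2 & B <= 6 & A == 1L & c1 & c2
      if (any(del)) {
        m <- m & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Label 8-connected components of a logical mask. Returns an integer matrix
# (0 = background) and the number of components.
label_components <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(list(labels = lab, n = 0L))
  nr <- nrow(mask)
  pos <- matrix(0L, nrow(mask), ncol(mask))
  pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in list(c(-1, 0), c(0, -1), c(-1, -1), c(-1, 1))) {
    nb <- shift_mat(mask, off[1L], off[2L], FALSE)
    both <- which(mask & nb)
    if (length(both)) {
      src <- pos[both]
      tgt_idx <- both - off[1L] - off[2L] * nr
      tgt <- pos[tgt_idx]
      edges <- c(edges, rbind(src, tgt))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  list(labels = lab, n = comp$no)
}

# Skeleton length in pixel units by step counting over unique neighbor
# pairs: 1 per orthogonal step, sqrt(2) per diagonal step, skipping a
# diagonal when its two pixels already share an orthogonal skeleton
# neighbor (corners would otherwise be counted twice).
pair_steps <- function(component_mask) {
  nr <- nrow(component_mask)
  len <- 0
  for (off in list(c(-1, 0), c(0, -1))) {
    nb <- shift_mat(component_mask, off[1L], off[2L], FALSE)
    len <- len + sum(component_mask & nb)
  }
  for (off in list(c(-1, -1), c(-1, 1))) {
    nb <- shift_mat(component_mask, off[1L], off[2L], FALSE)
    pairs <- which(component_mask & nb)
    if (length(pairs)) {
      c1 <- pairs - off[1L]            # shares column step
      c2 <- pairs - off[2L] * nr       # shares row step
      redundant <- component_mask[c1] | component_mask[c2]
      len <- len + sum(!redundant) * sqrt(2)
    }
  }
  len
}

# Fill holes: background components not connected to the image border become
# foreground (4-connectivity for the background).
fill_holes <- function(mask) {
  bg <- !mask
  idx <- which(bg)
  if (length(idx) == 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  pos <- matrix(0L, nr, nc)
  pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in list(c(-1, 0), c(0, -1))) {
    nb <- shift_mat(bg, off[1L], off[2L], FALSE)
    both <- which(bg & nb)
    if (length(both)) {
      src <- pos[both]
      tgt <- pos[both - off[1L] - off[2L] * nr]
      edges <- c(edges, rbind(src, tgt))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  rc <- arrayInd(idx, c(nr, nc))
  on_border <- rc[, 1L] == 1L | rc[, 1L] == nr | rc[, 2L] == 1L | rc[, 2L] == nc
  border_comps <- unique(comp[on_border])
  hole <- !(comp %in% border_comps)
  out <- mask
  out[idx[hole]] <- TRUE
  out
}
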