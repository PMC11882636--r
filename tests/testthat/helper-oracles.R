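# Brute-force reference implementations used as independent oracles.
# These deliberately use straightforward algorithms (explicit loops,
# exhaustive scans) rather than the package's own code paths.

# --- connected components by explicit BFS over a neighbour table --------
oracle_label3d <- function(vol, conn) {
  dims <- dim(vol)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nn <- rowSums(abs(offs))
  offs <- offs[nn > 0 & nn <= switch(as.character(conn), "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, dims)
  nxt <- 0L
  idx <- which(vol)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- arrayInd(cur, dims)
      for (k in seq_len(nrow(offs))) {
        p <- pos + offs[k, ]
        if (any(p < 1) || any(p > dims)) next
        j <- p[1] + dims[1] * (p[2] - 1 + dims[2] * (p[3] - 1))
        if (vol[j] && lab[j] == 0L) {
          lab[j] <- nxt
          stack <- c(stack, j)
        }
      }
    }
  }
  lab
}

# two label maps describe the same partition (numbering may differ)
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# --- exhaustive Yen criterion scan --------------------------------------
oracle_yen_cut <- function(counts) {
  p <- counts / sum(counts)
  n <- length(p)
  best <- -Inf
  bt <- NA_integer_
  for (t in seq_len(n - 1)) {
    P1 <- sum(p[1:t])
    S1 <- sum(p[1:t]^2)
    S2 <- sum(p[(t + 1):n]^2)
    if (P1 <= 0 || P1 >= 1 || S1 <= 0 || S2 <= 0) next
    tc <- -log((S1 * S2) / (P1^2 * (1 - P1)^2))
    if (tc > best) { best <- tc; bt <- t }
  }
  bt
}

oracle_yen_crit <- function(counts, t) {
  p <- counts / sum(counts)
  n <- length(p)
  P1 <- sum(p[1:t]); S1 <- sum(p[1:t]^2); S2 <- sum(p[(t + 1):n]^2)
  -log((S1 * S2) / (P1^2 * (1 - P1)^2))
}

# --- grayscale opening by a ball element via shifted matrices -----------
shift_pad <- function(m, dy, dx, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

oracle_ball_opening <- function(img, radius) {
  r <- floor(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  h <- sqrt(radius^2 - offs$dy^2 - offs$dx^2) - radius
  ero <- matrix(Inf, nrow(img), ncol(img))
  for (k in seq_len(nrow(offs))) {
    ero <- pmin(ero, shift_pad(img, -offs$dy[k], -offs$dx[k], Inf) - h[k])
  }
  dil <- matrix(-Inf, nrow(img), ncol(img))
  for (k in seq_len(nrow(offs))) {
    dil <- pmax(dil, shift_pad(ero, offs$dy[k], offs$dx[k], -Inf) + h[k])
  }
  dil
}

# --- distances ----------------------------------------------------------
oracle_feret <- function(pixels, pixel_size = 1) {
  corners <- rbind(
    cbind(pixels[, 1], pixels[, 2]), cbind(pixels[, 1] + 1, pixels[, 2]),
    cbind(pixels[, 1], pixels[, 2] + 1), cbind(pixels[, 1] + 1, pixels[, 2] + 1))
  best <- 0
  for (i in seq_len(nrow(corners))) {
    d <- sqrt((corners[, 1] - corners[i, 1])^2 + (corners[, 2] - corners[i, 2])^2)
    best <- max(best, max(d))
  }
  best * pixel_size
}

# Cauchy mean-width perimeter of the pixel-corner hull by numerical
# integration over caliper angles
oracle_hull_perimeter <- function(pixels, n_angles = 1440) {
  corners <- rbind(
    cbind(pixels[, 1], pixels[, 2]), cbind(pixels[, 1] + 1, pixels[, 2]),
    cbind(pixels[, 1], pixels[, 2] + 1), cbind(pixels[, 1] + 1, pixels[, 2] + 1))
  th <- seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)]
  widths <- vapply(th, function(a) {
    p <- corners[, 1] * cos(a) + corners[, 2] * sin(a)
    max(p) - min(p)
  }, numeric(1))
  pi * mean(widths)
}

# brute-force Euclidean disk dilation
oracle_dilate <- function(mask, radius) {
  w <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    d2 <- (w[, 1] - i)^2 + (w[, 2] - j)^2
    out[i, j] <- any(d2 <= radius^2)
  }
  out
}

# brute-force signed Euclidean distance (positive inside, zero level at
# the half-pixel boundary between pixel centers)
oracle_signed_distance <- function(m) {
  fg <- which(m, arr.ind = TRUE)
  bg <- which(!m, arr.ind = TRUE)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j]) {
      out[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2)) - 0.5
    } else {
      out[i, j] <- -(sqrt(min((fg[, 1] - i)^2 + (fg[, 2] - j)^2)) - 0.5)
    }
  }
  out
}

# --- small fixtures -----------------------------------------------------
disk_mask <- function(radius, n, center = c(n / 2, n / 2)) {
  d2 <- outer((seq_len(n) - 0.5 - center[1])^2,
              (seq_len(n) - 0.5 - center[2])^2, `+`)
  d2 <= radius^2
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
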