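# Brute-force definitional oracles, implemented independently of the
# package internals (plain R loops), used to validate the morphology,
# watershed and matching primitives.

shift_mat <- function(m, dx, dy, fill) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(fill, nx, ny)
  xs <- seq_len(nx) + dx; ys <- seq_len(ny) + dy
  okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

bf_erode <- function(px, se) {
  nx <- nrow(px); ny <- ncol(px)
  out <- matrix(NA_real_, nx, ny)
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    qx <- x + se[, 1]; qy <- y + se[, 2]
    ok <- qx >= 1 & qx <= nx & qy >= 1 & qy <= ny
    out[x, y] <- min(px[cbind(qx[ok], qy[ok])])
  }
  out
}

bf_dilate <- function(px, se) {
  nx <- nrow(px); ny <- ncol(px)
  out <- matrix(NA_real_, nx, ny)
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    qx <- x + se[, 1]; qy <- y + se[, 2]
    ok <- qx >= 1 & qx <= nx & qy >= 1 & qy <= ny
    out[x, y] <- max(px[cbind(qx[ok], qy[ok])])
  }
  out
}

bf_open <- function(px, se) bf_dilate(bf_erode(px, se), -se)
bf_close <- function(px, se) bf_erode(bf_dilate(px, se), -se)

# grayscale reconstruction by dilation: iterate 8-neighbour dilation under
# the mask until stable
bf_reconstruct <- function(marker, mask) {
  f <- pmin(marker, mask)
  repeat {
    d <- f
    for (dx in -1:1) for (dy in -1:1)
      d <- pmax(d, shift_mat(f, dx, dy, -Inf))
    d <- pmin(d, mask)
    if (identical(d, f)) return(f)
    f <- d
  }
}

bf_hdome <- function(px, h) px - bf_reconstruct(px - h, px)

# regional maxima as a logical mask: plateau flood + strict dominance test
bf_regional_maxima_mask <- function(px, conn = 8) {
  nx <- nrow(px); ny <- ncol(px)
  offs <- if (conn == 8) expand.grid(dx = -1:1, dy = -1:1)[-5, ]
          else data.frame(dx = c(0, -1, 1, 0), dy = c(-1, 0, 0, 1))
  seen <- matrix(FALSE, nx, ny)
  out <- matrix(FALSE, nx, ny)
  for (p0 in seq_len(nx * ny)) {
    if (seen[p0]) next
    v <- px[p0]
    plateau <- p0; seen[p0] <- TRUE
    stack <- p0
    is_max <- TRUE
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      x <- (p - 1) %% nx + 1; y <- (p - 1) %/% nx + 1
      for (k in seq_len(nrow(offs))) {
        qx <- x + offs$dx[k]; qy <- y + offs$dy[k]
        if (qx < 1 || qx > nx || qy < 1 || qy > ny) next
        q <- qx + (qy - 1) * nx
        if (px[q] > v) is_max <- FALSE
        else if (px[q] == v && !seen[q]) {
          seen[q] <- TRUE; plateau <- c(plateau, q); stack <- c(stack, q)
        }
      }
    }
    if (length(plateau) == nx * ny) is_max <- FALSE
    if (is_max) out[plateau] <- TRUE
  }
  out
}

# naive Meyer flooding (4-connected), linear-scan priority selection;
# assumes distinct relief values so the pop order is unambiguous
bf_watershed <- function(relief, markers) {
  nx <- nrow(relief); ny <- ncol(relief)
  lab <- markers
  state <- matrix(0L, nx, ny)
  state[markers > 0] <- 2L
  qpix <- integer(0)
  nbrs <- function(p) {
    x <- (p - 1) %% nx + 1; y <- (p - 1) %/% nx + 1
    q <- c(if (y > 1) p - nx, if (x > 1) p - 1,
           if (x < nx) p + 1, if (y < ny) p + nx)
    q
  }
  for (p in which(state == 2L)) for (q in nbrs(p))
    if (state[q] == 0L) { state[q] <- 1L; qpix <- c(qpix, q) }
  while (length(qpix)) {
    i <- which.min(relief[qpix])
    p <- qpix[i]; qpix <- qpix[-i]
    ls <- unique(lab[nbrs(p)])
    ls <- ls[ls > 0L]
    state[p] <- 2L
    if (length(ls) == 1L) {
      lab[p] <- ls
      for (q in nbrs(p)) if (state[q] == 0L) { state[q] <- 1L; qpix <- c(qpix, q) }
    }
  }
  lab
}

# exhaustive maximum-cardinality one-to-one matching given a logical
# truth x pred adjacency matrix
bf_max_matching <- function(adj) {
  nt <- nrow(adj); np <- ncol(adj)
  if (nt == 0 || np == 0) return(0L)
  best <- 0L
  rec <- function(i, used, cnt) {
    if (cnt + (nt - i + 1L) <= best) return()
    if (i > nt) { best <<- max(best, cnt); return() }
    rec(i + 1L, used, cnt)
    for (j in which(adj[i, ] & !used)) {
      used[j] <- TRUE
      rec(i + 1L, used, cnt + 1L)
      used[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, np), 0L)
  best
}

# dense 2-D convolution with symmetric (mirror) padding, direct evaluation
bf_gauss_blur <- function(px, sigma, h) {
  k1 <- exp(-((-h:h)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  nx <- nrow(px); ny <- ncol(px)
  idx <- function(i, n) { # symmetric reflection abba
    i <- ((i - 1) %% (2 * n))
    ifelse(i < n, i + 1, 2 * n - i)
  }
  out <- matrix(0, nx, ny)
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    s <- 0
    for (a in -h:h) for (b in -h:h)
      s <- s + K[a + h + 1, b + h + 1] * px[idx(x + a, nx), idx(y + b, ny)]
    out[x, y] <- s
  }
  out
}
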