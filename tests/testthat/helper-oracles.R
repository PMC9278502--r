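# Independent oracles used across tests. These deliberately use naive
# O(n^2)/exhaustive formulations, not the package's own code paths.

# exhaustive Otsu: minimize total within-class variance over every split
# (<= s vs > s), s = 0..254; ties resolved by the plateau midpoint
otsu_bruteforce <- function(raster) {
  v <- pmin(pmax(round(as.numeric(raster)), 0), 255)
  ssw <- vapply(0:254, function(s) {
    a <- v[v <= s]; b <- v[v > s]
    if (!length(a) || !length(b)) return(Inf)
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, 0)
  cand <- (0:254)[ssw == min(ssw)]
  mean(cand)
}

# naive k x k median filter with replicate padding
median_naive <- function(m, k = 3) {
  half <- (k - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(rep(1, half), seq_len(nr), rep(nr, half)),
           c(rep(1, half), seq_len(nc), rep(nc, half))]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- stats::median(pad[i:(i + k - 1), j:(j + k - 1)])
  out
}

# smallest pairwise distance by the O(n^2) definition
min_pairwise_dist <- function(x, y) {
  n <- length(x)
  if (n < 2) return(Inf)
  mn <- Inf
  for (i in seq_len(n - 1))
    mn <- min(mn, sqrt((x[(i + 1):n] - x[i])^2 + (y[(i + 1):n] - y[i])^2))
  mn
}

# number of intersecting axis-aligned tile rectangles, O(n^2)
count_tile_overlaps <- function(x, y, tw, th) {
  n <- length(x); cnt <- 0L
  if (n < 2) return(0L)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x[i] < x[j] + tw && x[j] < x[i] + tw &&
        y[i] < y[j] + th && y[j] < y[i] + th) cnt <- cnt + 1L
  }
  cnt
}

# mean silhouette width of a 2-group labelling in a 2D embedding
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# direct additive recomposition of cleaned planes with their colors
recompose_rgb <- function(cleaned, palette) {
  d <- dim(cleaned)
  rgb <- array(0, c(d[1], d[2], 3))
  for (i in seq_len(d[3])) {
    col <- as.numeric(grDevices::col2rgb(palette[i])) / 255
    for (p in 1:3) rgb[, , p] <- rgb[, , p] + cleaned[, , i] * col[p]
  }
  array(as.integer(pmin(round(rgb), 255)), dim(rgb))
}
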