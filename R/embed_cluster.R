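#' Abstract an image to its first six channel means
#'
#' The inbuilt fallback (used when the user supplies neither embedding
#' coordinates nor cluster labels) represents each image by a vector of
#' length 6 holding the arithmetic means of its initial six channels, in
#' stored plane order, computed on the raw (uncleaned) intensities. Images
#' with fewer than six channels are zero-padded with a warning so the
#' cohort feature matrix stays rectangular.
#'
#' @param image a [multiplex_image()].
#' @return numeric vector of length 6.
#' @export
image_feature_vector <- function(image) {
  stopifnot(inherits(image, "multiplex_image"))
  n_ch <- dim(image$channels)[3]
  use <- min(6L, n_ch)
  v <- vapply(seq_len(use), function(c) mean(image$channels[, , c]), 0)
  if (n_ch < 6L) {
    warning(sprintf("image '%s' has %d channel(s); padding feature vector with zeros",
                    image$image_id, n_ch), call. = FALSE)
    v <- c(v, rep(0, 6L - n_ch))
  }
  v
}

#' Cohort feature matrix
#'
#' @param images list of [multiplex_image()] (cohort order).
#' @return tibble with `image_id` and `ch_mean1`..`ch_mean6`.
#' @export
feature_matrix <- function(images) {
  m <- t(vapply(images, image_feature_vector, numeric(6)))
  colnames(m) <- paste0("ch_mean", 1:6)
  dplyr::bind_cols(
    tibble::tibble(image_id = vapply(images, function(im) im$image_id, "")),
    tibble::as_tibble(m))
}

feature_numeric <- function(features) {
  if (is.matrix(features)) return(features)
  as.matrix(dplyr::select(features, dplyr::where(is.numeric)))
}

#' 2D embedding of the cohort feature matrix (exact t-SNE)
#'
#' Exact (all-pairs) t-SNE: input similarities are Gaussian with per-point
#' bandwidths calibrated by bisection to the target perplexity; the
#' low-dimensional map minimizes the Kullback-Leibler divergence to the
#' Student-t similarities by momentum gradient descent with early
#' exaggeration. Cohorts here are tens to a few hundred images, so the
#' quadratic algorithm is the right tool. Deterministic given `seed`.
#'
#' @param features tibble with `image_id` plus numeric feature columns (as
#'   from [feature_matrix()]), or a plain numeric matrix.
#' @param perplexity target perplexity; default `min(30, (n - 1) / 3)`.
#'   Values too large for the cohort are reduced to `max(2, (n - 1) / 3)`
#'   with a warning.
#' @param seed integer seed.
#' @param n_iter gradient-descent iterations.
#' @return tibble with `image_id`, `x`, `y` (ids are `"row1"`.. when
#'   `features` is a bare matrix).
#' @export
embed_2d <- function(features, perplexity = NULL, seed = 42, n_iter = 500) {
  X <- feature_numeric(features)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 rows to embed", call. = FALSE)
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  if (perplexity >= n) {
    perplexity <- max(2, (n - 1) / 3)
    warning(sprintf("perplexity too large for %d rows; reduced to %g", n, perplexity),
            call. = FALSE)
  }
  ids <- if (is.matrix(features)) paste0("row", seq_len(n)) else features$image_id
  Y <- tsne_exact(X, perplexity = perplexity, seed = seed, n_iter = n_iter)
  tibble::tibble(image_id = ids, x = Y[, 1], y = Y[, 2])
}

# exact t-SNE core; returns an n x 2 matrix
tsne_exact <- function(X, perplexity, seed, n_iter = 500,
                       exaggeration = 12, exag_iter = 100, eta = NULL) {
  n <- nrow(X)
  # learning rate scaled to the problem (the usual n / (4 * exaggeration)
  # rule, floored at 50); a fixed large rate makes small maps oscillate
  if (is.null(eta)) eta <- max(n / (4 * exaggeration), 50)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1
    for (it in 1:64) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        p <- p / sp
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - logU) < 1e-7) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (lo + hi) / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withr::with_seed(as.integer(seed), {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  })
  V <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= exag_iter) P * exaggeration else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 250) 0.5 else 0.8
    gains <- pmax(0.01, ifelse(sign(grad) != sign(V), gains + 0.2, gains * 0.8))
    V <- mom * V - eta * gains * grad
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Variational Bayesian Gaussian-mixture clustering
#'
#' Fits a Gaussian mixture with a truncated stick-breaking (Dirichlet
#' process) prior on the weights and Gauss-Wishart priors on the component
#' parameters, by mean-field variational inference. Superfluous components
#' receive vanishing weight, so the effective number of clusters is
#' inferred rather than fixed; `max_components` is only the truncation
#' level. Labels are the most probable component per row, renumbered
#' 0-based in order of first appearance. Deterministic given `seed`
#' (k-means initialization of the responsibilities).
#'
#' @param features tibble with `image_id` plus numeric columns, or a
#'   numeric matrix.
#' @param max_components truncation level of the mixture (>= 1).
#' @param seed integer seed.
#' @param max_iter maximum variational iterations.
#' @param tol convergence tolerance on the responsibilities.
#' @return integer vector of 0-based labels with attribute
#'   `n_components_used`. A degenerate fit (singular covariance update)
#'   falls back to a single cluster with a warning.
#' @export
cluster_vbgmm <- function(features, max_components = 10, seed = 42,
                          max_iter = 200, tol = 1e-5) {
  X <- feature_numeric(features)
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stop("need at least 2 rows to cluster", call. = FALSE)
  K <- max(1L, as.integer(max_components))
  if (K == 1L)
    return(structure(rep(0L, n), n_components_used = 1L))
  labels <- tryCatch(
    vbgmm_fit(X, K, seed = seed, max_iter = max_iter, tol = tol),
    error = function(e) {
      warning(sprintf("degenerate mixture fit (%s); falling back to one cluster",
                      conditionMessage(e)), call. = FALSE)
      rep(0L, n)
    })
  structure(labels, n_components_used = length(unique(labels)))
}

vbgmm_fit <- function(X, K, seed, max_iter, tol) {
  n <- nrow(X); d <- ncol(X)
  gamma0 <- 1 / K          # stick-breaking concentration
  beta0 <- 1
  m0 <- colMeans(X)
  nu0 <- d
  # covariance prior at the cohort's empirical per-axis variance
  W0inv <- nu0 * diag(apply(X, 2, stats::var) + 1e-6, d)
  # initial responsibilities: hard k-means assignment (uniform if k-means
  # cannot run, e.g. on identical rows)
  r <- withr::with_seed(as.integer(seed), {
    K_init <- min(K, nrow(unique(X)))
    km <- tryCatch(stats::kmeans(X, centers = K_init, nstart = 5),
                   error = function(e) NULL)
    if (is.null(km)) matrix(1 / K, n, K) else {
      rr <- matrix(1e-6, n, K)
      rr[cbind(seq_len(n), km$cluster)] <- 1
      rr / rowSums(rr)
    }
  })
  for (iter in seq_len(max_iter)) {
    # update variational posteriors
    Nk <- colSums(r) + 1e-10
    xbar <- t(r) %*% X / Nk
    betak <- beta0 + Nk
    nuk <- nu0 + Nk
    mk <- (beta0 * matrix(m0, K, d, byrow = TRUE) + Nk * xbar) / betak
    a <- 1 + Nk
    b <- gamma0 + rev(cumsum(rev(Nk))) - Nk      # sum over j > k
    elog_v <- digamma(a) - digamma(a + b)
    elog_1mv <- digamma(b) - digamma(a + b)
    elog_pi <- elog_v + c(0, cumsum(elog_1mv)[-K])
    logdetW <- numeric(K)
    Wk <- vector("list", K)
    for (k in seq_len(K)) {
      xc <- sweep(X, 2, xbar[k, ])
      Sk <- t(xc * r[, k]) %*% xc / Nk[k]
      dm <- xbar[k, ] - m0
      Winv <- W0inv + Nk[k] * Sk +
        (beta0 * Nk[k] / (beta0 + Nk[k])) * tcrossprod(dm)
      ch <- chol(Winv)     # errors on singular update -> caller fallback
      logdetW[k] <- -2 * sum(log(diag(ch)))
      Wk[[k]] <- chol2inv(ch)
    }
    elog_lambda <- vapply(seq_len(K), function(k)
      sum(digamma((nuk[k] + 1 - seq_len(d)) / 2)) + d * log(2) + logdetW[k], 0)
    # responsibilities
    logrho <- matrix(0, n, K)
    for (k in seq_len(K)) {
      xc <- sweep(X, 2, mk[k, ])
      quad <- d / betak[k] + nuk[k] * rowSums((xc %*% Wk[[k]]) * xc)
      logrho[, k] <- elog_pi[k] + 0.5 * elog_lambda[k] -
        d / 2 * log(2 * pi) - 0.5 * quad
    }
    mx <- apply(logrho, 1, max)
    r_new <- exp(logrho - mx)
    r_new <- r_new / rowSums(r_new)
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) break
  }
  raw <- max.col(r, ties.method = "first")
  as.integer(match(raw, unique(raw))) - 1L
}

#' Inbuilt embedding + clustering fallback
#'
#' Runs the whole fallback: channel-mean feature vectors, exact t-SNE
#' embedding, variational-mixture clustering. Triggered by the pipeline
#' when neither a coordinate file nor cluster metadata is available; the
#' cluster labels then populate the "cluster" live-canvas category.
#'
#' @param images list of [multiplex_image()].
#' @param max_components mixture truncation level.
#' @param perplexity forwarded to [embed_2d()].
#' @param seed integer seed.
#' @return an `embedding_result`: tibble with `image_id`, `x`, `y`,
#'   `cluster` (0-based integer), with attributes `n_components_used` and
#'   `seed`.
#' @export
embed_and_cluster <- function(images, max_components = 10, perplexity = NULL,
                              seed = 42) {
  fm <- feature_matrix(images)
  coords <- embed_2d(fm, perplexity = perplexity, seed = seed)
  labels <- cluster_vbgmm(fm, max_components = max_components, seed = seed)
  res <- dplyr::mutate(coords, cluster = as.integer(labels))
  structure(res,
            class = c("embedding_result", class(res)),
            n_components_used = attr(labels, "n_components_used"),
            seed = as.integer(seed))
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d image(s), %d cluster(s), seed %d\n",
              nrow(x), attr(x, "n_components_used"), attr(x, "seed")))
  NextMethod()
}

#' Tidy an embedding result
#' @param x an `embedding_result`.
#' @param ... unused.
#' @return plain tibble with `image_id`, `x`, `y`, `cluster`.
#' @export
tidy.embedding_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("image_id", "x", "y", "cluster")])
}

#' One-row summary of an embedding result
#' @param x an `embedding_result`.
#' @param ... unused.
#' @return tibble with `n_images`, `n_components_used`, `seed`.
#' @export
glance.embedding_result <- function(x, ...) {
  tibble::tibble(n_images = nrow(x),
                 n_components_used = attr(x, "n_components_used"),
                 seed = attr(x, "seed"))
}

#' @importFrom generics tidy glance
NULL

#' Scatterplot of an embedding result
#' @param object an `embedding_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.embedding_result <- function(object, ...) {
  df <- tidy(object)
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", color = "cluster") +
    ggplot2::theme_minimal()
}
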