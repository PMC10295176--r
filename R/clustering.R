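# Motion-class discovery: z-scored features -> 2-D t-SNE embedding ->
# DBSCAN density clustering.  Exact (non-Barnes-Hut) t-SNE and a distance-
# matrix DBSCAN are implemented here; trajectory sets are small (hundreds),
# so the quadratic cost is immaterial.

# conditional probabilities for one row via binary search on the precision
.tsnePerplexityRow <- function(d2row, perplexity, tol = 1e-5) {
  beta <- 1
  lo <- -Inf; hi <- Inf
  logU <- log(perplexity)
  for (it in 1:50) {
    p <- exp(-d2row * beta)
    sumP <- sum(p)
    if (sumP == 0) sumP <- .Machine$double.eps
    H <- log(sumP) + beta * sum(d2row * p) / sumP
    diffH <- H - logU
    if (abs(diffH) < tol) break
    if (diffH > 0) {
      lo <- beta
      beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
    } else {
      hi <- beta
      beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
    }
  }
  p / sum(p)
}

#' Exact t-SNE embedding
#'
#' Standard exact t-distributed stochastic neighbour embedding (perplexity
#' calibration by binary search, early exaggeration, momentum gradient
#' descent).  Deterministic for a fixed seed.
#'
#' @param X numeric matrix (rows = observations)
#' @param dims embedding dimension (default 2)
#' @param perplexity perplexity (default 30, reduced automatically when the
#'   sample is too small)
#' @param maxIter gradient-descent iterations (default 1000)
#' @param seed integer seed for the random initialisation
#' @return matrix (nrow(X) x dims)
#' @export
tsneEmbed <- function(X, dims = 2, perplexity = 30, maxIter = 1000,
                      seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("too few rows for an embedding")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  set.seed(seed)
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  for (i in seq_len(n))
    P[i, -i] <- .tsnePerplexityRow(D2[i, -i], perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
  dY <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  exag <- 12
  momentum <- 0.5
  eta <- 200
  for (iter in seq_len(maxIter)) {
    Pe <- if (iter <= 100) P * exag else P
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    if (iter == 250) momentum <- 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' DBSCAN clustering from a distance matrix
#'
#' Classic density-based clustering: core points have at least `minPts`
#' neighbours (self included) within `eps`; clusters are the connected
#' components of core points plus their border points; everything else is
#' noise (label 0).
#'
#' @param X numeric matrix of observations (rows)
#' @param eps neighbourhood radius
#' @param minPts minimum neighbourhood size (default 5)
#' @return integer vector of cluster labels, 0 = noise
#' @export
dbscanCluster <- function(X, eps, minPts = 5) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= minPts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- union(queue, setdiff(nb[[j]], j))
      }
    }
  }
  labels
}

# k-distance elbow: point of maximum distance to the chord between the
# endpoints of the sorted k-NN distance curve
.kDistElbow <- function(X, k) {
  D <- as.matrix(dist(X))
  kd <- sort(apply(D, 1, function(r) sort(r)[k + 1]))
  n <- length(kd)
  x <- seq_len(n)
  x0 <- c(1, kd[1]); x1 <- c(n, kd[n])
  v <- x1 - x0
  v <- v / sqrt(sum(v^2))
  d <- vapply(seq_len(n), function(i) {
    w <- c(x[i], kd[i]) - x0
    abs(w[1] * v[2] - w[2] * v[1])
  }, numeric(1))
  kd[which.max(d)]
}

#' Embed trajectory features and cluster into motion classes
#'
#' z-scores the feature columns, embeds with [tsneEmbed()], clusters the
#' embedding with [dbscanCluster()], and flags clusters holding less than
#' `minClusterFrac` of the trajectories as excluded from downstream MSD
#' analysis.  Noise points get label -1 (DBSCAN's noise), reported as is.
#'
#' @param features data.frame from [featureTable()] (track_id + feature
#'   columns) or a plain numeric matrix
#' @param perplexity t-SNE perplexity (default 30)
#' @param maxIter t-SNE iterations (default 1000)
#' @param eps DBSCAN radius in embedding units; default: k-distance elbow
#' @param minPts DBSCAN minimum neighbourhood size (default 5)
#' @param minClusterFrac clusters below this fraction of trajectories are
#'   flagged excluded (default 0.04)
#' @param seed integer seed (embedding initialisation)
#' @return list with `labels` (integer, -1 = noise), `embedding`,
#'   `excluded` (cluster ids), `eps`
#' @export
embedAndCluster <- function(features, perplexity = 30, maxIter = 1000,
                            eps = NULL, minPts = 5, minClusterFrac = 0.04,
                            seed = 1) {
  X <- features
  if (is.data.frame(X)) X <- as.matrix(X[setdiff(names(X), "track_id")])
  if (nrow(X) < minPts) stop("fewer rows than minPts: cannot cluster")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Y <- tsneEmbed(Z, perplexity = perplexity, maxIter = maxIter, seed = seed)
  if (is.null(eps)) eps <- .kDistElbow(Y, minPts - 1)
  lab <- dbscanCluster(Y, eps = eps, minPts = minPts)
  labels <- ifelse(lab == 0L, -1L, lab)
  tab <- table(labels[labels > 0])
  excluded <- as.integer(names(tab)[tab / length(labels) < minClusterFrac])
  list(labels = labels, embedding = Y, excluded = excluded, eps = eps)
}
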