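# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. All exported simulators funnel their `seed` through here.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Dirichlet-multinomial draw of one bin's guide counts. dispersion = 0
# collapses to a plain multinomial; otherwise alpha = prob/dispersion, so
# smaller dispersion means tighter concentration around `prob`. Either way
# the draw sums to `depth` exactly.
.rdirmult <- function(depth, prob, dispersion = 0) {
  prob <- prob / sum(prob)
  if (dispersion <= 0) return(as.vector(stats::rmultinom(1, depth, prob)))
  w <- stats::rgamma(length(prob), shape = prob / dispersion)
  if (sum(w) <= 0) w <- prob
  as.vector(stats::rmultinom(1, depth, w / sum(w)))
}

# k-means with k-means++ seeding and random restarts; returns the
# stats::kmeans fit with the lowest total within-cluster sum of squares.
# The caller owns the RNG state.
.kmeanspp <- function(x, k, nstart = 50, iter.max = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k = ", k, " exceeds the number of observations (", n, ")")
  if (k == 1) {
    center <- matrix(colMeans(x), 1, dimnames = list(NULL, colnames(x)))
    ss <- sum(sweep(x, 2, center[1, ])^2)
    return(list(cluster = setNames(rep(1L, n), rownames(x)),
                centers = center, tot.withinss = ss))
  }
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- matrix(NA_real_, k, ncol(x))
    i <- sample.int(n, 1)
    centers[1, ] <- x[i, ]
    d2 <- rowSums(sweep(x, 2, x[i, ])^2)
    for (j in seq_len(k)[-1]) {
      i <- if (sum(d2) > 0) sample.int(n, 1, prob = d2)
           else sample(setdiff(seq_len(n), i), 1)
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[i, ])^2))
    }
    if (anyDuplicated(centers)) next
    fit <- tryCatch(stats::kmeans(x, centers, iter.max = iter.max),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))  # all restarts degenerate (e.g. tied points): fall back
    best <- stats::kmeans(x, k, nstart = nstart, iter.max = iter.max)
  best$cluster <- setNames(best$cluster, rownames(x))
  best
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
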