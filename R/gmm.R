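# Gaussian-mixture machinery for array subtyping. EM is implemented here
# (rather than delegated) because the subtyping contract requires seeded
# multi-start initialization, a per-iteration log-likelihood trace, and a
# BIC choice between full and diagonal covariance at fixed k.

log_dmvnorm2 <- function(x, mean, cov) {
  # x: n x d; returns log density vector (closed form for d = 2)
  d <- ncol(x)
  if (d == 2) {
    a <- cov[1, 1]; b <- cov[1, 2]; cc <- cov[2, 2]
    det <- a * cc - b * b
    if (det <= 1e-12 || a <= 0) {
      a <- a + 1e-6; cc <- cc + 1e-6
      det <- a * cc - b * b
    }
    dx <- x[, 1] - mean[1]
    dy <- x[, 2] - mean[2]
    q <- (cc * dx * dx - 2 * b * dx * dy + a * dy * dy) / det
    return(-log(2 * pi) - 0.5 * log(det) - 0.5 * q)
  }
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch)) {
    cov <- cov + diag(1e-6, d)
    ch <- chol(cov)
  }
  xc <- sweep(x, 2, mean)
  z <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

em_once <- function(x, k, cov_type, init_means, max_iter, tol) {
  n <- nrow(x)
  d <- ncol(x)
  means <- init_means
  covs <- replicate(k, diag(apply(x, 2, stats::var) + 1e-6, d),
                    simplify = FALSE)
  weights <- rep(1 / k, k)
  loglik_trace <- numeric(0)
  prev <- -Inf
  resp <- NULL
  logd <- matrix(0, nrow = n, ncol = k)
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      logd[, j] <- log(weights[j]) + log_dmvnorm2(x, means[j, ], covs[[j]])
    }
    mx <- do.call(pmax, as.data.frame(logd))
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    resp <- exp(logd - lse)
    if (is.finite(prev) && abs(ll - prev) < tol) break
    prev <- ll
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    weights <- nk / n
    means <- t(vapply(seq_len(k), function(j) {
      colSums(resp[, j] * x) / nk[j]
    }, numeric(d)))
    covs <- lapply(seq_len(k), function(j) {
      xc <- sweep(x, 2, means[j, ])
      cv <- crossprod(xc * resp[, j], xc) / nk[j]
      if (cov_type == "diagonal") cv <- diag(diag(cv), d)
      if (any(diag(cv) < 1e-8)) cv <- cv + diag(1e-6, d)
      cv
    })
  }
  list(loglik = loglik_trace[length(loglik_trace)],
       loglik_trace = loglik_trace, weights = weights, means = means,
       covs = covs, resp = resp)
}

#' Fit a Gaussian mixture model to standardized accessibility features
#'
#' Expectation-maximization with `n_starts` seeded random initializations
#' (best final log-likelihood kept), run to convergence (absolute
#' log-likelihood change below `tol`, or `max_iter` iterations). Both a
#' full-covariance and a diagonal-covariance variant are fitted and the
#' winner is chosen by lower BIC. Components with near-singular
#' covariance are ridge-regularized.
#'
#' @param x A numeric matrix or data frame of points (rows) by features
#'   (columns); typically the `(iae_z, bps_z)` plane.
#' @param k Number of mixture components.
#' @param seed Integer seed controlling the restarts.
#' @param n_starts Number of random restarts per covariance type.
#' @param max_iter,tol EM stopping controls.
#' @return An object of class `nurepress_gmm` with weights, means,
#'   covariances, responsibilities, hard `labels`, per-iteration
#'   `loglik_trace`, and `bic`.
#' @export
fit_gmm <- function(x, k, seed = 17L, n_starts = 10L, max_iter = 500L,
                    tol = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 3 * k) abort("fit_gmm needs at least 3*k points")
  fits <- list()
  for (cov_type in c("full", "diagonal")) {
    best <- NULL
    set.seed(seed)
    for (s in seq_len(n_starts)) {
      init <- x[sample.int(n, k), , drop = FALSE]
      fit <- em_once(x, k, cov_type, init, max_iter, tol)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    d <- ncol(x)
    npar <- (k - 1) + k * d + k * (if (cov_type == "full") d * (d + 1) / 2 else d)
    best$bic <- -2 * best$loglik + npar * log(n)
    best$cov_type <- cov_type
    fits[[cov_type]] <- best
  }
  win <- fits[[which.min(vapply(fits, function(f) f$bic, numeric(1)))]]
  labels <- apply(win$resp, 1, which.max) # first max on ties -> lower index
  structure(
    list(k = k, cov_type = win$cov_type, weights = win$weights,
         means = win$means, covs = win$covs, responsibilities = win$resp,
         labels = labels, loglik = win$loglik,
         loglik_trace = win$loglik_trace, bic = win$bic,
         bic_by_type = vapply(fits, function(f) f$bic, numeric(1)),
         seed = seed, n = n),
    class = "nurepress_gmm"
  )
}

#' @export
print.nurepress_gmm <- function(x, ...) {
  cat(sprintf("<nurepress_gmm> k = %d (%s covariance), n = %d, logLik = %.3f, BIC = %.2f\n",
              x$k, x$cov_type, x$n, x$loglik, x$bic))
  invisible(x)
}

#' Mean silhouette coefficient
#'
#' For each point, `a` is its mean distance to its own cluster (excluding
#' itself), `b` the minimum over other clusters of the mean distance to
#' that cluster, and `s = (b - a) / max(a, b)`. Members of singleton
#' clusters score 0 by convention, as do points coincident with both their
#' own and the nearest foreign cluster. Distances are Euclidean in the
#' feature plane.
#'
#' @param x Numeric matrix or data frame of points.
#' @param labels Cluster assignment vector (at least two distinct values).
#' @return The mean silhouette over all points.
#' @export
mean_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.vector(labels)
  cl <- unique(labels)
  if (length(cl) < 2) abort("silhouette is undefined for a single cluster")
  dmat <- as.matrix(stats::dist(x))
  n <- nrow(x)
  sizes <- table(labels)
  s <- vapply(seq_len(n), function(i) {
    own <- labels[i]
    if (sizes[[as.character(own)]] == 1) return(0)
    a <- mean(dmat[i, labels == own & seq_len(n) != i])
    b <- min(vapply(setdiff(cl, own), function(oc) {
      mean(dmat[i, labels == oc])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Select accessibility subtypes by silhouette-maximizing mixture fit
#'
#' Fits a Gaussian mixture for every candidate number of components,
#' derives hard labels (maximum posterior responsibility, ties to the
#' lower index), scores each solution by the mean silhouette coefficient
#' in the standardized IAE-BPS plane, and keeps the k that maximizes it
#' (ties favor the smaller k). Within each k, the covariance structure is
#' chosen by BIC. Cluster names are anchored to the two phenotypes and
#' stable across seeds: `C1` is the cluster with the lowest mean
#' standardized IAE (the boundary-transition archetype), `C2` the one
#' with the highest (the accessibility-uniform archetype); any
#' intermediate clusters are named `C3..Ck` in ascending IAE order.
#'
#' @param features Tibble with `array_id`, `iae_z`, `bps_z` (see
#'   [zscore_features()]).
#' @param k_range Candidate numbers of subtypes (default 2:6; truncated
#'   with a warning when there are fewer than `3 * max(k_range)` arrays).
#' @param seed Integer seed for the mixture fits.
#' @param n_starts Restarts per fit.
#' @return An object of class `nurepress_subtypes`: the chosen `k`,
#'   per-array `assignments` (with `subtype` labels `C1..Ck`), the winning
#'   `model`, and per-k `silhouette` / `bic` diagnostics.
#' @export
select_subtypes <- function(features, k_range = 2:6, seed = 17L,
                            n_starts = 10L) {
  stop_missing_cols(features, c("array_id", "iae_z", "bps_z"), "feature table")
  n <- nrow(features)
  k_range <- sort(unique(as.integer(k_range)))
  feasible <- k_range[n >= 3L * k_range]
  if (length(feasible) < length(k_range)) {
    warn(sprintf("k range truncated to {%s}: only %d arrays",
                 paste(feasible, collapse = ","), n))
    k_range <- feasible
  }
  if (length(k_range) == 0) abort("too few arrays for any candidate k")
  x <- as.matrix(features[, c("iae_z", "bps_z")])
  fits <- list()
  sils <- rep(NA_real_, length(k_range))
  bics <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- fit_gmm(x, k, seed = seed, n_starts = n_starts)
    fits[[i]] <- fit
    bics[i] <- fit$bic
    if (length(unique(fit$labels)) >= 2) {
      sils[i] <- mean_silhouette(x, fit$labels)
    }
  }
  if (all(is.na(sils))) abort("no candidate k produced two non-empty clusters")
  best_i <- which(sils == max(sils, na.rm = TRUE))[1]
  fit <- fits[[best_i]]
  k <- k_range[best_i]
  # canonical phenotype-anchored naming: C1 = lowest mean standardized IAE
  # (boundary-transition), C2 = highest (accessibility-uniform); any
  # intermediate clusters become C3..Ck in ascending IAE order
  mean_iae <- vapply(seq_len(k), function(j) {
    mean(features$iae_z[fit$labels == j])
  }, numeric(1))
  ord <- order(mean_iae)
  rename <- integer(k)
  rename[ord[1]] <- 1L
  rename[ord[k]] <- 2L
  if (k > 2) rename[ord[2:(k - 1)]] <- 2L + seq_len(k - 2)
  subtype <- paste0("C", rename[fit$labels])
  structure(
    list(
      k = k, seed = seed,
      assignments = mutate(features, subtype = subtype),
      model = fit,
      silhouette = sils[best_i],
      diagnostics = tibble(k = k_range, mean_silhouette = sils, bic = bics)
    ),
    class = "nurepress_subtypes"
  )
}

#' @export
print.nurepress_subtypes <- function(x, ...) {
  cat(sprintf("<nurepress_subtypes> k = %d, mean silhouette = %.3f, %d arrays\n",
              x$k, x$silhouette, nrow(x$assignments)))
  print(table(x$assignments$subtype))
  invisible(x)
}

#' @describeIn select_subtypes Per-subtype summary (size, mean IAE/BPS).
#' @param x A `nurepress_subtypes` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nurepress_subtypes <- function(x, ...) {
  x$assignments |>
    group_by(.data$subtype) |>
    summarise(
      n_arrays = n(),
      mean_iae = if ("iae" %in% names(x$assignments)) mean(.data$iae) else NA_real_,
      mean_bps = if ("bps" %in% names(x$assignments)) mean(.data$bps) else NA_real_,
      mean_iae_z = mean(.data$iae_z),
      mean_bps_z = mean(.data$bps_z),
      .groups = "drop"
    )
}

#' @describeIn select_subtypes One-row model summary.
#' @exportS3Method generics::glance
glance.nurepress_subtypes <- function(x, ...) {
  tibble(
    k = x$k, mean_silhouette = x$silhouette, bic = x$model$bic,
    covariance = x$model$cov_type, n_arrays = nrow(x$assignments),
    seed = x$seed
  )
}
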