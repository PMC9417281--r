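#' Fit a Gaussian mixture model by expectation-maximization
#'
#' Full-covariance GMM fit in shape-feature space (by default the log-Hu
#' plane), the engine behind the package's soft shape classification.
#' Initialization is k-means++ seeding followed by a hard assignment;
#' `n_restarts` independently seeded runs are performed and the best
#' log-likelihood kept. Covariance matrices are regularized by an
#' eigenvalue floor of `reg` times the mean feature variance, which keeps
#' EM stable when features are strongly correlated along an aspect-ratio
#' continuum. The E-step uses log-sum-exp throughout, so responsibilities
#' never underflow to NaN.
#'
#' Components whose weight collapses below `1e-8` during iteration are
#' pruned and the fit continues with fewer classes rather than failing.
#'
#' @param features numeric matrix or data frame, N rows x d feature columns.
#' @param K number of mixture components (N > K*d required).
#' @param seed integer master seed; fits are bit-reproducible.
#' @param n_restarts independent EM starts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per start.
#' @param reg covariance eigenvalue floor, relative to mean feature variance.
#' @return object of class `gmm_model`: `K`, `weights`, `means` (K x d),
#'   `covariances` (list of d x d), `loglik`, `loglik_trace`, `bic`,
#'   `n_iter`, `seed`, `n`, `d`.
#' @seealso [select_classes()], [soft_assign()]
#' @export
fit_gmm <- function(features, K, seed = 1L, n_restarts = 10L, tol = 1e-8,
                    max_iter = 500L, reg = 1e-6) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("features must be finite")
  n <- nrow(X); d <- ncol(X)
  if (n <= K * d) stop("too few observations (need N > K*d)")
  floor_eig <- reg * mean(apply(X, 2L, stats::var))
  if (!is.finite(floor_eig) || floor_eig <= 0) floor_eig <- reg

  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- withr::with_seed(as.integer(seed) + r - 1L,
                                kmeanspp_centers(X, K))
    fit <- em_run(X, centers, tol = tol, max_iter = max_iter,
                  floor_eig = floor_eig)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  p <- (best$K - 1) + best$K * d + best$K * d * (d + 1) / 2
  structure(c(best, list(bic = -2 * best$loglik + p * log(n),
                         seed = as.integer(seed), n = n, d = d,
                         feature_names = colnames(X))),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> K = %d, d = %d, n = %d, loglik = %.4f, BIC = %.2f\n",
              x$K, x$d, x$n, x$loglik, x$bic))
  invisible(x)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1L] <- sample.int(n, 1L)
  if (K > 1L) {
    d2 <- rowSums(sweep(X, 2L, X[idx[1L], ])^2)
    for (k in 2:K) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[k] <- sample.int(n, 1L, prob = prob)
      d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx[k], ])^2))
    }
  }
  X[idx, , drop = FALSE]
}

# one EM run from given centers; returns weights/means/covs/loglik trace
em_run <- function(X, centers, tol, max_iter, floor_eig) {
  n <- nrow(X); d <- ncol(X); K <- nrow(centers)
  # hard init from nearest center
  d2 <- vapply(seq_len(K), function(k) rowSums(sweep(X, 2L, centers[k, ])^2),
               numeric(n))
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), max.col(-d2))] <- 1

  w <- mu <- S <- NULL
  trace <- numeric(0)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    # M step
    Nk <- colSums(resp)
    live <- Nk > n * 1e-8
    if (!all(live)) { # prune collapsed components
      resp <- resp[, live, drop = FALSE]
      resp <- resp / rowSums(resp)
      Nk <- colSums(resp)
      K <- ncol(resp)
    }
    w <- Nk / n
    mu <- crossprod(resp, X) / Nk
    S <- vector("list", K)
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2L, mu[k, ])
      Ck <- crossprod(Xc * resp[, k], Xc) / Nk[k]
      S[[k]] <- floor_cov(Ck, floor_eig)
    }
    # E step (log-sum-exp)
    logdens <- vapply(seq_len(K), function(k) {
      log(w[k]) + dmvnorm_log(X, mu[k, ], S[[k]])
    }, numeric(n))
    if (K == 1L) logdens <- matrix(logdens, ncol = 1L)
    m <- apply(logdens, 1L, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    resp <- exp(logdens - lse)
    ll <- sum(lse)
    iter <- iter + 1L
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) break
    if (iter >= max_iter) break
    ll_old <- ll
  }
  list(K = K, weights = w, means = mu, covariances = S,
       loglik = trace[length(trace)], loglik_trace = trace, n_iter = iter)
}

# clamp covariance eigenvalues from below
floor_cov <- function(C, floor_eig) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  v <- pmax(e$values, floor_eig)
  e$vectors %*% (v * t(e$vectors))
}

# log density of rows of X under N(mu, S), via Cholesky
dmvnorm_log <- function(X, mu, S) {
  R <- chol(S)
  Xc <- sweep(X, 2L, mu)
  z <- backsolve(R, t(Xc), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(R))) - ncol(X) / 2 * log(2 * pi)
}

#' Select the number of shape classes automatically
#'
#' For well-separated shape families the class count reduces to the true
#' number on its own; this function makes the reduction explicit. With
#' `criterion = "icl"` (default), models with K = 1..`K_max` are fitted and
#' the minimizer of the entropy-penalized BIC (the integrated
#' complete-likelihood criterion) is kept: BIC counts density
#' *components* — including ones that merely accommodate the heavy tail of
#' logH2 near the isotropy singularity — while ICL's assignment-entropy
#' penalty counts distinct, well-separated *classes*, which is the quantity
#' shape metrology needs. `"bic"` uses the plain BIC minimizer. Either way
#' a post-hoc weight-pruning pass removes components with weight below
#' `prune_weight` (refitting at the reduced K). With
#' `criterion = "weight_prune"`, a `K_max`-component model is fitted and
#' low-weight components are pruned iteratively until all weights exceed
#' `prune_weight`.
#'
#' @inheritParams fit_gmm
#' @param K_max largest class count considered.
#' @param criterion `"icl"`, `"bic"` or `"weight_prune"`.
#' @param prune_weight minimum component weight retained.
#' @param min_members minimum effective number of particles a retained
#'   class must hold; the pruning threshold is
#'   `max(prune_weight, min_members / N)`. A "class" holding a single
#'   outlier particle is not a shape class.
#' @param ... passed to [fit_gmm()].
#' @return the selected `gmm_model`.
#' @export
select_classes <- function(features, K_max = 5L,
                           criterion = c("icl", "bic", "weight_prune"),
                           prune_weight = 0.01, min_members = 2L,
                           seed = 1L, ...) {
  criterion <- match.arg(criterion)
  stopifnot(K_max >= 1L)
  prune_weight <- max(prune_weight, min_members / nrow(as.matrix(features)))
  if (criterion %in% c("icl", "bic")) {
    fits <- purrr::map(seq_len(K_max),
                       function(K) fit_gmm(features, K, seed = seed, ...))
    score <- purrr::map_dbl(fits, function(f) {
      if (criterion == "bic") f$bic else gmm_icl(f, features)
    })
    best <- fits[[which.min(score)]]
  } else {
    best <- fit_gmm(features, K_max, seed = seed, ...)
  }
  # post-hoc weight pruning (both criteria): refit at reduced K until stable
  repeat {
    keepK <- sum(best$weights >= prune_weight)
    if (keepK == best$K || keepK == 0L) break
    best <- fit_gmm(features, keepK, seed = seed, ...)
  }
  best
}

# entropy-penalized BIC (integrated complete likelihood)
gmm_icl <- function(model, features) {
  r <- soft_assign(model, features)$responsibilities
  model$bic + 2 * (-sum(ifelse(r > 0, r * log(r), 0)))
}

#' Soft-assign observations to mixture components
#'
#' Computes the responsibility matrix
#' \eqn{r_{ik} = \pi_k N(x_i; \mu_k, C_k) / \sum_j \pi_j N(x_i; \mu_j, C_j)}
#' (rows sum to 1), the per-class effective numbers
#' \eqn{\Sigma_k = \sum_i r_{ik}} and fractions \eqn{\Sigma_k / N}, and a
#' derived hard label (row argmax). Classes are ordered by descending
#' \eqn{\Sigma_k}, so class 1 is always the majority class.
#'
#' @param model a [fit_gmm()] result.
#' @param features the feature matrix the model applies to.
#' @return object of class `shape_classification`: list with
#'   `responsibilities` (N x K), `class_totals`, `fractions`,
#'   `hard_labels`, and the (re-ordered) `model`.
#' @export
soft_assign <- function(model, features) {
  stopifnot(inherits(model, "gmm_model"))
  X <- as.matrix(features)
  if (ncol(X) != model$d) stop("feature dimensionality does not match model")
  K <- model$K
  logdens <- vapply(seq_len(K), function(k) {
    log(model$weights[k]) +
      dmvnorm_log(X, model$means[k, ], model$covariances[[k]])
  }, numeric(nrow(X)))
  logdens <- matrix(logdens, nrow = nrow(X))
  m <- apply(logdens, 1L, max)
  resp <- exp(logdens - (m + log(rowSums(exp(logdens - m)))))
  ord <- order(colSums(resp), decreasing = TRUE)
  resp <- resp[, ord, drop = FALSE]
  model_ord <- model
  model_ord$weights <- model$weights[ord]
  model_ord$means <- model$means[ord, , drop = FALSE]
  model_ord$covariances <- model$covariances[ord]
  colnames(resp) <- paste0("r_", seq_len(K))
  structure(list(
    responsibilities = resp,
    class_totals = colSums(resp),
    fractions = colSums(resp) / nrow(X),
    hard_labels = max.col(resp, ties.method = "first"),
    model = model_ord
  ), class = "shape_classification")
}

#' @export
print.shape_classification <- function(x, ...) {
  cat(sprintf("<shape_classification> N = %d, K = %d; class totals: %s\n",
              nrow(x$responsibilities), ncol(x$responsibilities),
              paste(sprintf("%.1f", x$class_totals), collapse = ", ")))
  invisible(x)
}

#' Responsibility-weighted per-class summary statistics
#'
#' The class summary a metrologist reports: per class the effective number
#' \eqn{\Sigma_k} (sum of responsibilities, generally non-integer), the
#' fraction of particles, and the responsibility-weighted mean and standard
#' deviation of effective diameter and aspect ratio. Soft weighting makes
#' these statistics unbiased for the underlying class parameters even when
#' classes overlap, which is the central advantage over hard assignment.
#'
#' @param classification a [soft_assign()] result.
#' @param descriptors a [shape_descriptors()] tibble, same row order.
#' @return a tibble with columns `k`, `sigma`, `fraction`, `diam_mean`,
#'   `diam_sd`, `ar_mean`, `ar_sd`, sorted by descending `sigma`.
#' @export
class_summary <- function(classification, descriptors) {
  stopifnot(inherits(classification, "shape_classification"))
  resp <- classification$responsibilities
  if (nrow(resp) != nrow(descriptors)) {
    stop("classification and descriptor row counts differ")
  }
  wstats <- function(x, w) {
    W <- sum(w)
    if (W <= 0) return(c(NA_real_, NA_real_))
    m <- sum(w * x) / W
    c(m, sqrt(max(sum(w * (x - m)^2) / W, 0)))
  }
  rows <- purrr::map(seq_len(ncol(resp)), function(k) {
    w <- resp[, k]
    dm <- wstats(descriptors$d_eff_nm, w)
    ar <- wstats(descriptors$aspect_ratio, w)
    tibble::tibble(k = k, sigma = sum(w), fraction = sum(w) / nrow(resp),
                   diam_mean = dm[1L], diam_sd = dm[2L],
                   ar_mean = ar[1L], ar_sd = ar[2L])
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$sigma))
}

#' Classify particle shapes from a descriptor table
#'
#' Convenience wrapper: selects the class count from the log-Hu features
#' ([select_classes()]) and soft-assigns every particle
#' ([soft_assign()]).
#'
#' @param descriptors a [shape_descriptors()] tibble.
#' @param feature_cols descriptor columns used as features (default the
#'   log-Hu plane).
#' @param K_max,criterion,prune_weight,seed,... passed to [select_classes()].
#' @return a `shape_classification` (see [soft_assign()]).
#' @export
classify_shapes <- function(descriptors, feature_cols = c("logH1", "logH2"),
                            K_max = 5L, criterion = "icl",
                            prune_weight = 0.01, seed = 1L, ...) {
  X <- as.matrix(descriptors[, feature_cols])
  model <- select_classes(X, K_max = K_max, criterion = criterion,
                          prune_weight = prune_weight, seed = seed, ...)
  soft_assign(model, X)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted mixture model
#'
#' One row per mixture component: weight, mean coordinates and covariance
#' entries.
#' @param x a `gmm_model`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.gmm_model <- function(x, ...) {
  nm <- x$feature_names %||% paste0("f", seq_len(x$d))
  rows <- purrr::map(seq_len(x$K), function(k) {
    mu <- stats::setNames(as.list(x$means[k, ]), paste0("mean_", nm))
    C <- x$covariances[[k]]
    cv <- list()
    for (i in seq_len(x$d)) for (j in i:x$d) {
      cv[[paste0("cov_", nm[i], "_", nm[j])]] <- C[i, j]
    }
    dplyr::bind_cols(tibble::tibble(component = k, weight = x$weights[k]),
                     tibble::as_tibble(mu), tibble::as_tibble(cv))
  })
  dplyr::bind_rows(rows)
}

#' Glance at a fitted mixture model
#' @param x a `gmm_model`.
#' @param ... unused.
#' @return a one-row tibble with `K`, `loglik`, `bic`, `n_iter`, `n`.
#' @export
glance.gmm_model <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik, bic = x$bic,
                 n_iter = x$n_iter, n = x$n)
}

#' Tidy a soft classification
#'
#' One row per particle: responsibilities for every class plus the derived
#' hard label.
#' @param x a `shape_classification`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.shape_classification <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(particle = seq_len(nrow(x$responsibilities))),
    tibble::as_tibble(x$responsibilities),
    tibble::tibble(hard_label = x$hard_labels)
  )
}

#' Glance at a soft classification
#' @param x a `shape_classification`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.shape_classification <- function(x, ...) {
  tibble::tibble(n = nrow(x$responsibilities),
                 K = ncol(x$responsibilities),
                 loglik = x$model$loglik, bic = x$model$bic)
}
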