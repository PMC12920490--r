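#' @useDynLib bodysense, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

as_predictor_matrix <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("predictors must be numeric", call. = FALSE)
  if (ncol(X) < 2) stop("need at least 2 predictor variables", call. = FALSE)
  X
}

#' Fit a partial least squares regression (SIMPLS)
#'
#' Predictor columns are z-scored and the response centered at fit time;
#' the stored standardization parameters are reapplied to new rows at
#' prediction. Weights are reported on the standardized-predictor scale, the
#' scale on which they are compared against permutation nulls.
#'
#' @param X numeric matrix or data.frame (participants x variables).
#' @param y numeric response.
#' @param K number of components, `1 <= K <= min(n - 1, p)`.
#' @return A `plsr_fit`: coefficients at 1..K components, standardization
#'   parameters, chosen K.
#' @export
plsr_fit <- function(X, y, K) {
  X <- as_predictor_matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, K >= 1)
  if (K > min(n - 1, p)) {
    stop("K exceeds min(n - 1, p) = ", min(n - 1, p), call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  mu <- colMeans(X)
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  ym <- mean(y)
  res <- cpp_simpls_fit(Z, y - ym, as.integer(K))
  if (res$n_effective < K) {
    # benign when the covariance Krylov space is exhausted within rank(X)
    # (later components add nothing); an error when K exceeds rank(X)
    if (!res$exhausted || K > qr(Z)$rank) {
      stop("K = ", K, " exceeds the effective rank (",
           max(res$n_effective, qr(Z)$rank * (res$exhausted)), ")",
           call. = FALSE)
    }
  }
  B <- res$coefficients
  rownames(B) <- colnames(X)
  structure(
    list(coefficients = B, K = K, x_center = mu, x_scale = sds,
         y_center = ym, weights = B[, K]),
    class = "plsr_fit"
  )
}

#' @export
predict.plsr_fit <- function(object, newdata, K = object$K, ...) {
  Z <- sweep(sweep(as.matrix(newdata), 2, object$x_center), 2,
             object$x_scale, "/")
  as.numeric(Z %*% object$coefficients[, K] + object$y_center)
}

# Modal K across outer folds; ties among modes -> smallest; all-distinct
# folds -> (lower) median.
modal_k <- function(chosen_k) {
  tab <- table(chosen_k)
  if (max(tab) == 1L) {
    return(as.integer(floor(stats::median(chosen_k))))
  }
  min(as.integer(names(tab)[tab == max(tab)]))
}

#' Nested leave-one-out cross-validation for PLSR
#'
#' Outer loop leaves out each participant; an inner leave-one-out over the
#' remaining n - 1 picks the number of components minimizing inner mean
#' squared prediction error (ties broken toward the smallest K); the model
#' is refit on the n - 1 at that K and the held-out participant predicted.
#' Standardization, imputation (training-fold medians) and K selection all
#' happen strictly inside the training fold.
#'
#' @param X predictors (missing values allowed; fold-median imputed).
#' @param y response.
#' @param K_max largest candidate K, `<= min(n - 2, p)`.
#' @return A `plsr_cv`: out-of-sample `predictions`, `chosen_k` per fold,
#'   `modal_k`, and `r` (Pearson correlation of actual vs predicted).
#' @export
nested_loo_cv <- function(X, y, K_max = 10L) {
  X <- as_predictor_matrix(X)
  n <- nrow(X)
  if (n < 10) stop("need n >= 10 for nested cross-validation", call. = FALSE)
  stopifnot(length(y) == n, all(is.finite(y)))
  K_max <- as.integer(min(K_max, n - 2, ncol(X)))
  res <- cpp_nested_cv(X, y, K_max)
  structure(
    list(predictions = as.numeric(res$predictions),
         chosen_k = as.integer(res$chosen_k),
         modal_k = modal_k(as.integer(res$chosen_k)),
         r = res$r, K_max = K_max, y = y),
    class = "plsr_cv"
  )
}

#' Final full-data weights at the modal cross-validated K
#'
#' @param X,y as in [nested_loo_cv()].
#' @param K number of components (the modal outer-fold K).
#' @return Named numeric vector of standardized weights.
#' @export
final_weights <- function(X, y, K) {
  X <- as_predictor_matrix(X)
  P <- matrix(seq_len(nrow(X)) - 1L, ncol = 1)
  W <- cpp_perm_weights(X, y, as.integer(K), P)  # identity permutation
  stats::setNames(as.numeric(W[1, ]), colnames(X))
}

#' Nested-CV PLSR with permutation inference on fit and weights
#'
#' Runs [nested_loo_cv()], then (a) a permutation test of the out-of-sample
#' correlation r -- the response rows are permuted and the cross-validated r
#' recomputed per permutation, by default with leave-one-out prediction at
#' the observed modal K (`perm_scheme = "fixed_k"`, the tractable reduced
#' scheme) or by full re-selection (`"full"`) -- and (b) a permutation null
#' for every final-model weight, refitting the full-data model at the
#' observed modal K per permutation. A weight is flagged significant when it
#' falls outside the 2.5%-97.5% quantiles of its null. The p-value for r
#' uses the add-one convention (1 + #{null >= observed}) / (1 + n_perm).
#'
#' @param X,y,K_max as in [nested_loo_cv()].
#' @param n_perm number of permutations, >= 200 (default 1000).
#' @param seed integer seed for the permutation stream (required).
#' @param perm_scheme `"fixed_k"` (default) or `"full"`.
#' @return A `plsr_cv_result` with fields `r`, `p_perm`, `predictions`,
#'   `chosen_k`, `modal_k`, `weights`, `null_lo`, `null_hi`, `significant`.
#' @export
permutation_inference <- function(X, y, K_max = 10L, n_perm = 1000L, seed,
                                  perm_scheme = c("fixed_k", "full")) {
  perm_scheme <- match.arg(perm_scheme)
  if (n_perm < 200) {
    stop("n_perm must be >= 200 for stable 95% null quantiles", call. = FALSE)
  }
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  X <- as_predictor_matrix(X)
  cv <- nested_loo_cv(X, y, K_max)
  n <- nrow(X)

  set.seed(as.integer(seed))
  perms <- vapply(seq_len(n_perm), function(i) sample.int(n) - 1L,
                  integer(n))

  null_r <- if (perm_scheme == "fixed_k") {
    cpp_perm_r_fixed_k(X, y, cv$modal_k, perms)
  } else {
    cpp_perm_r_nested(X, y, cv$K_max, perms)
  }
  p_perm <- (1 + sum(null_r >= cv$r)) / (1 + n_perm)

  W_null <- cpp_perm_weights(X, y, cv$modal_k, perms)
  w_obs <- final_weights(X, y, cv$modal_k)
  null_lo <- apply(W_null, 2, stats::quantile, probs = 0.025, names = FALSE)
  null_hi <- apply(W_null, 2, stats::quantile, probs = 0.975, names = FALSE)
  sig <- w_obs < null_lo | w_obs > null_hi

  structure(
    list(r = cv$r, p_perm = p_perm,
         predictions = cv$predictions, chosen_k = cv$chosen_k,
         modal_k = cv$modal_k,
         weights = w_obs,
         null_lo = stats::setNames(null_lo, names(w_obs)),
         null_hi = stats::setNames(null_hi, names(w_obs)),
         significant = sig,
         n_perm = n_perm, perm_scheme = perm_scheme, seed = seed),
    class = "plsr_cv_result"
  )
}

#' @export
print.plsr_cv_result <- function(x, ...) {
  cat("PLSR nested leave-one-out CV\n")
  cat(sprintf("  out-of-sample r = %.3f (permutation p = %.4g, %d perms)\n",
              x$r, x$p_perm, x$n_perm))
  cat(sprintf("  modal K = %d\n", x$modal_k))
  sig <- names(x$weights)[x$significant]
  cat("  significant weights:",
      if (length(sig)) paste(sig, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
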