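#' Partial least-squares regression by NIPALS
#'
#' Fits the per-subject linear model linking single-trial pain ratings to
#' pre- and post-stimulus features,
#' `Y = a0 + sum_m a_m^pre X_m^pre + sum_n a_n^post X_n^post + eps`,
#' with the Nonlinear Iterative Partial Least Squares algorithm. Features are
#' column-centered and, by default, unit-scaled internally: spectrogram power
#' spans orders of magnitude across frequency bands (1/f), and without
#' scaling the latent components are monopolized by high-variance
#' low-frequency features, leaving genuine narrow-band effects (e.g. gamma)
#' with inconsistent coefficients. The returned coefficients are always
#' mapped back to the original (uncentered, unscaled) feature space, so they
#' remain in interpretable power / BOLD units. With as many components as the
#' rank of `X`, the unscaled fit coincides with ordinary least squares.
#'
#' @param X Numeric matrix, trials x features.
#' @param y Numeric response vector (ratings, usually energy-normalized).
#' @param n_components Number of latent components (default 3). Values
#'   exceeding the effective rank are reduced with a warning.
#' @param tol Convergence / rank-exhaustion tolerance.
#' @param standardize Unit-scale features internally (default `TRUE`);
#'   coefficients are back-transformed to raw units either way. Constant
#'   features are left unscaled.
#' @param phase Optional per-feature `"pre"`/`"post"` tags; when supplied the
#'   coefficient vector is also split into `coef_pre` and `coef_post`.
#' @return Object of class `plsr_model`: `intercept`, `coefficients`,
#'   optionally `coef_pre`/`coef_post`, `n_components` (actually used),
#'   `residual_var`, and the NIPALS loadings.
#' @export
fit_plsr_nipals <- function(X, y, n_components = 3L, tol = 1e-12,
                            standardize = TRUE, phase = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y disagree on trial count")
  if (nrow(X) < 3L) stop("need at least 3 trials")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stop("NaN or non-finite values in X or y")
  if (stats::var(y) == 0) stop("y has zero variance (no variable sensation)")
  if (n_components < 1L) stop("n_components must be >= 1")
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components > kmax) {
    warning("n_components reduced from ", n_components, " to ", kmax)
    n_components <- kmax
  }

  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  xsd <- rep(1, ncol(X))
  if (standardize) {
    xsd <- apply(Xc, 2L, stats::sd)
    xsd[xsd == 0] <- 1
    Xc <- sweep(Xc, 2L, xsd, `/`)
  }
  yc <- y - ybar
  x_scale <- sqrt(mean(Xc^2))                  # guards the rank tolerance against unit choice
  if (x_scale == 0) stop("X is constant across trials")

  p <- ncol(X)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  qvec <- numeric(n_components)
  used <- 0L
  Xd <- Xc
  yd <- yc
  for (k in seq_len(n_components)) {
    w <- crossprod(Xd, yd)                     # for a univariate response NIPALS converges in one pass
    wn <- sqrt(sum(w^2))
    if (wn < tol * x_scale * sqrt(sum(yd^2) + tol)) break
    w <- w / wn
    t_scores <- Xd %*% w
    tt <- sum(t_scores^2)
    if (tt < tol * x_scale^2) break
    pk <- crossprod(Xd, t_scores) / tt
    qk <- sum(yd * t_scores) / tt
    Xd <- Xd - tcrossprod(t_scores, pk)
    yd <- yd - qk * t_scores
    W[, k] <- w
    P[, k] <- pk
    qvec[k] <- qk
    used <- k
  }
  if (used == 0L) stop("NIPALS extracted no components (X orthogonal to y?)")
  if (used < n_components)
    warning("rank exhausted: n_components reduced to ", used)
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  qvec <- qvec[seq_len(used)]

  beta <- W %*% solve(crossprod(P, W), qvec)
  beta <- as.numeric(beta) / xsd               # back to raw feature units
  intercept <- ybar - sum(xbar * beta)
  fitted <- intercept + as.numeric(X %*% beta)
  res <- y - fitted

  out <- list(intercept = intercept, coefficients = beta,
              n_components = used,
              residual_var = if (length(res) > 1L) stats::var(res) else 0,
              loadings = P, weights = W, y_loadings = qvec)
  if (!is.null(phase)) {
    stopifnot(length(phase) == p)
    out$coef_pre <- beta[phase == "pre"]
    out$coef_post <- beta[phase == "post"]
  }
  structure(out, class = "plsr_model")
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  object$intercept + as.numeric(as.matrix(newdata) %*% object$coefficients)
}

#' Per-subject PLSR coefficient maps
#'
#' Fits one PLSR model per subject on its energy-normalized features and
#' ratings and stacks the coefficient vectors into a subjects x features
#' matrix for group-level inference. Subjects whose ratings do not vary
#' (no variable sensation) or that fail the fit preconditions are dropped,
#' with the reason recorded.
#'
#' @param fms List of normalized `feature_matrix` objects, one per subject,
#'   sharing a single feature grid.
#' @param n_components Components per subject model (default 3).
#' @return List with `maps` (subjects x features), `subjects`, `models`,
#'   `excluded` (data.frame subject/reason), plus the shared `coords`,
#'   `phase` and `grid`.
#' @export
subject_coefficient_maps <- function(fms, n_components = 3L) {
  stopifnot(length(fms) >= 1L, all(vapply(fms, inherits, TRUE, "feature_matrix")))
  ref <- fms[[1L]]
  for (fm in fms) {
    if (ncol(fm$values) != ncol(ref$values) ||
        !identical(fm$phase, ref$phase) ||
        !isTRUE(all.equal(fm$coords, ref$coords)))
      stop("subjects do not share one feature grid")
    if (!isTRUE(fm$normalized))
      stop("feature matrices must be energy-normalized first")
  }
  rows <- list()
  models <- list()
  subjects <- character(0)
  excluded <- data.frame(subject = character(0), reason = character(0))
  for (fm in fms) {
    sid <- as.character(fm$meta$subject_id[1L])
    y <- fm$meta$rating_norm
    if (stats::var(y) == 0) {
      excluded <- rbind(excluded, data.frame(subject = sid,
                                             reason = "no variable sensation"))
      next
    }
    fit <- tryCatch(
      fit_plsr_nipals(fm$values, y, n_components = n_components,
                      phase = fm$phase),
      error = function(e) e)
    if (inherits(fit, "error")) {
      excluded <- rbind(excluded, data.frame(subject = sid,
                                             reason = conditionMessage(fit)))
      next
    }
    rows[[length(rows) + 1L]] <- fit$coefficients
    models[[sid]] <- fit
    subjects <- c(subjects, sid)
  }
  if (length(rows) < 3L)
    stop("fewer than 3 usable subjects; group t-test is undefined")
  if (nrow(excluded) > 0L)
    message(nrow(excluded), " subject(s) excluded: ",
            paste(excluded$subject, excluded$reason, sep = ": ", collapse = "; "))
  list(maps = do.call(rbind, rows), subjects = subjects, models = models,
       excluded = excluded, coords = ref$coords, phase = ref$phase,
       grid = ref$grid)
}
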