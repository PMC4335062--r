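#' Fit the linear additive scoring model by semi-quantitative SVR
#'
#' Minimises `|w|^2 + C1 * sum(xi1) + C2 * sum(xi2)` subject to
#' `|E_k - y_k| <= epsilon + xi1_k` for measured binders and
#' `E_k >= E_cutoff - xi2_k` for censored non-binders (slacks nonnegative),
#' where `E_k = sum_i w_i x_ki` is the predicted score on the log10 K_d (nM)
#' scale. Solved exactly in the dual by coordinate descent; the problem is
#' strongly convex, so the minimiser is unique.
#'
#' @param X Sparse or dense design matrix (records x feature keys), e.g. from
#'   [encode_dataset()]; column names become feature keys.
#' @param y Numeric vector of log10 K_d for each record (ignored for censored
#'   records).
#' @param censored Logical vector: `TRUE` for non-binders, which contribute
#'   only the one-sided floor constraint.
#' @param C1,C2 Positive slack penalties for binders / non-binders.
#' @param epsilon Nonnegative epsilon-insensitivity for binders.
#' @param E_cutoff Score floor for non-binders (default `log10(5000)`).
#' @param fit_intercept If `TRUE`, an L2-penalised constant feature is added
#'   and its fitted weight reported as the model intercept.
#' @param tol,max_pass Convergence tolerance on the dual KKT violation and
#'   the pass cap.
#' @return A [cc_model()] with fitted weights; attributes `objective`,
#'   `dual_objective`, `duality_gap` and `gamma` carry the optimisation
#'   certificate.
#' @export
fit_semisvr <- function(X, y, censored, C1 = 10, C2 = 10, epsilon = 0.1,
                        E_cutoff = log10(5000), fit_intercept = FALSE,
                        tol = 1e-9, max_pass = 50000L) {
  stopifnot(C1 > 0, C2 > 0, epsilon >= 0)
  X <- methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  n <- nrow(X)
  stopifnot(length(y) == n, length(censored) == n)
  if (!any(!censored)) stop("at least one measured binder is required")
  keys <- colnames(X)
  if (is.null(keys)) keys <- paste0("f", seq_len(ncol(X)))
  if (fit_intercept) {
    X <- cbind(X, `(Intercept)` = rep(1, n))
    keys <- c(keys, "(Intercept)")
  }
  Xt <- Matrix::t(X) # CSC of t(X) == CSR of X
  y2 <- ifelse(censored, 0, y)
  res <- dcd_semisvr(Xt@p, Xt@i, Xt@x, ncol(X), as.double(y2),
                     as.logical(censored), C1, C2, epsilon, E_cutoff,
                     tol, as.integer(max_pass), numeric(0))
  if (!res$converged)
    warning("semisvr solver hit the pass cap (", max_pass,
            ") before reaching tolerance ", tol)
  w <- stats::setNames(res$w, keys)
  intercept <- 0
  if (fit_intercept) {
    intercept <- unname(w[["(Intercept)"]])
    w <- w[names(w) != "(Intercept)"]
  }
  E <- as.numeric(X %*% res$w)
  obj <- sum(res$w^2) +
    C1 * sum(pmax(0, abs(E[!censored] - y[!censored]) - epsilon)) +
    C2 * sum(pmax(0, E_cutoff - E[censored]))
  ## zero-feature records decouple from w; their optimal dual variable sits
  ## at the box corner matching the (constant) primal slack
  zero_row <- Matrix::rowSums(X^2) == 0
  gam <- res$gamma
  gam[zero_row & !censored] <-
    sign(y[zero_row & !censored]) *
    C1 * (abs(y[zero_row & !censored]) > epsilon)
  gam[zero_row & censored] <- C2 * (E_cutoff > 0)
  dual <- -sum(res$w^2) +
    sum(gam[!censored] * y[!censored] - epsilon * abs(gam[!censored])) +
    sum(gam[censored] * E_cutoff)
  model <- cc_model(w = w[w != 0],
                    C1 = C1, C2 = C2, epsilon = epsilon,
                    E_cutoff = E_cutoff, intercept = intercept)
  attr(model, "objective") <- obj
  attr(model, "dual_objective") <- dual
  attr(model, "duality_gap") <- obj - dual
  attr(model, "gamma") <- res$gamma
  attr(model, "passes") <- res$passes
  model
}

#' Primal objective of the semi-quantitative SVR at a given weight vector
#'
#' @param w Named weight vector (aligned to `colnames(X)` by name).
#' @inheritParams fit_semisvr
#' @return The objective value (used for solver cross-checks).
#' @export
semisvr_objective <- function(w, X, y, censored, C1, C2, epsilon,
                              E_cutoff = log10(5000)) {
  wv <- stats::setNames(rep(0, ncol(X)), colnames(X))
  wv[names(w)] <- w
  E <- as.numeric(X %*% wv)
  sum(wv^2) +
    C1 * sum(pmax(0, abs(E[!censored] - y[!censored]) - epsilon)) +
    C2 * sum(pmax(0, E_cutoff - E[censored]))
}

#' Score dimers with a fitted model
#'
#' `predict()` on a `cc_model` returns `intercept + sum(w * x)`: the
#' predicted log10 K_d in nM, so lower scores mean tighter predicted
#' binding and a score difference of 2 is a 100-fold predicted K_d ratio.
#'
#' @param object A `cc_model`.
#' @param newdata A feature tibble from [encode()], a list of such tibbles,
#'   or a sparse design matrix with feature keys as column names.
#' @param ... Unused.
#' @return Numeric score(s).
#' @export
predict.cc_model <- function(object, newdata, ...) {
  if (inherits(newdata, "Matrix") || is.matrix(newdata)) {
    wv <- stats::setNames(rep(0, ncol(newdata)), colnames(newdata))
    hit <- intersect(names(object$w), names(wv))
    wv[hit] <- object$w[hit]
    return(object$intercept + as.numeric(newdata %*% wv))
  }
  if (is.data.frame(newdata)) newdata <- list(newdata)
  vapply(newdata, function(fv) {
    object$intercept + sum(object$w[fv$key] * fv$count, na.rm = TRUE)
  }, numeric(1))
}

#' @rdname predict.cc_model
#' @param coil_a,coil_b One-row registered-coil tibbles.
#' @export
score_pair <- function(object, coil_a, coil_b) {
  predict(object, encode(coil_a, coil_b, categories = object$categories,
                         roles = object$roles))
}

#' Train a scoring model directly from a dataset
#'
#' Convenience wrapper: encodes all records and fits the semi-quantitative
#' SVR.
#'
#' @param dataset A `cc_dataset`.
#' @param categories,roles Encoder options (see [encode()]).
#' @inheritParams fit_semisvr
#' @param binders_only If `TRUE`, censored non-binders are excluded from
#'   training.
#' @return A fitted `cc_model` (with `categories`/`roles` recorded).
#' @export
train_model <- function(dataset, C1 = 10, C2 = 10, epsilon = 0.1,
                        E_cutoff = log10(dataset$ceiling),
                        categories = names(CC_CATEGORIES), roles = "both",
                        binders_only = FALSE, ...) {
  X <- encode_dataset(dataset, categories = categories, roles = roles)
  keep <- if (binders_only) dataset$records$is_binder else rep(TRUE, nrow(X))
  m <- fit_semisvr(X[keep, , drop = FALSE], dataset$records$log10_kd[keep],
                   dataset$records$is_censored[keep],
                   C1 = C1, C2 = C2, epsilon = epsilon, E_cutoff = E_cutoff, ...)
  m$categories <- categories
  m$roles <- roles
  m
}

#' Recursive feature elimination
#'
#' Iteratively drops the 5% (by default) of features with the smallest
#' absolute fitted weight and refits, tracking validation performance, until
#' no features remain; the retained set is the one with the best validation
#' Pearson R on binders.
#'
#' @param X,y,censored Training design/labels as in [fit_semisvr()].
#' @param X_val,y_val,censored_val Validation split used to score each step.
#' @inheritParams fit_semisvr
#' @param step_fraction Fraction of remaining features dropped per step.
#' @return List with `best_model`, `best_keys` and `curve` (tibble:
#'   `n_features`, `r_val`, `auc_val`).
#' @export
rfe <- function(X, y, censored, X_val, y_val, censored_val,
                C1 = 10, C2 = 10, epsilon = 0.1, E_cutoff = log10(5000),
                step_fraction = 0.05, ...) {
  stopifnot(step_fraction > 0, step_fraction < 1)
  keys <- colnames(X)
  curve <- list()
  best <- list(r = -Inf, model = NULL, keys = keys)
  while (length(keys) > 0L) {
    m <- fit_semisvr(X[, keys, drop = FALSE], y, censored,
                     C1 = C1, C2 = C2, epsilon = epsilon, E_cutoff = E_cutoff, ...)
    pred <- predict(m, X_val[, keys, drop = FALSE])
    r_val <- if (sum(!censored_val) >= 3L)
      suppressWarnings(stats::cor(pred[!censored_val], y_val[!censored_val]))
    else NA_real_
    auc_val <- auc_scores(pred, !censored_val)
    curve[[length(curve) + 1L]] <-
      tibble(n_features = length(keys), r_val = r_val, auc_val = auc_val)
    if (!is.na(r_val) && r_val > best$r)
      best <- list(r = r_val, model = m, keys = keys)
    wfull <- stats::setNames(rep(0, length(keys)), keys)
    wfull[names(m$w)] <- m$w
    drop_n <- ceiling(step_fraction * length(keys))
    ord <- order(abs(wfull), seq_along(wfull)) # stable
    keys <- keys[-ord[seq_len(drop_n)]]
  }
  list(best_model = best$model, best_keys = best$keys,
       curve = dplyr::bind_rows(curve))
}
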