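## Similarity-aware partitioning, nested cross-validation, metrics,
## bootstrap CI, permutation control, learning curves, identity splits.

## AUC with lower score = positive class, by the Mann-Whitney rank statistic
## (average ranks give the standard 1/2 credit for ties).
auc_scores <- function(scores, is_positive) {
  np <- sum(is_positive); nn <- sum(!is_positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  u_high <- sum(r[is_positive]) - np * (np + 1) / 2
  1 - u_high / (np * nn)
}

#' Prediction metrics: Pearson R on binders and strong-vs-weak AUC
#'
#' R is the Pearson correlation between predicted scores and log10 K_d over
#' records with `binder_lo < K_d < ceiling` nM. AUC measures discrimination
#' of strong binders (K_d < `strong_cut`) from weak/non-binders
#' (K_d >= `ceiling`), intermediates excluded; scores are oriented so that
#' lower score = strong.
#'
#' @param pred Predicted scores (log10 nM; lower = tighter).
#' @param kd_nM Experimental K_d in nM (censored at `ceiling`).
#' @param ceiling,strong_cut,binder_lo Class boundaries in nM.
#' @return Tibble with `r`, `auc`, `n_binders`, `n_strong`, `n_weak`.
#' @export
cc_metrics <- function(pred, kd_nM, ceiling = 5000, strong_cut = 250, binder_lo = 1) {
  binder <- kd_nM > binder_lo & kd_nM < ceiling
  r <- if (sum(binder) >= 3L)
    suppressWarnings(stats::cor(pred[binder], log10(kd_nM[binder])))
  else NA_real_
  strong <- kd_nM < strong_cut
  weak <- kd_nM >= ceiling
  auc <- auc_scores(pred[strong | weak], strong[strong | weak])
  tibble(r = r, auc = auc, n_binders = sum(binder),
         n_strong = sum(strong), n_weak = sum(weak))
}

## Pairwise Jaccard distance between record encodings (dense, on supports).
jaccard_matrix <- function(X) {
  B <- Matrix::Matrix(X > 0, sparse = TRUE) * 1
  inter <- as.matrix(Matrix::tcrossprod(B))
  sz <- Matrix::rowSums(B)
  uni <- outer(sz, sz, "+") - inter
  d <- 1 - inter / pmax(uni, 1)
  d[uni == 0] <- 0
  d
}

#' Partition a dataset into balanced, minimally similar folds
#'
#' Builds a record-similarity graph (similarity = 1 - Jaccard distance of
#' feature supports, sparsified to each record's `k_nn` nearest neighbours)
#' and assigns records to `K` folds so that (i) within each affinity stratum
#' fold sizes differ by at most one and (ii) similar records land in the
#' same fold where the balance allows: records are seeded in cluster order
#' and greedily attracted to the fold holding their most similar records,
#' followed by local same-stratum swap refinement that reduces the
#' cross-fold similarity cut (refinement runs for datasets up to 400
#' records; above that the greedy pass is kept).
#'
#' @param dataset A `cc_dataset`.
#' @param K Number of folds.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @param X Optional precomputed design matrix from [encode_dataset()].
#' @param k_nn Neighbourhood size of the sparsified similarity graph.
#' @return Tibble with `record` (row index), `idA`, `idB`, `stratum`, `fold`.
#' @export
partition <- function(dataset, K = 10, seed = 1, X = NULL, k_nn = 20) {
  n <- nrow(dataset$records)
  if (K > n) stop("more folds than records")
  if (is.null(X)) X <- encode_dataset(dataset)
  lab <- label_classes(dataset)
  D <- jaccard_matrix(X)
  S <- 1 - D
  diag(S) <- 0
  ## sparsify: keep each record's k_nn strongest similarities (symmetrised)
  if (n > k_nn + 1L) {
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nb <- order(-S[i, ], seq_len(n))[seq_len(k_nn)]
      keep[i, nb] <- TRUE
    }
    S[!(keep | t(keep))] <- 0
  }
  set.seed(seed)
  fold <- rep(NA_integer_, n)
  fold_sizes <- rep(0L, K)
  for (str in unique(lab$stratum)) {
    idx <- which(lab$stratum == str)
    ns <- length(idx)
    base <- ns %/% K
    extra <- ns %% K
    ## folds currently smallest take the remainder records
    pri <- order(fold_sizes, sample.int(K))
    quota <- rep(base, K)
    if (extra > 0L) quota[pri[seq_len(extra)]] <- base + 1L
    ## cluster order keeps similar records adjacent
    ord <- if (ns > 2L) {
      hc <- stats::hclust(stats::as.dist(D[idx, idx, drop = FALSE]), method = "average")
      idx[hc$order]
    } else idx
    left <- quota
    for (i in ord) {
      open <- which(left > 0L)
      attr_w <- vapply(open, function(f) {
        members <- which(fold == f)
        if (length(members) == 0L) 0 else sum(S[i, members])
      }, numeric(1))
      f <- open[order(-attr_w, fold_sizes[open], open)[1L]]
      fold[i] <- f
      left[f] <- left[f] - 1L
      fold_sizes[f] <- fold_sizes[f] + 1L
    }
  }
  ## local refinement: same-stratum swaps that reduce the cut weight
  if (n <= 400L) {
    cut_gain <- function(i, j) {
      fi <- fold[i]; fj <- fold[j]
      mi <- which(fold == fi); mj <- which(fold == fj)
      before <- sum(S[i, mi]) + sum(S[j, mj])
      after <- sum(S[i, mj]) + sum(S[j, mi]) - 2 * S[i, j]
      after - before
    }
    for (pass in 1:3) {
      improved <- FALSE
      for (str in unique(lab$stratum)) {
        idx <- which(lab$stratum == str)
        for (i in idx) for (j in idx) {
          if (i < j && fold[i] != fold[j] && cut_gain(i, j) > 1e-12) {
            tmp <- fold[i]; fold[i] <- fold[j]; fold[j] <- tmp
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }
  tibble(record = seq_len(n), idA = dataset$records$idA,
         idB = dataset$records$idB, stratum = lab$stratum, fold = fold)
}

#' Grid search for the regression hyperparameters by inner cross-validation
#'
#' Evaluates every `(C1, C2, epsilon)` combination by K-fold CV and selects
#' by pooled Pearson R on binders, breaking ties by AUC and then by smaller
#' `C1 + C2`.
#'
#' @param X,y,censored Design and labels (see [fit_semisvr()]).
#' @param kd_nM K_d values used to define metric classes.
#' @param folds Integer fold assignment per record.
#' @param grid Tibble with columns `C1`, `C2`, `epsilon`.
#' @param ceiling Censoring ceiling in nM.
#' @inheritParams fit_semisvr
#' @param binders_only Train on binders only (non-binders still predicted).
#' @return List with `best` (one-row tibble) and the full `results` table.
#' @export
grid_search <- function(X, y, censored, kd_nM, folds, grid,
                        ceiling = 5000, E_cutoff = log10(ceiling),
                        binders_only = FALSE, ...) {
  results <- purrr::pmap_dfr(grid, function(C1, C2, epsilon) {
    pred <- rep(NA_real_, length(y))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (binders_only) tr <- tr & !censored
      if (sum(!censored[tr]) == 0L) next
      m <- fit_semisvr(X[tr, , drop = FALSE], y[tr], censored[tr],
                       C1 = C1, C2 = C2, epsilon = epsilon,
                       E_cutoff = E_cutoff, ...)
      pred[folds == f] <- predict(m, X[folds == f, , drop = FALSE])
    }
    met <- cc_metrics(pred, kd_nM, ceiling = ceiling)
    tibble(C1 = C1, C2 = C2, epsilon = epsilon, r = met$r, auc = met$auc)
  })
  ord <- order(-results$r, -results$auc, results$C1 + results$C2)
  list(best = results[ord[1L], ], results = results)
}

#' Default hyperparameter grid
#'
#' Log-spaced slack penalties bracketing the interpolation and
#' high-regularisation regimes, crossed with a few epsilon-tube widths.
#'
#' @param n_C Points per penalty axis (log-spaced over 1e-2..1e3).
#' @param eps_values Epsilon values.
#' @return Tibble with columns `C1`, `C2`, `epsilon`.
#' @export
default_grid <- function(n_C = 6, eps_values = c(0, 0.1, 0.2, 0.4)) {
  Cs <- 10^seq(-2, 3, length.out = n_C)
  tidyr::expand_grid(C1 = Cs, C2 = Cs, epsilon = eps_values)
}

#' Nested cross-validation of the scoring model
#'
#' Outer loop: hold out one similarity-aware fold; inner loop: re-partition
#' the remaining records and pick `(C1, C2, epsilon)` by grid search; refit
#' on the outer training set and predict the held-out fold. Held-out
#' predictions are pooled across folds and summarised with [cc_metrics()].
#' No record ever influences the model that scores it.
#'
#' @param dataset A `cc_dataset`.
#' @param grid Hyperparameter grid (see [default_grid()]).
#' @param outer_k,inner_k Fold counts of the two loops.
#' @param seed Integer seed controlling both partitionings.
#' @param categories,roles Encoder options.
#' @param binders_only Exclude censored records from training.
#' @param E_cutoff Non-binder score floor.
#' @param ... Passed to [fit_semisvr()].
#' @return A `cc_cv` object: list with `predictions` (tibble with pooled
#'   held-out scores), `metrics`, `fold_params` and the call parameters.
#' @export
nested_cv <- function(dataset, grid = default_grid(), outer_k = 10, inner_k = 10,
                      seed = 1, categories = names(CC_CATEGORIES), roles = "both",
                      binders_only = FALSE, E_cutoff = log10(dataset$ceiling), ...) {
  X <- encode_dataset(dataset, categories = categories, roles = roles)
  recs <- dataset$records
  part <- partition(dataset, K = outer_k, seed = seed, X = X)
  pred <- rep(NA_real_, nrow(recs))
  fold_params <- list()
  for (f in sort(unique(part$fold))) {
    tr <- which(part$fold != f)
    te <- which(part$fold == f)
    inner_ds <- dataset
    inner_ds$records <- recs[tr, , drop = FALSE]
    inner_part <- partition(inner_ds, K = min(inner_k, length(tr)),
                            seed = seed + f, X = X[tr, , drop = FALSE])
    gs <- grid_search(X[tr, , drop = FALSE], recs$log10_kd[tr],
                      recs$is_censored[tr], recs$kd_nM[tr],
                      inner_part$fold, grid, ceiling = dataset$ceiling,
                      E_cutoff = E_cutoff, binders_only = binders_only, ...)
    trf <- if (binders_only) tr[!recs$is_censored[tr]] else tr
    m <- fit_semisvr(X[trf, , drop = FALSE], recs$log10_kd[trf],
                     recs$is_censored[trf], C1 = gs$best$C1, C2 = gs$best$C2,
                     epsilon = gs$best$epsilon, E_cutoff = E_cutoff, ...)
    pred[te] <- predict(m, X[te, , drop = FALSE])
    fold_params[[length(fold_params) + 1L]] <-
      dplyr::mutate(gs$best, fold = f, .before = 1L)
  }
  predictions <- dplyr::mutate(label_classes(dataset), pred = pred,
                               fold = part$fold)
  structure(list(
    predictions = predictions,
    metrics = cc_metrics(pred, recs$kd_nM, ceiling = dataset$ceiling),
    fold_params = dplyr::bind_rows(fold_params),
    outer_k = outer_k, inner_k = inner_k, seed = seed,
    binders_only = binders_only, categories = categories
  ), class = "cc_cv")
}

#' @exportS3Method base::print
print.cc_cv <- function(x, ...) {
  cat("<cc_cv> ", x$outer_k, "-fold nested CV: R = ", signif(x$metrics$r, 3),
      " (", x$metrics$n_binders, " binders), AUC = ", signif(x$metrics$auc, 3),
      "\n", sep = "")
  invisible(x)
}

#' Bootstrap confidence interval for the cross-validated Pearson R
#'
#' Resamples (prediction, truth) pairs with replacement and reports the
#' percentile interval of the correlation.
#'
#' @param pred,truth Paired numeric vectors (binder subset, log10 scale).
#' @param B Number of resamples.
#' @param seed Integer seed.
#' @param conf Interval mass (default 0.95).
#' @return Tibble with `r`, `lo`, `hi`, `B`.
#' @export
bootstrap_ci <- function(pred, truth, B = 1000, seed = 1, conf = 0.95) {
  stopifnot(length(pred) == length(truth), length(pred) >= 3L)
  set.seed(seed)
  n <- length(pred)
  rs <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    suppressWarnings(stats::cor(pred[i], truth[i]))
  }, numeric(1))
  rs <- rs[!is.na(rs)]
  qa <- stats::quantile(rs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  tibble(r = suppressWarnings(stats::cor(pred, truth)), lo = qa[1], hi = qa[2], B = B)
}

#' Permutation control for the nested cross-validation
#'
#' Randomly reshuffles the measured affinities (K_d and censoring status
#' jointly) across records and reruns the full nested CV; an unbiased
#' protocol yields R near 0 and AUC near 0.5.
#'
#' @inheritParams nested_cv
#' @return A `cc_cv` object on the permuted dataset.
#' @export
permutation_control <- function(dataset, grid = default_grid(), outer_k = 10,
                                inner_k = 10, seed = 1, ...) {
  set.seed(seed)
  perm <- sample.int(nrow(dataset$records))
  cols <- c("kd_nM", "log10_kd", "is_binder", "is_censored")
  dataset$records[cols] <- dataset$records[perm, cols]
  nested_cv(dataset, grid = grid, outer_k = outer_k, inner_k = inner_k,
            seed = seed, ...)
}

#' Learning curve: performance vs training-set size
#'
#' Runs the nested CV on stratified random subsets containing the given
#' fractions of all records.
#'
#' @inheritParams nested_cv
#' @param fractions Fractions of the dataset to use.
#' @return Tibble with `fraction`, `n`, `r`, `auc`.
#' @export
learning_curve <- function(dataset, fractions = seq(0.1, 1, by = 0.1),
                           grid = default_grid(), outer_k = 10, inner_k = 10,
                           seed = 1, ...) {
  lab <- label_classes(dataset)
  purrr::map_dfr(fractions, function(fr) {
    set.seed(seed + round(1000 * fr))
    take <- integer(0)
    n_target <- round(fr * nrow(lab))
    for (str in unique(lab$stratum)) {
      idx <- which(lab$stratum == str)
      take <- c(take, sample(idx, round(fr * length(idx))))
    }
    ## stratified rounding can drift by a record or two from round(fr * n)
    sub <- dataset
    sub$records <- dataset$records[sort(take), , drop = FALSE]
    cv <- nested_cv(sub, grid = grid, outer_k = outer_k, inner_k = inner_k,
                    seed = seed, ...)
    tibble(fraction = fr, n = length(take), r = cv$metrics$r, auc = cv$metrics$auc)
  })
}

## Pairwise sequence identity over aligned a,d,e,g positions of the block
## overlap.
core_identity <- function(coil_a, coil_b) {
  ca <- core_residues(coil_a$sequence[1], coil_a$register[1])
  cb <- core_residues(coil_b$sequence[1], coil_b$register[1])
  n <- min(length(ca), length(cb))
  if (n == 0L) return(0)
  mean(ca[seq_len(n)] == cb[seq_len(n)])
}

#' Split a dataset into low-identity train/test sets
#'
#' Clusters proteins by single linkage at the identity threshold (identity
#' computed over aligned `a`, `d`, `e`, `g` positions), then assigns whole
#' clusters to the training side until its share of records reaches the
#' target. No cross-side protein pair exceeds `max_identity`; records
#' spanning the two sides are dropped.
#'
#' @param dataset A `cc_dataset`.
#' @param max_identity Maximum allowed cross-side identity (e.g. 0.5).
#' @param target_fraction Desired fraction of records on the training side.
#' @return List with `train`, `test` (both `cc_dataset`), `dropped`
#'   (records tibble) and `protein_side` tibble.
#' @export
identity_split <- function(dataset, max_identity = 0.5, target_fraction = 0.7) {
  coils <- dataset$coils
  n <- nrow(coils)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (core_identity(coils[i, ], coils[j, ]) > max_identity) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  cl <- vapply(seq_len(n), find, integer(1))
  recs <- dataset$records
  cl_of <- stats::setNames(cl, coils$id)
  cluster_sizes <- purrr::map_int(unique(cl), function(k) {
    ids <- coils$id[cl == k]
    sum(recs$idA %in% ids | recs$idB %in% ids)
  })
  ord <- unique(cl)[order(-cluster_sizes)]
  side <- stats::setNames(rep("test", length(ord)), ord)
  n_train <- 0L
  for (k in ord) {
    if (n_train >= target_fraction * nrow(recs)) break
    side[as.character(k)] <- "train"
    ids_tr <- coils$id[cl %in% as.integer(names(side)[side == "train"])]
    n_train <- sum(recs$idA %in% ids_tr & recs$idB %in% ids_tr)
  }
  if (all(side == "train"))
    warning("identity clustering produced a single giant cluster; best-effort split")
  side_of <- side[as.character(cl_of)]
  names(side_of) <- names(cl_of)
  sideA <- side_of[recs$idA]; sideB <- side_of[recs$idB]
  mk <- function(which_side) {
    ids <- names(side_of)[side_of == which_side]
    d <- dataset
    d$coils <- coils[coils$id %in% ids, , drop = FALSE]
    d$records <- recs[sideA == which_side & sideB == which_side, , drop = FALSE]
    d
  }
  list(train = mk("train"), test = mk("test"),
       dropped = recs[sideA != sideB, , drop = FALSE],
       protein_side = tibble(id = names(side_of), side = unname(side_of)))
}
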