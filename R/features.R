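## Structurally conserved contact types of the parallel coiled-coil dimer.
## Each slot is (chain, position, heptad offset); chain 1 is the unprimed
## helix, chain 2 the primed partner. Heptad indices follow the canonical
## a..g frame (g_i packs against e' of heptad i+1).
##
## Symmetric categories canonicalise the residue tuple (lexicographic order);
## aa' and dd' are additionally self-symmetric: swapping chain roles maps the
## contact onto itself, so it is enumerated under one role only. For every
## other category the two chain-role assignments are distinct physical
## contacts of the dimer and both are counted, which makes the encoding
## invariant under swapping the two chains.
cc_slot <- function(chain, pos, off) list(chain = chain, pos = pos, off = off)

CC_CATEGORIES <- list(
  aa  = list(type = "pair", symmetric = TRUE,  selfsym = TRUE,
             slots = list(cc_slot(1, "a", 0), cc_slot(2, "a", 0))),
  dd  = list(type = "pair", symmetric = TRUE,  selfsym = TRUE,
             slots = list(cc_slot(1, "d", 0), cc_slot(2, "d", 0))),
  ge  = list(type = "pair", symmetric = TRUE,  selfsym = FALSE,
             slots = list(cc_slot(1, "g", 0), cc_slot(2, "e", 1))),
  eg  = list(type = "pair", symmetric = TRUE,  selfsym = FALSE,
             slots = list(cc_slot(1, "e", 0), cc_slot(2, "g", 0))),
  ad  = list(type = "pair", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "a", 0), cc_slot(2, "d", 0))),
  da  = list(type = "pair", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "d", 0), cc_slot(2, "a", 1))),
  de  = list(type = "pair", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "d", 0), cc_slot(2, "e", 0))),
  ga  = list(type = "pair", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "g", 0), cc_slot(2, "a", 1))),
  ada = list(type = "triplet", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "a", 0), cc_slot(1, "d", 0), cc_slot(2, "a", 0))),
  dad = list(type = "triplet", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "d", 0), cc_slot(1, "a", 1), cc_slot(2, "d", 0))),
  gde = list(type = "triplet", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "g", 0), cc_slot(1, "d", 1), cc_slot(2, "e", 1))),
  gae = list(type = "triplet", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "g", 0), cc_slot(2, "a", 1), cc_slot(2, "e", 1))),
  edg = list(type = "triplet", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "e", 0), cc_slot(2, "d", 0), cc_slot(2, "g", 0))),
  eag = list(type = "triplet", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "e", 0), cc_slot(1, "a", 1), cc_slot(2, "g", 0))),
  agd = list(type = "triplet", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "a", 0), cc_slot(2, "g", -1), cc_slot(2, "d", 0))),
  aed = list(type = "triplet", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "a", 0), cc_slot(1, "e", 0), cc_slot(2, "d", 0))),
  dea = list(type = "triplet", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "d", 0), cc_slot(2, "e", 0), cc_slot(2, "a", 1))),
  dga = list(type = "triplet", symmetric = FALSE, selfsym = FALSE,
             slots = list(cc_slot(1, "d", 0), cc_slot(1, "g", 0), cc_slot(2, "a", 1)))
)

#' Sizes of the pair/triplet feature space
#'
#' Counts the distinct residue combinations each contact category can take:
#' 210 for symmetric pair categories (unordered pairs over 20 amino acids),
#' 400 for asymmetric pair categories and 8,000 per triplet category.
#'
#' @return Tibble with columns `category`, `type`, `size`, plus an attribute
#'   `total`; `feature_space_total()` returns the grand total directly.
#' @examples
#' feature_space_total() # 82440
#' @export
feature_space_size <- function() {
  out <- purrr::imap_dfr(CC_CATEGORIES, function(cat, name) {
    size <- if (cat$type == "triplet") 20L^3L
    else if (cat$symmetric) 20L * 21L / 2L
    else 20L^2L
    tibble(category = name, type = cat$type, size = as.integer(size))
  })
  attr(out, "total") <- sum(out$size)
  out
}

#' @rdname feature_space_size
#' @export
feature_space_total <- function() {
  sum(feature_space_size()$size)
}

## Enumerate contact instances of one chain-role assignment as feature keys
## "cat:R1-R2[-R3]". mA plays the unprimed role.
role_keys <- function(mA, mB, categories) {
  h_all <- intersect(as.integer(rownames(mA)), as.integer(rownames(mB)))
  h_lo <- min(as.integer(rownames(mA))[1], as.integer(rownames(mB))[1]) - 1L
  h_hi <- max(as.integer(rownames(mA))[nrow(mA)], as.integer(rownames(mB))[nrow(mB)]) + 1L
  hs <- h_lo:h_hi
  keys <- character(0)
  for (name in names(categories)) {
    cat <- categories[[name]]
    resm <- vapply(cat$slots, function(s) {
      m <- if (s$chain == 1L) mA else mB
      hm_at(m, hs + s$off, s$pos)
    }, character(length(hs)))
    if (is.null(dim(resm))) resm <- matrix(resm, nrow = 1L)
    ok <- rowSums(is.na(resm)) == 0L
    if (!any(ok)) next
    resm <- resm[ok, , drop = FALSE]
    if (isTRUE(cat$symmetric)) {
      resm <- t(apply(resm, 1L, sort))
    }
    keys <- c(keys, paste0(name, ":", apply(resm, 1L, paste, collapse = "-")))
  }
  keys
}

#' Encode a registered coiled-coil dimer as sparse contact counts
#'
#' Counts every instance of the predefined pair and triplet contact
#' categories in the aligned dimer. The two coils are aligned by heptad index
#' anchored at each coil's first complete f-anchored block. The encoding is
#' exactly invariant under swapping the two chains.
#'
#' @param coil_a,coil_b One-row registered-coil tibbles (columns `sequence`,
#'   `register`), e.g. rows of [simulate_coils()] output.
#' @param categories Character vector of category names to use (default all
#'   18); e.g. `c("aa","dd","ge")` for the simplified pair model.
#' @param roles `"both"` (default) counts both chain-role assignments of
#'   every non-self-symmetric category; `"single"` counts one assignment
#'   only.
#' @return Tibble with columns `key` (e.g. `"aa:N-N"`) and `count`, sorted by
#'   key.
#' @export
encode <- function(coil_a, coil_b, categories = names(CC_CATEGORIES), roles = c("both", "single")) {
  roles <- match.arg(roles)
  cats <- CC_CATEGORIES[categories]
  if (anyNA(names(cats))) stop("unknown feature category")
  mA <- heptad_matrix(coil_a$sequence[1], coil_a$register[1])
  mB <- heptad_matrix(coil_b$sequence[1], coil_b$register[1])
  ha <- as.integer(rownames(mA)); hb <- as.integer(rownames(mB))
  shared <- intersect(ha[!is.na(mA[, "a"])], hb[!is.na(mB[, "a"])])
  if (length(shared) == 0L) stop("coils have no overlapping full heptad")
  keys <- role_keys(mA, mB, cats)
  if (roles == "both") {
    cats2 <- cats[!vapply(cats, function(c) isTRUE(c$selfsym), logical(1))]
    keys <- c(keys, role_keys(mB, mA, cats2))
  }
  tab <- table(keys)
  tibble(key = names(tab), count = as.integer(tab))
}

key_category <- function(key) sub(":.*$", "", key)

#' Jaccard distance between the supports of two feature vectors
#'
#' The fraction of features, among those present in either dimer encoding,
#' that are present in only one of the two.
#'
#' @param u,v Feature tibbles from [encode()] (only the `key` support is
#'   used).
#' @return A number in `[0, 1]`; 0 when both supports are empty.
#' @export
jaccard_distance <- function(u, v) {
  su <- unique(u$key); sv <- unique(v$key)
  un <- union(su, sv)
  if (length(un) == 0L) return(0)
  length(setdiff(un, intersect(su, sv))) / length(un)
}

#' Encode every record of a dataset into a sparse design matrix
#'
#' @param dataset A `cc_dataset` (see [as_cc_dataset()]).
#' @inheritParams encode
#' @return Sparse `dgCMatrix` (records x feature keys), rows in record order.
#' @export
encode_dataset <- function(dataset, categories = names(CC_CATEGORIES), roles = "both") {
  coils <- dataset$coils
  recs <- dataset$records
  fvs <- purrr::map2(recs$idA, recs$idB, function(a, b) {
    encode(coils[coils$id == a, ], coils[coils$id == b, ],
           categories = categories, roles = roles)
  })
  all_keys <- sort(unique(unlist(purrr::map(fvs, "key"))))
  i <- rep(seq_along(fvs), vapply(fvs, nrow, integer(1)))
  j <- match(unlist(purrr::map(fvs, "key")), all_keys)
  x <- unlist(purrr::map(fvs, "count"))
  Matrix::sparseMatrix(
    i = i, j = j, x = as.double(x),
    dims = c(length(fvs), length(all_keys)),
    dimnames = list(paste(recs$idA, recs$idB, sep = "--"), all_keys)
  )
}

#' Distinct features observed at least once in a dataset
#'
#' @param dataset A `cc_dataset`, or a sparse matrix from [encode_dataset()].
#' @inheritParams encode
#' @return List with `n_pairs`, `n_triplets` and the observed `keys`.
#' @export
observed_features <- function(dataset, categories = names(CC_CATEGORIES), roles = "both") {
  X <- if (inherits(dataset, "Matrix")) dataset
  else if (nrow(dataset$records) == 0L) Matrix::Matrix(0, 0, 0, sparse = TRUE)
  else encode_dataset(dataset, categories = categories, roles = roles)
  keys <- colnames(X)[Matrix::colSums(X) > 0]
  if (is.null(keys)) keys <- character(0)
  types <- vapply(CC_CATEGORIES, `[[`, character(1), "type")
  is_pair <- types[key_category(keys)] == "pair"
  list(n_pairs = sum(is_pair), n_triplets = sum(!is_pair), keys = keys)
}
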