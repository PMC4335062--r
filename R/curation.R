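## Dataset curation: the three cleaning filters applied before training, and
## the class labelings used for evaluation and for stratified partitioning.

## a-position residues of the aligned overlap, paired block-by-block from
## each coil's first complete block.
aligned_a_residues <- function(coil_a, coil_b) {
  ba <- coil_blocks_str(coil_a$sequence[1], coil_a$register[1])
  bb <- coil_blocks_str(coil_b$sequence[1], coil_b$register[1])
  K <- min(nrow(ba), nrow(bb))
  if (K == 0L) return(tibble(block = integer(), resA = character(), resB = character(),
                             terminal = logical()))
  tibble(
    block = seq_len(K),
    resA = substr(ba$heptad[seq_len(K)], 3L, 3L),
    resB = substr(bb$heptad[seq_len(K)], 3L, 3L),
    terminal = seq_len(K) %in% c(1L, K)
  )
}

#' Exclude dimers with asparagine mismatches in non-terminal heptads
#'
#' An Asn at an `a` position facing Val, Leu or Ile at the opposing `a`
#' position strongly destabilises the dimer and casts doubt on the assumed
#' helix alignment; such records are removed. The first and last block of
#' the aligned overlap are exempt (the effect is much weaker at coil ends).
#'
#' @param dataset A `cc_dataset`.
#' @return List with the filtered `dataset` and `excluded` (tibble of
#'   removed pairs with the offending block).
#' @export
filter_asn_mismatch <- function(dataset) {
  recs <- dataset$records
  hydroph <- c("V", "L", "I")
  hit <- purrr::map2(recs$idA, recs$idB, function(a, b) {
    al <- aligned_a_residues(dataset$coils[dataset$coils$id == a, ],
                             dataset$coils[dataset$coils$id == b, ])
    mm <- !al$terminal &
      ((al$resA == "N" & al$resB %in% hydroph) |
         (al$resB == "N" & al$resA %in% hydroph))
    if (any(mm)) al$block[which(mm)[1]] else NA_integer_
  })
  bad <- !is.na(unlist(hit))
  excluded <- tibble(idA = recs$idA[bad], idB = recs$idB[bad],
                     block = unlist(hit)[bad])
  dataset$records <- recs[!bad, , drop = FALSE]
  list(dataset = dataset, excluded = excluded)
}

#' Position-specific scoring matrix over the interface positions
#'
#' Estimates, with add-one smoothing, the probability `p_i(aa)` of each amino
#' acid at heptad positions `a`, `d`, `e`, `g` across the given coils, and a
#' background probability `p(aa)` over all positions, and scores
#' `s_i(aa) = -log(p_i(aa) / p(aa))`: residues frequent at a position score
#' low.
#'
#' @param coils Registered-coil tibble.
#' @return List with matrices `p_pos`, `scores` (20 x 4) and vector `p_bg`.
#' @export
build_pssm <- function(coils) {
  pos4 <- c("a", "d", "e", "g")
  res_all <- strsplit(paste(coils$sequence, collapse = ""), "")[[1]]
  lab_all <- strsplit(paste(coils$register, collapse = ""), "")[[1]]
  counts <- sapply(pos4, function(p) {
    tab <- table(factor(res_all[lab_all == p], levels = AA20))
    as.numeric(tab) + 1 # add-one smoothing
  })
  rownames(counts) <- AA20
  p_pos <- sweep(counts, 2L, colSums(counts), "/")
  bg <- as.numeric(table(factor(res_all, levels = AA20))) + 1
  p_bg <- stats::setNames(bg / sum(bg), AA20)
  scores <- -log(p_pos / p_bg)
  list(p_pos = p_pos, p_bg = p_bg, scores = scores)
}

#' Score each protein against the PSSM and drop the top outliers
#'
#' Proteins with uncharacteristic interface residues get high PSSM scores;
#' the top `fraction` of proteins (ceiling of `fraction * n`, ties broken by
#' id) are removed together with every interaction they participate in.
#'
#' @param dataset A `cc_dataset`.
#' @param fraction Fraction of proteins to remove, in (0, 1).
#' @param mode `"mean"` (default; score divided by the number of scored
#'   residues, so coils of different lengths are comparable) or `"sum"`.
#' @return List with the filtered `dataset`, `excluded_proteins` (tibble with
#'   scores) and the per-protein `scores` tibble.
#' @export
pssm_outlier_filter <- function(dataset, fraction = 0.1, mode = c("mean", "sum")) {
  stopifnot(fraction > 0, fraction < 1)
  mode <- match.arg(mode)
  pssm <- build_pssm(dataset$coils)
  pos4 <- c("a", "d", "e", "g")
  score_one <- function(sequence, register) {
    res <- strsplit(sequence, "")[[1]]
    lab <- strsplit(register, "")[[1]]
    keep <- lab %in% pos4
    s <- pssm$scores[cbind(match(res[keep], AA20), match(lab[keep], pos4))]
    if (mode == "mean") mean(s) else sum(s)
  }
  scores <- tibble(
    id = dataset$coils$id,
    score = purrr::map2_dbl(dataset$coils$sequence, dataset$coils$register, score_one)
  )
  n_drop <- ceiling(fraction * nrow(scores))
  ord <- order(-scores$score, scores$id)
  drop_ids <- scores$id[ord[seq_len(n_drop)]]
  keep_rec <- !(dataset$records$idA %in% drop_ids | dataset$records$idB %in% drop_ids)
  excluded <- scores[scores$id %in% drop_ids, ]
  dataset$records <- dataset$records[keep_rec, , drop = FALSE]
  dataset$coils <- dataset$coils[!dataset$coils$id %in% drop_ids, , drop = FALSE]
  list(dataset = dataset, excluded_proteins = excluded, scores = scores)
}

#' Remove conflicting measurements from length variants of the same coils
#'
#' Different-length constructs of the same proteins present the identical
#' coiled-coil interaction motif; when two records share both partners'
#' complete-block sequences but report different K_d values, all such
#' records are removed (conflicting measurements of one motif). Records that
#' agree are deduplicated to one.
#'
#' @param dataset A `cc_dataset`.
#' @return List with the filtered `dataset` and `excluded` records.
#' @export
filter_variant_conflicts <- function(dataset) {
  block_seq <- stats::setNames(
    vapply(seq_len(nrow(dataset$coils)), function(i) {
      paste(coil_blocks_str(dataset$coils$sequence[i],
                            dataset$coils$register[i])$heptad, collapse = "")
    }, character(1)),
    dataset$coils$id
  )
  recs <- dataset$records
  motif <- purrr::map2_chr(recs$idA, recs$idB, function(a, b) {
    paste(sort(c(block_seq[[a]], block_seq[[b]])), collapse = "|")
  })
  keep <- rep(TRUE, nrow(recs))
  for (m in unique(motif[duplicated(motif)])) {
    idx <- which(motif == m)
    if (length(unique(recs$kd_nM[idx])) > 1L) {
      keep[idx] <- FALSE # conflicting K_d for one motif: drop all
    } else {
      keep[idx[-1L]] <- FALSE # identical duplicates: keep the first
    }
  }
  excluded <- recs[!keep, , drop = FALSE]
  dataset$records <- recs[keep, , drop = FALSE]
  list(dataset = dataset, excluded = excluded)
}

#' Class labelings for evaluation and stratification
#'
#' Emits the two labelings used downstream: the ROC labeling (strong:
#' K_d < `strong_cut`; weak/non: K_d >= `weak_cut`; everything between is
#' excluded from AUC) and the stratification labeling used to balance
#' cross-validation folds (< `binder_lo` / `binder_lo`..`weak_cut` /
#' >= `weak_cut`).
#'
#' @param dataset A `cc_dataset`.
#' @param strong_cut,weak_cut,binder_lo Class boundaries in nM.
#' @return Records tibble with added `auc_class` and `stratum`.
#' @export
label_classes <- function(dataset, strong_cut = 250, weak_cut = 5000, binder_lo = 50) {
  dplyr::mutate(
    dataset$records,
    auc_class = dplyr::case_when(
      .data$kd_nM < strong_cut ~ "strong",
      .data$kd_nM >= weak_cut ~ "weak_non",
      TRUE ~ "intermediate"
    ),
    stratum = dplyr::case_when(
      .data$kd_nM < binder_lo ~ "strong_binder",
      .data$kd_nM < weak_cut ~ "weaker_binder",
      TRUE ~ "non_binder"
    )
  )
}

#' Full curation pipeline
#'
#' Applies, in order: the asparagine-mismatch filter, the PSSM outlier
#' filter and the variant-conflict filter.
#'
#' @param dataset A `cc_dataset`.
#' @param pssm_fraction Fraction for [pssm_outlier_filter()]; `NULL` skips it.
#' @param asn_filter,variant_filter Logical switches.
#' @return List with the curated `dataset` and an `exclusions` tibble
#'   (`step`, `idA`, `idB`).
#' @export
curate <- function(dataset, asn_filter = TRUE, pssm_fraction = 0.1,
                   variant_filter = TRUE) {
  exclusions <- list()
  if (asn_filter) {
    st <- filter_asn_mismatch(dataset)
    dataset <- st$dataset
    exclusions$asn_mismatch <- st$excluded[, c("idA", "idB")]
  }
  if (!is.null(pssm_fraction)) {
    st <- pssm_outlier_filter(dataset, fraction = pssm_fraction)
    dataset <- st$dataset
    exclusions$pssm_outlier <- tibble(idA = st$excluded_proteins$id, idB = NA_character_)
  }
  if (variant_filter) {
    st <- filter_variant_conflicts(dataset)
    dataset <- st$dataset
    exclusions$variant_conflict <- st$excluded[, c("idA", "idB")]
  }
  list(dataset = dataset,
       exclusions = dplyr::bind_rows(exclusions, .id = "step"))
}
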