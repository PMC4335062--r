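# helper: coil with chosen a-position residues per block (other positions
# fixed to a neutral pattern); blocks are (f,g,a,b,c,d,e)
coil_with_a <- function(a_residues, id) {
  blocks <- vapply(a_residues, function(a) paste0("FG", a, "ACLE"), character(1))
  assign_register(paste(blocks, collapse = ""), phase = "f", id = id)
}

test_that("asparagine mismatches in non-terminal blocks are excluded", {
  # 4 blocks; mismatch planted at block 3 (non-terminal)
  A <- coil_with_a(c("L", "L", "N", "L"), "A")
  B <- coil_with_a(c("L", "L", "L", "L"), "B")
  C <- coil_with_a(c("L", "L", "N", "L"), "C")
  D <- coil_with_a(c("L", "L", "I", "N"), "D") # Asn only in last block vs A's L
  coils <- dplyr::bind_rows(A, B, C, D)
  recs <- tibble::tibble(idA = c("A", "A", "A"), idB = c("B", "C", "D"),
                         kd_nM = c(100, 100, 100))
  ds <- as_cc_dataset(coils, recs)
  out <- filter_asn_mismatch(ds)
  # A-B: N vs L at block 3 -> excluded; A-C: N vs N -> retained;
  # A-D: N vs I only at terminal block 3?? A has N at block 3, D has I there
  expect_true(any(out$excluded$idB == "B"))
  expect_false(any(out$excluded$idB == "C"))
  # A(N at 3) faces D(I at 3): block 3 is non-terminal (of 4) -> excluded
  expect_true(any(out$excluded$idB == "D"))

  # mismatch only in the last aligned block is exempt
  E <- coil_with_a(c("L", "L", "L", "N"), "E")
  F2 <- coil_with_a(c("L", "L", "L", "I"), "F")
  ds2 <- as_cc_dataset(dplyr::bind_rows(E, F2),
                       tibble::tibble(idA = "E", idB = "F", kd_nM = 50))
  out2 <- filter_asn_mismatch(ds2)
  expect_equal(nrow(out2$excluded), 0L)
  expect_equal(nrow(out2$dataset$records), 1L)
})

test_that("planted asparagine mismatches are exactly the removed records", {
  set.seed(55)
  n <- 20
  coils <- purrr::map_dfr(seq_len(n), function(i) {
    a_res <- sample(c("L", "K", "A", "T"), 5, replace = TRUE)
    coil_with_a(a_res, sprintf("P%02d", i))
  })
  pairs <- t(combn(n, 2))[sample(choose(n, 2), 40), ]
  recs <- tibble::tibble(idA = coils$id[pairs[, 1]], idB = coils$id[pairs[, 2]],
                         kd_nM = runif(40, 10, 4000))
  # plant mismatches in 6 random records at an internal block
  planted <- sample(40, 6)
  for (r in planted) {
    blk <- sample(2:4, 1)
    pa <- recs$idA[r]; pb <- recs$idB[r]
    sa <- coils$sequence[coils$id == pa]
    substr(sa, (blk - 1) * 7 + 3, (blk - 1) * 7 + 3) <- "N"
    coils$sequence[coils$id == pa] <- sa
    sb <- coils$sequence[coils$id == pb]
    substr(sb, (blk - 1) * 7 + 3, (blk - 1) * 7 + 3) <- sample(c("V", "L", "I"), 1)
    coils$sequence[coils$id == pb] <- sb
  }
  ds <- as_cc_dataset(coils, recs)
  out <- filter_asn_mismatch(ds)
  got <- paste(out$excluded$idA, out$excluded$idB)
  # independent literal rescan: planting into shared proteins can create
  # further true mismatches, so the oracle re-derives the full exclusion set
  want <- character(0)
  for (r in seq_len(nrow(ds$records))) {
    sa <- coils$sequence[coils$id == ds$records$idA[r]]
    sb <- coils$sequence[coils$id == ds$records$idB[r]]
    for (blk in 2:4) { # internal blocks of the 5-block coils
      ra <- substr(sa, (blk - 1) * 7 + 3, (blk - 1) * 7 + 3)
      rb <- substr(sb, (blk - 1) * 7 + 3, (blk - 1) * 7 + 3)
      if ((ra == "N" && rb %in% c("V", "L", "I")) ||
          (rb == "N" && ra %in% c("V", "L", "I"))) {
        want <- c(want, paste(ds$records$idA[r], ds$records$idB[r]))
        break
      }
    }
  }
  expect_setequal(got, want)
  expect_true(all(paste(pmin(recs$idA[planted], recs$idB[planted]),
                        pmax(recs$idA[planted], recs$idB[planted])) %in% got))
})

test_that("PSSM probabilities and scores match hand-computed counts", {
  P1 <- coil_with_a(c("L", "L", "L"), "P1")
  P2 <- coil_with_a(c("L", "L", "K"), "P2")
  P3 <- coil_with_a(c("W", "W", "W"), "P3")
  coils <- dplyr::bind_rows(P1, P2, P3)
  pssm <- build_pssm(coils)
  # at position a: counts L=5, K=1, W=3 (+1 smoothing over 20 residues)
  p_a_W <- (3 + 1) / (9 + 20)
  expect_equal(unname(pssm$p_pos["W", "a"]), p_a_W)
  # background over all residues: fixed F,G,A,C,L,E pattern (9 each) plus
  # the a residues; W appears only at a -> total W count 3 (+1), 63+20 total
  expect_equal(unname(pssm$p_bg[["W"]]), 4 / 83)
  expect_equal(unname(pssm$scores["W", "a"]), -log(p_a_W / (4 / 83)))
  expect_equal(unname(pssm$scores["L", "a"]), -log((6 / 29) / (15 / 83)))
})

test_that("a protein with uncharacteristic core residues is removed first", {
  # 11 ordinary proteins; W occurs in the background only at surface b
  # positions, so the one protein carrying W at its a positions is the
  # outlier with the highest (least characteristic) PSSM score
  set.seed(12)
  mk <- function(a_res, b_res, id) {
    blocks <- vapply(seq_along(a_res), function(i)
      paste0("FG", a_res[i], b_res[i], "CLE"), character(1))
    assign_register(paste(blocks, collapse = ""), phase = "f", id = id)
  }
  coils <- purrr::map_dfr(1:11, function(i)
    mk(sample(c("L", "N", "K"), 3, TRUE), sample(c("A", "W"), 3, TRUE),
       sprintf("P%02d", i)))
  outlier <- mk(c("W", "W", "W"), c("A", "A", "A"), "P12")
  coils <- dplyr::bind_rows(coils, outlier)
  recs <- tibble::tibble(idA = coils$id, idB = coils$id, kd_nM = 100)
  ds <- as_cc_dataset(coils, recs)
  scores <- pssm_outlier_filter(ds, fraction = 0.05)$scores
  expect_equal(scores$id[which.max(scores$score)], "P12")
  out <- pssm_outlier_filter(ds, fraction = 0.05) # ceiling(0.05*12) = 1
  expect_equal(out$excluded_proteins$id, "P12")
  expect_false(any(out$dataset$records$idA == "P12" |
                     out$dataset$records$idB == "P12"))
})

test_that("the outlier filter removes exactly ceiling(fraction * n) proteins", {
  coils <- simulate_coils(220, blocks_per_protein = 2, seed = 8)
  recs <- tibble::tibble(idA = coils$id, idB = coils$id, kd_nM = 100)
  ds <- as_cc_dataset(coils, recs)
  out <- pssm_outlier_filter(ds, fraction = 0.1)
  expect_equal(nrow(out$excluded_proteins), 22L)

  # degenerate input: all proteins identical -> ties broken by id order
  same <- purrr::map_dfr(1:10, function(i)
    assign_register(strrep("LKALEQE", 2), phase = "f", id = sprintf("Q%02d", i)))
  ds2 <- as_cc_dataset(same, tibble::tibble(idA = same$id, idB = same$id, kd_nM = 10))
  out2 <- pssm_outlier_filter(ds2, fraction = 0.25)
  expect_equal(out2$excluded_proteins$id, c("Q01", "Q02", "Q03"))
})

test_that("variant conflicts are removed; agreeing duplicates deduplicate", {
  base <- strrep("FGLACLE", 3)
  A1 <- assign_register(base, phase = "f", id = "A1")
  A2 <- assign_register(paste0(base, "KE"), phase = "f", id = "A2") # same blocks
  B <- assign_register(strrep("FGKAALE", 3), phase = "f", id = "B")
  coils <- dplyr::bind_rows(A1, A2, B)
  # same motif pair (A*, B) with conflicting K_d -> both removed
  ds <- as_cc_dataset(coils, tibble::tibble(idA = c("A1", "A2"), idB = c("B", "B"),
                                            kd_nM = c(50, 400)))
  out <- filter_variant_conflicts(ds)
  expect_equal(nrow(out$dataset$records), 0L)
  expect_equal(nrow(out$excluded), 2L)
  # same motif, same K_d -> one kept
  ds2 <- as_cc_dataset(coils, tibble::tibble(idA = c("A1", "A2"), idB = c("B", "B"),
                                             kd_nM = c(50, 50)))
  out2 <- filter_variant_conflicts(ds2)
  expect_equal(nrow(out2$dataset$records), 1L)
  # different motifs (one residue differs) -> both kept
  C <- assign_register(sub("LAC", "IAC", base), phase = "f", id = "C")
  ds3 <- as_cc_dataset(dplyr::bind_rows(A1, C, B),
                       tibble::tibble(idA = c("A1", "C"), idB = c("B", "B"),
                                      kd_nM = c(50, 400)))
  out3 <- filter_variant_conflicts(ds3)
  expect_equal(nrow(out3$dataset$records), 2L)
})

test_that("class labelings follow the affinity boundaries", {
  coils <- dplyr::bind_rows(coil_with_a(c("L", "L"), "A"))
  mk <- function(kd) {
    ds <- as_cc_dataset(coils, tibble::tibble(idA = "A", idB = "A", kd_nM = kd))
    label_classes(ds)
  }
  # K_d = 100 nM: below the 250 nM strong-interaction boundary for the ROC
  # labeling, but in the 50-5000 nM "weaker binder" stratum
  l100 <- mk(100)
  expect_equal(l100$auc_class, "strong")
  expect_equal(l100$stratum, "weaker_binder")
  l1000 <- mk(1000)
  expect_equal(l1000$auc_class, "intermediate")
  expect_equal(l1000$stratum, "weaker_binder")
  l5000 <- mk(5000)
  expect_equal(l5000$auc_class, "weak_non")
  expect_equal(l5000$stratum, "non_binder")
  l10 <- mk(10)
  expect_equal(l10$auc_class, "strong")
  expect_equal(l10$stratum, "strong_binder")
})

test_that("asn and variant filters are idempotent", {
  toy <- worked_toy()
  once <- filter_asn_mismatch(toy$dataset)
  twice <- filter_asn_mismatch(once$dataset)
  expect_equal(twice$dataset$records, once$dataset$records)
  expect_equal(nrow(twice$excluded), 0L)
  v1 <- filter_variant_conflicts(toy$dataset)
  v2 <- filter_variant_conflicts(v1$dataset)
  expect_equal(v2$dataset$records, v1$dataset$records)
})

test_that("the curation pipeline runs end to end and reports exclusions", {
  toy <- worked_toy()
  out <- curate(toy$dataset, pssm_fraction = 0.1)
  expect_s3_class(out$dataset, "cc_dataset")
  expect_true(all(c("step") %in% names(out$exclusions)) || nrow(out$exclusions) == 0)
  expect_lte(nrow(out$dataset$records), nrow(toy$dataset$records))
})
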