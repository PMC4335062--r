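test_that("library building dedupes, flags N-terminal blocks, and prefilters", {
  c1 <- assign_register(strrep("FGLACLE", 2), phase = "f", id = "A")
  c2 <- assign_register(paste0("FGLACLE", "FGNACIE"), phase = "f", id = "B")
  lib <- build_library(dplyr::bind_rows(c1, c2), prefilter = FALSE)
  expect_equal(nrow(lib), 2L) # shared heptad deduped
  expect_true(lib$n_terminal[lib$heptad == "FGLACLE"])
  # d=W removed by the a/d alphabet prefilter
  c3 <- assign_register(strrep("FGLACWE", 2), phase = "f", id = "C")
  lib2 <- build_library(dplyr::bind_rows(c1, c3), prefilter = TRUE)
  expect_false("FGLACWE" %in% lib2$heptad)
  expect_true("FGLACLE" %in% lib2$heptad)
})

test_that("design-space combinatorics match the closed forms", {
  expect_equal(design_space_size(1303, 6), 1303^6)
  expect_equal(basis_heptad_count(), 1000L)
})

test_that("decomposition assigns within-block and junction mass correctly", {
  target <- assign_register(strrep("FGNACLE", 3), phase = "f", id = "T")
  lib <- toy_library(c("FGLACLE", "FGNACIE", "FGKACVE"))
  # aa-only model: every aa contact is within one design block -> c == 0
  m_aa <- cc_model(w = c("aa:L-N" = -1, "aa:N-N" = 2, "aa:K-N" = 0.5))
  dec <- decompose(m_aa, target, lib, M = 3)
  expect_true(all(vapply(dec$c, function(x) all(x == 0), logical(1))))
  expect_equal(dec$s[1, 1], -1) # lib1 a=L vs target a=N
  expect_equal(dec$s[2, 2], 2)
  # every pair category has exactly one design-chain residue, so pair mass
  # is always block-local; junction corrections arise from triplets whose
  # two same-chain residues straddle a block boundary (e.g. d_i-a_{i+1}-d'_i)
  m_da <- cc_model(w = c("da:L-N" = 1.5))
  dec2 <- decompose(m_da, target, lib, M = 3)
  expect_true(all(vapply(dec2$c, function(x) all(x == 0), logical(1))))
  expect_gt(sum(dec2$s != 0), 0)
  m_dad <- cc_model(w = c("dad:L-N-L" = 1, "dad:L-L-L" = -1, "dad:I-N-L" = 0.7))
  dec3 <- decompose(m_dad, target, lib, M = 3)
  # role 1 (design supplies d_i and a_{i+1}) is junction mass; role 2
  # (design supplies only the primed d'_i) stays block-local
  in_c <- sum(vapply(dec3$c, function(x) sum(x != 0), numeric(1)))
  expect_gt(in_c, 0)
})

test_that("block + junction scores reproduce the full model score exactly", {
  set.seed(606)
  for (rep in 1:10) {
    model <- random_model(600 + rep)
    target <- random_coil(n_blocks = sample(3:4, 1), id = "T")
    lib <- toy_library(vapply(1:5, function(i)
      paste(sample(AA, 7, TRUE), collapse = ""), character(1)))
    M <- 3
    dec <- decompose(model, target, lib, M)
    for (k in 1:10) {
      pick <- sample(5, M, replace = TRUE)
      total <- sum(dec$s[cbind(pick, 1:M)]) +
        sum(vapply(1:(M - 1), function(i) dec$c[[i]][pick[i], pick[i + 1]],
                   numeric(1)))
      seqn <- paste(lib$heptad[pick], collapse = "")
      dcoil <- assign_register(seqn, phase = "f", id = "D")
      full <- score_pair(model, dcoil, target)
      expect_equal(total + model$intercept, full, tolerance = 1e-9)
    }
  }
})

test_that("junction admissibility equals a brute-force scan of native pairs", {
  set.seed(77)
  natives <- purrr::map_dfr(1:5, function(i) random_coil(3, sprintf("N%d", i)))
  lib <- build_library(natives, prefilter = FALSE)
  allowed <- junction_rules(lib, natives)
  # oracle: literal double loop over library entries and native sequences
  obs_pairs <- function(off, lab1, lab2) {
    out <- character(0)
    for (i in seq_len(nrow(natives))) {
      res <- strsplit(natives$sequence[i], "")[[1]]
      lab <- strsplit(natives$register[i], "")[[1]]
      for (p in seq_along(res)) {
        if (p + off <= length(res) && lab[p] == lab1 && lab[p + off] == lab2)
          out <- c(out, paste0(res[p], res[p + off]))
      }
    }
    out
  }
  EF <- obs_pairs(1, "e", "f"); DG <- obs_pairs(3, "d", "g"); EA <- obs_pairs(3, "e", "a")
  for (j in seq_len(nrow(lib))) for (k in seq_len(nrow(lib))) {
    e_j <- substr(lib$heptad[j], 7, 7); d_j <- substr(lib$heptad[j], 6, 6)
    f_k <- substr(lib$heptad[k], 1, 1); g_k <- substr(lib$heptad[k], 2, 2)
    a_k <- substr(lib$heptad[k], 3, 3)
    want <- paste0(e_j, f_k) %in% EF && paste0(d_j, g_k) %in% DG &&
      paste0(e_j, a_k) %in% EA
    expect_equal(allowed[j, k], want)
  }
  # a native coil's own adjacencies are always admissible
  bl <- coil_blocks(natives[1, ])
  j <- match(bl$heptad[1], lib$heptad); k <- match(bl$heptad[2], lib$heptad)
  expect_true(allowed[j, k])
})

test_that("composition constraints fix the documented variables to zero", {
  lib <- toy_library(c("FGLACHE",  # d=H
                       "FGEACLE",  # a=E
                       "FGNACLE",  # a=N (polar)
                       "FGLACME",  # d=M
                       "FGKACLE")) # a=K (polar)
  lib$n_terminal[5] <- TRUE
  cons <- composition_constraints(lib, M = 4)
  expect_false(any(cons$allowed[1, 1:3])) # His at d only in the last block
  expect_true(cons$allowed[1, 4])
  expect_false(any(cons$allowed[2, 2:4])) # Glu at a only in the first block
  expect_true(cons$allowed[2, 1])
  expect_false(cons$allowed[3, 1]) # Asn at a not in terminal blocks
  expect_false(cons$allowed[3, 4])
  expect_true(cons$allowed[3, 2])
  expect_false(any(cons$allowed[5, 2:4])) # N-terminal entry only at block 1
  expect_equal(cons$met_d, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(cons$polar_a, c(FALSE, TRUE, TRUE, FALSE, TRUE))
})

test_that("the rare-pair veto reproduces an exhaustive strong-binder count", {
  sim <- {
    coils <- simulate_coils(15, blocks_per_protein = 3, seed = 44)
    pm <- plant_model(seed = 45)
    simulate_dataset(coils, pm, n_pairs = 60, noise_sd = 0.3,
                     binder_fraction = 0.5, seed = 46)
  }
  sp <- rare_core_pairs(sim$dataset, strong_cut = 250)
  # oracle: count aligned a/a and d/d pairs over strong records literally
  strong <- sim$dataset$records[sim$dataset$records$kd_nM < 250, ]
  cnt <- list()
  for (r in seq_len(nrow(strong))) {
    for (pos in c("a", "d")) {
      slot <- if (pos == "a") 3 else 6
      sa <- sim$dataset$coils$sequence[sim$dataset$coils$id == strong$idA[r]]
      sb <- sim$dataset$coils$sequence[sim$dataset$coils$id == strong$idB[r]]
      for (b in 1:3) {
        r1 <- substr(sa, (b - 1) * 7 + slot, (b - 1) * 7 + slot)
        r2 <- substr(sb, (b - 1) * 7 + slot, (b - 1) * 7 + slot)
        key <- paste(pos, min(r1, r2), max(r1, r2))
        cnt[[key]] <- (cnt[[key]] %||% 0L) + 1L
      }
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  expect_equal(nrow(sp), length(cnt))
  for (i in seq_len(nrow(sp))) {
    expect_equal(sp$n[i], cnt[[paste(sp$pos[i], sp$res1[i], sp$res2[i])]])
  }
})

test_that("a forced library yields the unique assembly", {
  target <- assign_register(strrep("FGNACLE", 3), phase = "f", id = "T")
  lib <- toy_library("FGLACLE")
  m <- random_model(9)
  sol <- solve_design(m, target, lib, M = 3)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$sequence, strrep("FGLACLE", 3))
  # reported target score is reproduced from scratch
  chk <- verify_solution(sol, m, target)
  expect_true(all(chk$ok))
})

test_that("branch-and-bound equals exhaustive enumeration on toy instances", {
  set.seed(99)
  for (rep in 1:6) {
    model <- random_model(900 + rep)
    target <- random_coil(n_blocks = 4, id = "T")
    nlib <- sample(4:6, 1); M <- sample(2:3, 1)
    lib <- toy_library(vapply(seq_len(nlib), function(i)
      paste(sample(AA, 7, TRUE), collapse = ""), character(1)))
    offs <- dplyr::bind_rows(random_coil(3, "O1"), random_coil(3, "O2"))
    for (with_off in c(FALSE, TRUE)) {
      ot <- if (with_off) offs else NULL
      sol <- solve_design(model, target, lib, off_targets = ot, M = M,
                          mode = "relative", delta = 1)
      ref <- enumerate_designs(model, target, lib, M, off_targets = ot,
                               mode = "relative", delta = 1)
      if (is.null(ref)) {
        expect_equal(sol$status, "infeasible")
      } else {
        expect_equal(sol$status, "optimal")
        expect_equal(sol$S_target, ref$score, tolerance = 1e-9)
      }
    }
  }
})

test_that("enumeration agreement holds under junction and composition constraints", {
  set.seed(111)
  for (rep in 1:4) {
    model <- random_model(1100 + rep)
    target <- random_coil(n_blocks = 3, id = "T")
    natives <- purrr::map_dfr(1:4, function(i) random_coil(3, sprintf("N%d", i)))
    lib <- build_library(natives, prefilter = FALSE)
    lib <- lib[seq_len(min(6, nrow(lib))), ]
    M <- 3
    allowed <- junction_rules(lib, natives)
    cons <- composition_constraints(lib, M)
    sol <- solve_design(model, target, lib, M = M,
                        junction_allowed = allowed, constraints = cons)
    ref <- enumerate_designs(model, target, lib, M,
                             junction_allowed = allowed, constraints = cons)
    if (is.null(ref)) {
      expect_equal(sol$status, "infeasible")
    } else {
      expect_equal(sol$S_target, ref$score, tolerance = 1e-9)
    }
  }
})

test_that("the optimum is monotone as constraints are added", {
  model <- random_model(13)
  target <- random_coil(n_blocks = 3, id = "T", seed = 5)
  lib <- toy_library(vapply(1:6, function(i) {
    set.seed(200 + i); paste(sample(AA, 7, TRUE), collapse = "")
  }, character(1)))
  off <- random_coil(3, "O", seed = 6)
  s_free <- solve_design(model, target, lib, M = 3)
  s_gap <- solve_design(model, target, lib, off_targets = off, M = 3,
                        mode = "relative", delta = 2)
  if (s_gap$status == "optimal") expect_gte(s_gap$S_target, s_free$S_target - 1e-9)
  cons <- composition_constraints(lib, M = 3)
  s_cons <- solve_design(model, target, lib, M = 3, constraints = cons)
  if (s_cons$status == "optimal") expect_gte(s_cons$S_target, s_free$S_target - 1e-9)
  # two Met-at-d heptads forced -> cardinality 2 > 1 is infeasible
  lib_mm <- toy_library(c("FGLACME", "FGKACME"))
  cons_mm <- composition_constraints(lib_mm, M = 2)
  expect_equal(solve_design(model, target, lib_mm, M = 2,
                            constraints = cons_mm)$status, "infeasible")
})

test_that("verification flags corrupted solutions and gap shortfalls", {
  model <- random_model(21)
  target <- random_coil(n_blocks = 3, id = "T", seed = 7)
  off <- random_coil(3, "O", seed = 8)
  lib <- toy_library(vapply(1:5, function(i) {
    set.seed(300 + i); paste(sample(AA, 7, TRUE), collapse = "")
  }, character(1)))
  sol <- solve_design(model, target, lib, off_targets = off, M = 3,
                      mode = "relative", delta = -10) # easily feasible
  expect_equal(sol$status, "optimal")
  ok <- verify_solution(sol, model, target, off)
  expect_true(all(ok$ok))
  # corrupt one heptad: the recomputed score no longer matches
  bad <- sol
  substr(bad$sequence, 3, 3) <- if (substr(bad$sequence, 3, 3) == "A") "C" else "A"
  chk <- verify_solution(bad, model, target, off)
  expect_false(chk$ok[chk$check == "target_score_match"])
  # a reported gap shortfall is flagged
  short <- sol
  short$delta <- max(short$S_off - short$S_target) + 0.1
  chk2 <- verify_solution(short, model, target, off)
  expect_false(all(chk2$ok[grepl("^gap_", chk2$check)]))
})

test_that("the exported LP file contains the exact integer program", {
  model <- random_model(31)
  target <- random_coil(n_blocks = 2, id = "T", seed = 9)
  lib <- toy_library(c("FGLACLE", "FGNACIE"))
  path <- withr::local_tempfile(fileext = ".lp")
  export_lp(model, target, lib, path, M = 2)
  txt <- readLines(path)
  expect_true(any(grepl("^Minimize", txt)))
  expect_true(any(grepl("assign_1", txt)))
  expect_true(any(grepl("linkk_1_1", txt)))
  expect_true(any(grepl("^Binary", txt)))
  expect_true(any(grepl("x_2_2", txt)))
})
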