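## Heptad-assembly design: build a library of native 7-residue modules,
## decompose the scoring model into per-block and junction terms, and find
## the optimal assembly by exact branch-and-bound under knowledge-based
## constraints and off-target specificity requirements.

## Within-block slot order of an f-anchored heptad.
BLOCK_ORDER <- c("f", "g", "a", "b", "c", "d", "e")

lib_res <- function(library, pos) {
  idx <- match(pos, BLOCK_ORDER)
  substr(library$heptad, idx, idx)
}

#' Build a heptad library from registered coils
#'
#' Slides an f-anchored 7-residue window over each coil, deduplicates the
#' resulting heptads, flags those that occur as the first complete block of
#' any source (candidate N-terminal modules), and optionally prefilters to
#' heptads whose core residues come from the frequent bZIP alphabets
#' (`a` in L,N,V,I,K,A,R,T; `d` in L,H,V,M,I).
#'
#' @param coils Registered-coil tibble (native sources).
#' @param extra Optional additional coils (e.g. previously designed binders).
#' @param prefilter Apply the a/d alphabet prefilter (default `TRUE`).
#' @return Tibble with columns `heptad` (7-mer, `(f,g,a,b,c,d,e)` order),
#'   `sources` (comma-joined ids), `n_terminal`.
#' @export
build_library <- function(coils, extra = NULL, prefilter = TRUE) {
  all_coils <- dplyr::bind_rows(coils, extra)
  blocks <- coil_blocks(all_coils)
  if (nrow(blocks) == 0L) stop("no complete heptad blocks in input coils")
  lib <- blocks |>
    dplyr::group_by(.data$heptad) |>
    dplyr::summarise(sources = paste(unique(.data$id), collapse = ","),
                     n_terminal = any(.data$block == 1L), .groups = "drop")
  if (prefilter) {
    ok <- lib_res(lib, "a") %in% CORE_ALPHABETS$a &
      lib_res(lib, "d") %in% CORE_ALPHABETS$d
    lib <- lib[ok, , drop = FALSE]
  }
  lib
}

#' Combinatorics of the design space
#'
#' @param n_entries Library size.
#' @param M Number of design blocks.
#' @return `design_space_size`: number of distinct assemblies
#'   (`n_entries^M`, as a double). `basis_heptad_count`: size of the
#'   frequent-residue basis over the a, d, e, g positions
#'   (8 x 5 x 5 x 5 = 1000).
#' @export
design_space_size <- function(n_entries, M) {
  as.double(n_entries)^M
}

#' @rdname design_space_size
#' @export
basis_heptad_count <- function() {
  as.integer(prod(lengths(CORE_ALPHABETS)))
}

## Enumerate the contact instances of (design template with M blocks,
## partner), with design residues symbolic. Each instance is either
## within-block (all design residues in one block) or spans a junction of
## two consecutive blocks; cross-block pair contributions as well as
## cross-block triplets go to the junction term, which is what makes the
## block + junction decomposition exactly equal to the full dimer score.
design_instances <- function(partner, M) {
  mP <- heptad_matrix(partner$sequence[1], partner$register[1])
  out <- list()
  for (role in 1:2) {
    for (name in names(CC_CATEGORIES)) {
      cat <- CC_CATEGORIES[[name]]
      if (role == 2L && isTRUE(cat$selfsym)) next
      design_chain <- role # chain index played by the design
      for (i in -1:(M + 1L)) {
        slots_sym <- list(); res_part <- list(); ok <- TRUE
        for (s in cat$slots) {
          h <- i + s$off
          if (s$chain == design_chain) {
            if (s$pos %in% c("f", "g")) {
              b <- h + 1L
              idx <- match(s$pos, BLOCK_ORDER)
            } else {
              b <- h
              idx <- match(s$pos, BLOCK_ORDER)
            }
            if (is.na(b) || b < 1L || b > M) { ok <- FALSE; break }
            slots_sym[[length(slots_sym) + 1L]] <- c(block = b, idx = idx)
            res_part[[length(res_part) + 1L]] <- NA # placeholder keeps order
          } else {
            r <- hm_at(mP, h, s$pos)
            if (is.na(r)) { ok <- FALSE; break }
            res_part[[length(res_part) + 1L]] <- r
          }
        }
        if (!ok || length(slots_sym) == 0L) next
        bl <- vapply(slots_sym, `[[`, numeric(1), "block")
        if (max(bl) - min(bl) > 1L)
          stop("internal error: contact spans more than two blocks")
        out[[length(out) + 1L]] <- list(
          category = name, symmetric = isTRUE(cat$symmetric),
          residues = res_part, slots = slots_sym,
          b_lo = as.integer(min(bl)), b_hi = as.integer(max(bl))
        )
      }
    }
  }
  out
}

## Key strings for an instance given design residue vectors per symbolic
## slot (list of character vectors, recycled to a common length).
instance_keys <- function(inst, design_res) {
  parts <- list(); di <- 0L
  for (t in seq_along(inst$residues)) {
    if (is.na(inst$residues[[t]][1]) && !is.character(inst$residues[[t]])) {
      di <- di + 1L
      parts[[t]] <- design_res[[di]]
    } else {
      parts[[t]] <- inst$residues[[t]]
    }
  }
  n <- max(lengths(parts))
  parts <- lapply(parts, rep_len, n)
  if (inst$symmetric && length(parts) == 2L) {
    lo <- ifelse(parts[[1]] <= parts[[2]], parts[[1]], parts[[2]])
    hi <- ifelse(parts[[1]] <= parts[[2]], parts[[2]], parts[[1]])
    parts <- list(lo, hi)
  }
  paste0(inst$category, ":", do.call(paste, c(parts, sep = "-")))
}

#' Decompose the scoring model into block and junction terms
#'
#' Pre-computes, for a fixed partner, the score `s[j, i]` of placing library
#' heptad `j` at design block `i` (all contact contributions whose
#' design-chain residues lie inside block `i`) and the junction corrections
#' `c[[i]][j, k]` (contributions spanning blocks `i` and `i+1`). For any
#' complete assignment, `sum(s) + sum(c)` equals the full model score of the
#' assembled sequence against the partner exactly (up to the model
#' intercept, which is assignment-independent).
#'
#' @param model A `cc_model`.
#' @param partner One-row registered-coil tibble (target or off-target),
#'   aligned to the design frame at its first complete block.
#' @param library Heptad library from [build_library()].
#' @param M Number of design blocks.
#' @return A `cc_decomposition`: list with `s` (N x M), `c` (list of M-1
#'   N x N matrices), `library`, `M`, `partner_id`.
#' @export
decompose <- function(model, partner, library, M) {
  N <- nrow(library)
  W <- model$w
  wof <- function(keys) {
    v <- W[keys]
    v[is.na(v)] <- 0
    unname(v)
  }
  s <- matrix(0, N, M)
  cjun <- lapply(seq_len(max(M - 1L, 0L)), function(i) matrix(0, N, N))
  insts <- design_instances(partner, M)
  for (inst in insts) {
    if (inst$b_lo == inst$b_hi) {
      idxs <- vapply(inst$slots, `[[`, numeric(1), "idx")
      tup <- do.call(paste0, lapply(idxs, function(ix) substr(library$heptad, ix, ix)))
      u <- unique(tup)
      ures <- lapply(seq_along(idxs), function(t)
        substr(library$heptad[match(u, tup)], idxs[t], idxs[t]))
      keys <- instance_keys(inst, ures)
      s[, inst$b_lo] <- s[, inst$b_lo] + wof(keys)[match(tup, u)]
    } else {
      b <- inst$b_lo
      idx_lo <- vapply(inst$slots[vapply(inst$slots, `[[`, numeric(1), "block") == b],
                       `[[`, numeric(1), "idx")
      idx_hi <- vapply(inst$slots[vapply(inst$slots, `[[`, numeric(1), "block") == b + 1L],
                       `[[`, numeric(1), "idx")
      tup_j <- do.call(paste0, lapply(idx_lo, function(ix) substr(library$heptad, ix, ix)))
      tup_k <- do.call(paste0, lapply(idx_hi, function(ix) substr(library$heptad, ix, ix)))
      uj <- unique(tup_j); uk <- unique(tup_k)
      grid <- expand.grid(j = seq_along(uj), k = seq_along(uk))
      ## rebuild the per-slot design residues in original slot order (the
      ## q-th symbolic slot corresponds to the q-th placeholder in residues)
      res_by_slot <- vector("list", length(inst$residues))
      q <- 0L; lo_t <- 0L; hi_t <- 0L
      for (t in seq_along(inst$residues)) {
        if (is.character(inst$residues[[t]])) next
        q <- q + 1L
        sl <- inst$slots[[q]]
        if (sl[["block"]] == b) {
          lo_t <- lo_t + 1L
          res_by_slot[[t]] <- substr(uj[grid$j], lo_t, lo_t)
        } else {
          hi_t <- hi_t + 1L
          res_by_slot[[t]] <- substr(uk[grid$k], hi_t, hi_t)
        }
      }
      keys <- instance_keys_ordered(inst, res_by_slot)
      wv <- matrix(wof(keys), nrow = length(uj))
      cjun[[b]] <- cjun[[b]] + wv[match(tup_j, uj), match(tup_k, uk), drop = FALSE]
    }
  }
  structure(list(s = s, c = cjun, library = library, M = M,
                 partner_id = partner$id[1] %||% NA_character_),
            class = "cc_decomposition")
}

## As instance_keys() but with design residues supplied per original slot
## position (partner slots still taken from inst$residues).
instance_keys_ordered <- function(inst, design_by_slot) {
  parts <- list()
  for (t in seq_along(inst$residues)) {
    if (!is.character(inst$residues[[t]])) parts[[t]] <- design_by_slot[[t]]
    else parts[[t]] <- inst$residues[[t]]
  }
  n <- max(lengths(parts))
  parts <- lapply(parts, rep_len, n)
  if (inst$symmetric && length(parts) == 2L) {
    lo <- ifelse(parts[[1]] <= parts[[2]], parts[[1]], parts[[2]])
    hi <- ifelse(parts[[1]] <= parts[[2]], parts[[2]], parts[[1]])
    parts <- list(lo, hi)
  }
  paste0(inst$category, ":", do.call(paste, c(parts, sep = "-")))
}

#' Junction admissibility from native sequences
#'
#' Two heptads may be adjacent in a design only if each of the three
#' intra-chain residue pairs crossing the junction — (e of the first, f of
#' the second), (d, g) and (e, a) — occurs at those relative positions in at
#' least one native registered coil.
#'
#' @param library Heptad library.
#' @param native_coils Registered coils defining the observed pairs.
#' @return N x N logical matrix (`[j, k]`: heptad `k` may follow heptad `j`).
#' @export
junction_rules <- function(library, native_coils) {
  ef <- character(0); dg <- character(0); ea <- character(0)
  for (i in seq_len(nrow(native_coils))) {
    res <- strsplit(native_coils$sequence[i], "")[[1]]
    lab <- strsplit(native_coils$register[i], "")[[1]]
    n <- length(res)
    p_e <- which(lab == "e")
    p_d <- which(lab == "d")
    ef <- c(ef, paste0(res[p_e[p_e + 1L <= n]], res[p_e[p_e + 1L <= n] + 1L]))
    dg <- c(dg, paste0(res[p_d[p_d + 3L <= n]], res[p_d[p_d + 3L <= n] + 3L]))
    ea <- c(ea, paste0(res[p_e[p_e + 3L <= n]], res[p_e[p_e + 3L <= n] + 3L]))
  }
  e_j <- lib_res(library, "e"); f_k <- lib_res(library, "f")
  d_j <- lib_res(library, "d"); g_k <- lib_res(library, "g")
  a_k <- lib_res(library, "a")
  ok_ef <- outer(e_j, f_k, function(x, y) paste0(x, y) %in% ef)
  ok_dg <- outer(d_j, g_k, function(x, y) paste0(x, y) %in% dg)
  ok_ea <- outer(e_j, a_k, function(x, y) paste0(x, y) %in% ea)
  ok_ef & ok_dg & ok_ea
}

#' Pair counts of core a/d contacts among strong binders
#'
#' Counts how often each unordered aa' and dd' residue pair occurs in the
#' strong binders (K_d < `strong_cut`) of a dataset; pairs seen fewer than
#' twice are treated as unreliable and vetoed in design.
#'
#' @param dataset A `cc_dataset`.
#' @param strong_cut Strong-binder threshold in nM.
#' @return Tibble with `pos` ("a"/"d"), `res1 <= res2`, `n`.
#' @export
rare_core_pairs <- function(dataset, strong_cut = 250) {
  strong <- dataset$records[dataset$records$kd_nM < strong_cut, , drop = FALSE]
  counts <- list()
  for (r in seq_len(nrow(strong))) {
    al_a <- aligned_core_pairs(dataset, strong$idA[r], strong$idB[r], "a")
    al_d <- aligned_core_pairs(dataset, strong$idA[r], strong$idB[r], "d")
    counts[[length(counts) + 1L]] <- dplyr::bind_rows(
      tibble(pos = "a", pair = al_a), tibble(pos = "d", pair = al_d))
  }
  dplyr::bind_rows(counts) |>
    dplyr::count(.data$pos, .data$pair, name = "n") |>
    tidyr::separate_wider_delim("pair", "-", names = c("res1", "res2"))
}

aligned_core_pairs <- function(dataset, idA, idB, pos) {
  slot <- match(pos, BLOCK_ORDER)
  ba <- coil_blocks_str(dataset$coils$sequence[dataset$coils$id == idA],
                        dataset$coils$register[dataset$coils$id == idA])
  bb <- coil_blocks_str(dataset$coils$sequence[dataset$coils$id == idB],
                        dataset$coils$register[dataset$coils$id == idB])
  K <- min(nrow(ba), nrow(bb))
  if (K == 0L) return(character(0))
  r1 <- substr(ba$heptad[seq_len(K)], slot, slot)
  r2 <- substr(bb$heptad[seq_len(K)], slot, slot)
  paste(pmin(r1, r2), pmax(r1, r2), sep = "-")
}

#' Knowledge-based composition constraints for design
#'
#' Encodes the native-composition rules as per-block candidate masks and
#' global cardinality limits: His at `d` only in the last block; Glu at `a`
#' only in the first; Asn at `a` only in non-terminal blocks; N-terminal
#' library modules only at block 1; at most `met_d_max` Met at `d` and
#' `polar_a_max` polar residues (N, K, R, E, T, A) at `a` overall; and a
#' per-block veto of heptads whose `a`/`d` residue forms a destabilising
#' (coupling energy > 1 kcal/mol) or rarely observed (seen < 2 times among
#' strong binders) pair with the target's opposing core residue.
#'
#' @param library Heptad library.
#' @param M Number of design blocks.
#' @param target Optional target coil (needed for the pair vetoes).
#' @param coupling_energies Optional tibble `pos`, `res1`, `res2`,
#'   `energy` (kcal/mol) of measured aa'/dd' coupling energies; when absent
#'   that veto is skipped with a warning.
#' @param strong_pairs Optional tibble from [rare_core_pairs()]; when absent
#'   the rare-pair veto is skipped.
#' @param met_d_max,polar_a_max Cardinality limits.
#' @param his_d_last,glu_a_first,asn_a_internal,nterm_first Rule switches.
#' @return List with `allowed` (N x M logical), `met_d`, `polar_a` (logical
#'   per entry) and the limits.
#' @export
composition_constraints <- function(library, M, target = NULL,
                                    coupling_energies = NULL, strong_pairs = NULL,
                                    met_d_max = 1, polar_a_max = 4,
                                    his_d_last = TRUE, glu_a_first = TRUE,
                                    asn_a_internal = TRUE, nterm_first = TRUE) {
  N <- nrow(library)
  a_res <- lib_res(library, "a"); d_res <- lib_res(library, "d")
  allowed <- matrix(TRUE, N, M)
  if (his_d_last && M > 1L) allowed[d_res == "H", seq_len(M - 1L)] <- FALSE
  if (glu_a_first && M > 1L) allowed[a_res == "E", -1L] <- FALSE
  if (asn_a_internal) allowed[a_res == "N", c(1L, M)] <- FALSE
  if (nterm_first && M > 1L) allowed[library$n_terminal, -1L] <- FALSE
  if (!is.null(target)) {
    tb <- coil_blocks_str(target$sequence[1], target$register[1])
    Kt <- min(nrow(tb), M)
    pair_bad <- function(pos, res_lib, res_tgt) {
      bad <- rep(FALSE, length(res_lib))
      key1 <- pmin(res_lib, res_tgt); key2 <- pmax(res_lib, res_tgt)
      if (!is.null(coupling_energies)) {
        ce <- coupling_energies[coupling_energies$pos == pos, , drop = FALSE]
        cek <- paste(pmin(ce$res1, ce$res2), pmax(ce$res1, ce$res2))
        hit <- match(paste(key1, key2), cek)
        bad <- bad | (!is.na(hit) & ce$energy[hit] > 1)
      }
      if (!is.null(strong_pairs)) {
        sp <- strong_pairs[strong_pairs$pos == pos, , drop = FALSE]
        spk <- paste(pmin(sp$res1, sp$res2), pmax(sp$res1, sp$res2))
        hit <- match(paste(key1, key2), spk)
        n_seen <- ifelse(is.na(hit), 0L, sp$n[hit])
        bad <- bad | (n_seen < 2L)
      }
      bad
    }
    if (is.null(coupling_energies) && is.null(strong_pairs)) {
      warning("no coupling-energy table or strong-pair counts supplied; ",
              "destabilising/rare-pair vetoes skipped")
    } else {
      for (i in seq_len(Kt)) {
        ta <- substr(tb$heptad[i], 3L, 3L)
        td <- substr(tb$heptad[i], 6L, 6L)
        allowed[pair_bad("a", a_res, ta) | pair_bad("d", d_res, td), i] <- FALSE
      }
    }
  }
  list(allowed = allowed,
       met_d = d_res == "M", polar_a = a_res %in% c("N", "K", "R", "E", "T", "A"),
       met_d_max = met_d_max, polar_a_max = polar_a_max)
}

## Backward DP over blocks: value[i, j] = extreme (min or max) of
## sum_{i..M} block scores + junction terms, starting with heptad j at
## block i, restricted to allowed candidates and admissible junctions.
dp_togo <- function(s, cjun, cand, junction_allowed, maximize = FALSE) {
  M <- ncol(s); N <- nrow(s)
  ext <- if (maximize) max else min
  val <- matrix(if (maximize) -Inf else Inf, N, M)
  val[cand[[M]], M] <- s[cand[[M]], M]
  if (M > 1L) for (i in (M - 1L):1L) {
    for (j in cand[[i]]) {
      ks <- cand[[i + 1L]]
      if (!is.null(junction_allowed)) ks <- ks[junction_allowed[j, ks]]
      if (length(ks) == 0L) next
      val[j, i] <- s[j, i] + ext(cjun[[i]][j, ks] + val[ks, i + 1L])
    }
  }
  val
}

#' Design an optimal heptad assembly against a target
#'
#' Finds the assignment of one library heptad per block minimising the
#' predicted target score (log10 K_d; lower = tighter), subject to junction
#' admissibility, composition constraints and off-target specificity:
#' either a relative gap (`S_off >= S_target + delta`, default
#' `delta = 2`, i.e. a >100-fold predicted K_d separation) or absolute
#' cutoffs (`S_off >= cutoff`). The integer program is solved exactly by
#' depth-first branch-and-bound with bounds from backward dynamic programs
#' over the block chain; with a node limit the best incumbent and its
#' optimality gap are reported.
#'
#' @param model A `cc_model`.
#' @param target One-row registered-coil tibble to bind.
#' @param library Heptad library from [build_library()].
#' @param off_targets Registered-coil tibble of proteins to avoid (zero rows
#'   or `NULL` for none).
#' @param M Number of design blocks (default: the target's block count).
#' @param mode `"relative"` (gap `delta`) or `"absolute"` (per-off-target
#'   `cutoff`).
#' @param delta Required score gap in relative mode (log10 units).
#' @param cutoff Numeric cutoff(s) for absolute mode, recycled across
#'   off-targets.
#' @param junction_allowed Optional N x N logical from [junction_rules()].
#' @param constraints Optional list from [composition_constraints()].
#' @param node_limit Branch-and-bound node cap.
#' @return A `cc_design`: chosen heptads, assembled `sequence` (f-anchored
#'   register), `S_target`, `S_off`, `status` (`"optimal"`,
#'   `"node_limit"`, or `"infeasible"`), `nodes`, `bound` and `gap`.
#' @export
solve_design <- function(model, target, library, off_targets = NULL, M = NULL,
                         mode = c("relative", "absolute"), delta = 2,
                         cutoff = NULL, junction_allowed = NULL,
                         constraints = NULL, node_limit = 1e6) {
  mode <- match.arg(mode)
  if (is.null(M)) M <- nrow(coil_blocks_str(target$sequence[1], target$register[1]))
  stopifnot(M >= 1L)
  N <- nrow(library)
  dec_t <- decompose(model, target, library, M)
  offs <- if (is.null(off_targets) || nrow(off_targets) == 0L) list()
  else lapply(seq_len(nrow(off_targets)), function(i)
    decompose(model, off_targets[i, ], library, M))
  P <- length(offs)
  if (mode == "absolute" && P > 0L) {
    if (is.null(cutoff)) stop("absolute mode requires `cutoff`")
    cutoff <- rep_len(cutoff, P)
  }
  cand <- lapply(seq_len(M), function(i) {
    if (is.null(constraints)) seq_len(N) else which(constraints$allowed[, i])
  })
  if (any(lengths(cand) == 0L))
    return(infeasible_design(model, "no admissible heptad at some block"))
  met_d <- if (is.null(constraints)) rep(FALSE, N) else constraints$met_d
  polar_a <- if (is.null(constraints)) rep(FALSE, N) else constraints$polar_a
  met_max <- if (is.null(constraints)) Inf else constraints$met_d_max
  polar_max <- if (is.null(constraints)) Inf else constraints$polar_a_max
  ## remaining-minimum counters for the cardinality bounds
  min_met_togo <- rev(cumsum(rev(vapply(cand, function(k) min(met_d[k]), numeric(1)))))
  min_pol_togo <- rev(cumsum(rev(vapply(cand, function(k) min(polar_a[k]), numeric(1)))))
  min_met_togo <- c(min_met_togo, 0); min_pol_togo <- c(min_pol_togo, 0)

  f_t <- dp_togo(dec_t$s, dec_t$c, cand, junction_allowed, maximize = FALSE)
  g_off <- lapply(seq_len(P), function(p) {
    if (mode == "relative") {
      dp_togo(offs[[p]]$s - dec_t$s,
              lapply(seq_along(dec_t$c), function(i) offs[[p]]$c[[i]] - dec_t$c[[i]]),
              cand, junction_allowed, maximize = TRUE)
    } else {
      dp_togo(offs[[p]]$s, offs[[p]]$c, cand, junction_allowed, maximize = TRUE)
    }
  })

  best <- list(score = Inf, pick = NULL)
  nodes <- 0L
  hit_limit <- FALSE
  tol <- 1e-9
  recurse <- function(i, prev, cur_t, cur_off, met, pol) {
    if (nodes >= node_limit) { hit_limit <<- TRUE; return(invisible()) }
    ks <- cand[[i]]
    if (i > 1L && !is.null(junction_allowed)) ks <- ks[junction_allowed[prev[i - 1L], ks]]
    jc_t <- if (i > 1L) dec_t$c[[i - 1L]][prev[i - 1L], ] else rep(0, N)
    lb <- cur_t + jc_t[ks] + f_t[ks, i]
    ord <- order(lb)
    for (k in ks[ord]) {
      nodes <<- nodes + 1L
      new_t <- cur_t + (if (i > 1L) jc_t[k] else 0) # junction into block i
      if (new_t + f_t[k, i] >= best$score - tol) next # bound (sorted: could break, keep simple)
      new_met <- met + met_d[k]
      new_pol <- pol + polar_a[k]
      if (new_met + min_met_togo[i + 1L] > met_max) next
      if (new_pol + min_pol_togo[i + 1L] > polar_max) next
      new_off <- cur_off
      feas <- TRUE
      for (p in seq_len(P)) {
        jo <- if (i > 1L) {
          if (mode == "relative")
            offs[[p]]$c[[i - 1L]][prev[i - 1L], k] - dec_t$c[[i - 1L]][prev[i - 1L], k]
          else offs[[p]]$c[[i - 1L]][prev[i - 1L], k]
        } else 0
        new_off[p] <- cur_off[p] + jo
        req <- if (mode == "relative") delta else cutoff[p]
        if (new_off[p] + g_off[[p]][k, i] < req - tol) { feas <- FALSE; break }
      }
      if (!feas) next
      if (i == M) {
        cand_score <- new_t + dec_t$s[k, M]
        final_off <- new_off + vapply(seq_len(P), function(p)
          if (mode == "relative") offs[[p]]$s[k, M] - dec_t$s[k, M]
          else offs[[p]]$s[k, M], numeric(1))
        req <- if (mode == "relative") rep(delta, P) else cutoff
        if (cand_score < best$score - 1e-12 &&
            (P == 0L || all(final_off >= req - tol))) {
          best <<- list(score = cand_score, pick = c(prev, k))
        }
      } else {
        recurse(i + 1L, c(prev, k), new_t + dec_t$s[k, i],
                new_off + vapply(seq_len(P), function(p)
                  if (mode == "relative") offs[[p]]$s[k, i] - dec_t$s[k, i]
                  else offs[[p]]$s[k, i], numeric(1)),
                new_met, new_pol)
      }
    }
  }
  recurse(1L, integer(0), 0, rep(0, P), 0L, 0L)

  if (is.null(best$pick)) {
    status <- if (hit_limit) "node_limit" else "infeasible"
    return(infeasible_design(model, status, nodes = nodes))
  }
  pick <- best$pick
  seqs <- library$heptad[pick]
  sequence <- paste(seqs, collapse = "")
  S_target <- model$intercept + best$score
  S_off <- vapply(seq_len(P), function(p) {
    sc <- sum(offs[[p]]$s[cbind(pick, seq_len(M))])
    if (M > 1L) sc <- sc + sum(vapply(seq_len(M - 1L), function(i)
      offs[[p]]$c[[i]][pick[i], pick[i + 1L]], numeric(1)))
    model$intercept + sc
  }, numeric(1))
  names(S_off) <- if (P > 0L) off_targets$id else character(0)
  structure(list(
    heptads = tibble(block = seq_len(M), entry = pick, heptad = seqs),
    sequence = sequence, register = paste(rep(BLOCK_ORDER, M), collapse = ""),
    S_target = S_target, S_off = S_off, target_id = target$id[1],
    status = if (hit_limit) "node_limit" else "optimal",
    nodes = nodes, bound = if (hit_limit) NA_real_ else S_target,
    gap = if (hit_limit) NA_real_ else 0, mode = mode, delta = delta
  ), class = "cc_design")
}

infeasible_design <- function(model, status, nodes = 0L) {
  structure(list(heptads = tibble(block = integer(), entry = integer(),
                                  heptad = character()),
                 sequence = NA_character_, register = NA_character_,
                 S_target = NA_real_, S_off = numeric(0),
                 target_id = NA_character_, status = status,
                 nodes = nodes, bound = NA_real_, gap = NA_real_,
                 mode = NA_character_, delta = NA_real_),
            class = "cc_design")
}

#' @exportS3Method base::print
print.cc_design <- function(x, ...) {
  if (x$status %in% c("infeasible")) {
    cat("<cc_design> infeasible\n")
    return(invisible(x))
  }
  cat("<cc_design> ", x$status, ": S_target = ", signif(x$S_target, 4),
      if (length(x$S_off) > 0)
        paste0(", min off-target gap = ",
               signif(min(x$S_off) - x$S_target, 3)) else "",
      "\n  ", x$sequence, "\n", sep = "")
  invisible(x)
}

#' Independently verify a design solution
#'
#' Re-assembles the designed sequence, re-encodes it against the target and
#' every off-target with the feature encoder, recomputes scores from
#' scratch, and checks the reported target score (to 1e-9), the specificity
#' requirement, and the composition rules on the final sequence.
#'
#' @param solution A `cc_design`.
#' @param model The scoring model used.
#' @param target,off_targets Coils as passed to [solve_design()].
#' @param constraints Optional composition constraints to re-check.
#' @return Tibble of checks (`check`, `ok`, `detail`).
#' @export
verify_solution <- function(solution, model, target, off_targets = NULL,
                            constraints = NULL) {
  if (is.na(solution$sequence))
    stop("solution has no assembled sequence (status: ", solution$status, ")")
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble(check = check, ok = ok, detail = detail)
  }
  design_coil <- assign_register(solution$sequence, phase = "f", id = "design")
  s_t <- score_pair(model, design_coil, target)
  add("target_score_match", abs(s_t - solution$S_target) < 1e-9,
      sprintf("recomputed %.12f vs reported %.12f", s_t, solution$S_target))
  if (!is.null(off_targets) && nrow(off_targets) > 0L) {
    for (i in seq_len(nrow(off_targets))) {
      s_o <- score_pair(model, design_coil, off_targets[i, ])
      add(paste0("off_score_match_", off_targets$id[i]),
          abs(s_o - solution$S_off[[i]]) < 1e-9,
          sprintf("recomputed %.12f", s_o))
      if (identical(solution$mode, "relative"))
        add(paste0("gap_", off_targets$id[i]),
            s_o - s_t >= solution$delta - 1e-9,
            sprintf("gap %.4f (required %.2f)", s_o - s_t, solution$delta))
    }
  }
  if (!is.null(constraints)) {
    M <- nrow(solution$heptads)
    ok_mask <- all(constraints$allowed[cbind(solution$heptads$entry, seq_len(M))])
    add("per_block_admissible", ok_mask)
    add("met_d_limit",
        sum(constraints$met_d[solution$heptads$entry]) <= constraints$met_d_max)
    add("polar_a_limit",
        sum(constraints$polar_a[solution$heptads$entry]) <= constraints$polar_a_max)
  }
  dplyr::bind_rows(checks)
}

#' Export the design integer program in CPLEX LP format
#'
#' Writes the exact binary program (assignment variables `x_i_j`, adjacency
#' variables `z_i_j_k`, linking, junction, specificity and cardinality
#' constraints) so the problem can be handed to an external solver.
#'
#' @inheritParams solve_design
#' @param path Output file.
#' @return The path, invisibly.
#' @export
export_lp <- function(model, target, library, path, off_targets = NULL,
                      M = NULL, mode = c("relative", "absolute"), delta = 2,
                      cutoff = NULL, junction_allowed = NULL, constraints = NULL) {
  mode <- match.arg(mode)
  if (is.null(M)) M <- nrow(coil_blocks_str(target$sequence[1], target$register[1]))
  N <- nrow(library)
  dec_t <- decompose(model, target, library, M)
  offs <- if (is.null(off_targets) || nrow(off_targets) == 0L) list()
  else lapply(seq_len(nrow(off_targets)), function(i)
    decompose(model, off_targets[i, ], library, M))
  xv <- function(i, j) sprintf("x_%d_%d", i, j)
  zv <- function(i, j, k) sprintf("z_%d_%d_%d", i, j, k)
  lines <- c("Minimize", " obj:")
  terms <- c(
    unlist(lapply(seq_len(M), function(i)
      sprintf(" %+.12g %s", dec_t$s[, i], xv(i, seq_len(N))))),
    if (M > 1L) unlist(lapply(seq_len(M - 1L), function(i)
      sprintf(" %+.12g %s", as.vector(dec_t$c[[i]]),
              zv(i, rep(seq_len(N), N), rep(seq_len(N), each = N)))))
  )
  lines <- c(lines, terms, "Subject To")
  for (i in seq_len(M))
    lines <- c(lines, paste0(" assign_", i, ": ",
                             paste(sprintf("+ %s", xv(i, seq_len(N))), collapse = " "),
                             " = 1"))
  if (M > 1L) for (i in seq_len(M - 1L)) {
    for (k in seq_len(N))
      lines <- c(lines, paste0(" linkk_", i, "_", k, ": ",
                               paste(sprintf("+ %s", zv(i, seq_len(N), k)), collapse = " "),
                               " - ", xv(i + 1L, k), " = 0"))
    for (j in seq_len(N))
      lines <- c(lines, paste0(" linkj_", i, "_", j, ": ",
                               paste(sprintf("+ %s", zv(i, j, seq_len(N))), collapse = " "),
                               " - ", xv(i, j), " = 0"))
  }
  for (p in seq_along(offs)) {
    sp <- offs[[p]]$s; cp <- offs[[p]]$c
    if (mode == "relative") {
      sp <- sp - dec_t$s
      cp <- lapply(seq_along(cp), function(i) cp[[i]] - dec_t$c[[i]])
      rhs <- delta
    } else rhs <- rep_len(cutoff, length(offs))[p]
    terms <- c(
      unlist(lapply(seq_len(M), function(i)
        sprintf(" %+.12g %s", sp[, i], xv(i, seq_len(N))))),
      if (M > 1L) unlist(lapply(seq_len(M - 1L), function(i)
        sprintf(" %+.12g %s", as.vector(cp[[i]]),
                zv(i, rep(seq_len(N), N), rep(seq_len(N), each = N)))))
    )
    lines <- c(lines, paste0(" off_", p, ":"), terms, sprintf(" >= %.12g", rhs))
  }
  if (!is.null(constraints)) {
    if (any(constraints$met_d))
      lines <- c(lines, paste0(" met_d: ",
                               paste(sprintf("+ %s", xv(rep(seq_len(M), each = sum(constraints$met_d)),
                                                        rep(which(constraints$met_d), M))), collapse = " "),
                               " <= ", constraints$met_d_max))
    if (any(constraints$polar_a))
      lines <- c(lines, paste0(" polar_a: ",
                               paste(sprintf("+ %s", xv(rep(seq_len(M), each = sum(constraints$polar_a)),
                                                        rep(which(constraints$polar_a), M))), collapse = " "),
                               " <= ", constraints$polar_a_max))
    fixed0 <- which(!constraints$allowed, arr.ind = TRUE)
    for (r in seq_len(nrow(fixed0)))
      lines <- c(lines, sprintf(" fix_%d_%d: %s = 0", fixed0[r, 2L], fixed0[r, 1L],
                                xv(fixed0[r, 2L], fixed0[r, 1L])))
  }
  if (!is.null(junction_allowed) && M > 1L) {
    bad <- which(!junction_allowed, arr.ind = TRUE)
    for (i in seq_len(M - 1L)) for (r in seq_len(nrow(bad)))
      lines <- c(lines, sprintf(" jun_%d_%d_%d: %s = 0", i, bad[r, 1L], bad[r, 2L],
                                zv(i, bad[r, 1L], bad[r, 2L])))
  }
  lines <- c(lines, "Binary",
             unlist(lapply(seq_len(M), function(i) paste0(" ", xv(i, seq_len(N))))),
             if (M > 1L) unlist(lapply(seq_len(M - 1L), function(i)
               paste0(" ", zv(i, rep(seq_len(N), N), rep(seq_len(N), each = N))))),
             "End")
  writeLines(lines, path)
  invisible(path)
}
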