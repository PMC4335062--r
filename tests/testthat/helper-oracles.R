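# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / generic solvers, sharing no code path with the
# package internals they check.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ---- brute-force contact enumerator ---------------------------------------

# Literal contact-type table: each row lists (position, chain, heptad offset)
# per slot. Chain 1 is the unprimed role.
ORACLE_CONTACTS <- list(
  aa  = list(c("a", 1, 0), c("a", 2, 0)),
  dd  = list(c("d", 1, 0), c("d", 2, 0)),
  ge  = list(c("g", 1, 0), c("e", 2, 1)),
  eg  = list(c("e", 1, 0), c("g", 2, 0)),
  ad  = list(c("a", 1, 0), c("d", 2, 0)),
  da  = list(c("d", 1, 0), c("a", 2, 1)),
  de  = list(c("d", 1, 0), c("e", 2, 0)),
  ga  = list(c("g", 1, 0), c("a", 2, 1)),
  ada = list(c("a", 1, 0), c("d", 1, 0), c("a", 2, 0)),
  dad = list(c("d", 1, 0), c("a", 1, 1), c("d", 2, 0)),
  gde = list(c("g", 1, 0), c("d", 1, 1), c("e", 2, 1)),
  gae = list(c("g", 1, 0), c("a", 2, 1), c("e", 2, 1)),
  edg = list(c("e", 1, 0), c("d", 2, 0), c("g", 2, 0)),
  eag = list(c("e", 1, 0), c("a", 1, 1), c("g", 2, 0)),
  agd = list(c("a", 1, 0), c("g", 2, -1), c("d", 2, 0)),
  aed = list(c("a", 1, 0), c("e", 1, 0), c("d", 2, 0)),
  dea = list(c("d", 1, 0), c("e", 2, 0), c("a", 2, 1)),
  dga = list(c("d", 1, 0), c("g", 1, 0), c("a", 2, 1))
)
ORACLE_SYMMETRIC <- c("aa", "dd", "ge", "eg")
ORACLE_SELFSYM <- c("aa", "dd")

# residue lookup table: list pos -> named vector heptad -> residue, with
# heptad 1 anchored on the a-position of the first f-started 7-mer window.
oracle_chain_table <- function(sequence, register) {
  res <- strsplit(sequence, "")[[1]]
  lab <- strsplit(register, "")[[1]]
  f1 <- which(lab == "f")[1]
  a1 <- f1 + 2 # the a inside the first complete block
  stopifnot(lab[a1] == "a")
  tab <- list()
  for (p in c("a", "d", "e", "g")) tab[[p]] <- c()
  for (i in seq_along(res)) {
    p <- lab[i]
    if (!p %in% c("a", "d", "e", "g")) next
    # heptad of residue i: walk back to the nearest a at or before i
    offs <- c(a = 0, b = 1, c = 2, d = 3, e = 4, f = 5, g = 6)
    h <- 1 + (i - a1 - offs[[p]]) / 7
    tab[[p]][as.character(h)] <- res[i]
  }
  tab
}

oracle_encode <- function(coil_a, coil_b) {
  ta <- oracle_chain_table(coil_a$sequence[1], coil_a$register[1])
  tb <- oracle_chain_table(coil_b$sequence[1], coil_b$register[1])
  counts <- list()
  bump <- function(key) counts[[key]] <<- (counts[[key]] %||% 0L) + 1L
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (role in 1:2) {
    t1 <- if (role == 1) ta else tb
    t2 <- if (role == 1) tb else ta
    for (cat in names(ORACLE_CONTACTS)) {
      if (role == 2 && cat %in% ORACLE_SELFSYM) next
      for (h in -3:30) {
        rs <- character(0)
        ok <- TRUE
        for (slot in ORACLE_CONTACTS[[cat]]) {
          tt <- if (slot[2] == "1") t1 else t2
          r <- tt[[slot[1]]][as.character(h + as.numeric(slot[3]))]
          if (is.null(r) || is.na(r)) { ok <- FALSE; break }
          rs <- c(rs, unname(r))
        }
        if (!ok) next
        if (cat %in% ORACLE_SYMMETRIC) rs <- sort(rs)
        bump(paste0(cat, ":", paste(rs, collapse = "-")))
      }
    }
  }
  out <- tibble::tibble(key = names(counts),
                        count = as.integer(unlist(counts)))
  out[order(out$key), ]
}

# ---- random registered coils ----------------------------------------------

random_coil <- function(n_blocks = 2, id = "X", seed = NULL, phase = "f") {
  if (!is.null(seed)) set.seed(seed)
  len <- 7 * n_blocks + sample(0:4, 1)
  seqn <- paste(sample(AA, len, replace = TRUE), collapse = "")
  assign_register(seqn, phase = phase, id = id)
}

# ---- generic dense QP oracle (quadprog) ------------------------------------

# Solves the semi-quantitative SVR as an explicit QP over (w, slacks) with a
# tiny ridge on the slack block, then reports the exact objective of the
# recovered weight vector.
qp_oracle_objective <- function(X, y, censored, C1, C2, epsilon,
                                E_cutoff = log10(5000), ridge = 1e-8) {
  X <- as.matrix(X)
  p <- ncol(X); bi <- which(!censored); nb <- which(censored)
  m <- length(bi); n <- length(nb)
  nv <- p + m + n
  D <- diag(c(rep(2, p), rep(ridge, m + n)), nv)
  dvec <- -c(rep(0, p), rep(C1, m), rep(C2, n))
  rows <- list(); rhs <- c()
  ek <- function(i, block_off) { v <- rep(0, nv); v[p + block_off + i] <- 1; v }
  for (i in seq_len(m)) {
    k <- bi[i]
    rows[[length(rows) + 1]] <- c(-X[k, ], ek(i, 0)[-(1:p)]); rhs <- c(rhs, -y[k] - epsilon)
    rows[[length(rows) + 1]] <- c(X[k, ], ek(i, 0)[-(1:p)]); rhs <- c(rhs, y[k] - epsilon)
  }
  for (i in seq_len(n)) {
    k <- nb[i]
    rows[[length(rows) + 1]] <- c(X[k, ], ek(i, m)[-(1:p)]); rhs <- c(rhs, E_cutoff)
  }
  for (i in seq_len(m + n)) {
    v <- rep(0, nv); v[p + i] <- 1
    rows[[length(rows) + 1]] <- v; rhs <- c(rhs, 0)
  }
  Amat <- t(do.call(rbind, rows))
  sol <- quadprog::solve.QP(D, dvec, Amat, rhs)
  w <- sol$solution[1:p]
  E <- as.numeric(X %*% w)
  sum(w^2) +
    C1 * sum(pmax(0, abs(E[bi] - y[bi]) - epsilon)) +
    C2 * sum(pmax(0, E_cutoff - E[nb]))
}

# ---- brute-force AUC -------------------------------------------------------

auc_bruteforce <- function(scores, is_positive) {
  pos <- scores[is_positive]; neg <- scores[!is_positive]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a < b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# ---- exhaustive design enumeration ----------------------------------------

# Scores every assembly by assembling the sequence and calling the full
# encoder + predictor; applies constraints literally.
enumerate_designs <- function(model, target, library, M, off_targets = NULL,
                              mode = "relative", delta = 2, cutoff = NULL,
                              junction_allowed = NULL, constraints = NULL) {
  N <- nrow(library)
  grids <- rep(list(seq_len(N)), M)
  combos <- as.matrix(do.call(expand.grid, grids))
  best <- NULL
  P <- if (is.null(off_targets)) 0L else nrow(off_targets)
  for (r in seq_len(nrow(combos))) {
    pick <- combos[r, ]
    if (!is.null(constraints)) {
      if (!all(constraints$allowed[cbind(pick, seq_len(M))])) next
      if (sum(constraints$met_d[pick]) > constraints$met_d_max) next
      if (sum(constraints$polar_a[pick]) > constraints$polar_a_max) next
    }
    if (!is.null(junction_allowed) && M > 1) {
      ok <- all(vapply(seq_len(M - 1),
                       function(i) junction_allowed[pick[i], pick[i + 1]], logical(1)))
      if (!ok) next
    }
    seqn <- paste(library$heptad[pick], collapse = "")
    dc <- assign_register(seqn, phase = "f", id = "design")
    st <- score_pair(model, dc, target)
    feas <- TRUE
    if (P > 0) for (p in seq_len(P)) {
      so <- score_pair(model, dc, off_targets[p, ])
      req <- if (mode == "relative") st + delta else rep_len(cutoff, P)[p]
      if (so < req - 1e-9) { feas <- FALSE; break }
    }
    if (!feas) next
    if (is.null(best) || st < best$score - 1e-12) best <- list(score = st, pick = pick)
  }
  best
}

# ---- shared design-test builders ------------------------------------------

toy_library <- function(heptads) {
  tibble::tibble(heptad = heptads, sources = "toy",
                 n_terminal = rep(FALSE, length(heptads)))
}

# dense-ish random weight model over all contact categories
random_model <- function(seed, n = 150) {
  set.seed(seed)
  cats <- names(bzipspec:::CC_CATEGORIES)
  keys <- unique(unlist(lapply(cats, function(cat) {
    k <- if (nchar(cat) == 2) 2 else 3
    paste0(cat, ":", apply(matrix(sample(AA, n * k, TRUE), ncol = k), 1,
                           paste, collapse = "-"))
  })))
  # canonicalise symmetric pair keys so they can actually be hit
  sym <- sub(":.*", "", keys) %in% c("aa", "dd", "ge", "eg")
  parts <- strsplit(sub("^[a-z]+:", "", keys[sym]), "-")
  keys[sym] <- paste0(sub(":.*", "", keys[sym]), ":",
                      vapply(parts, function(p) paste(sort(p), collapse = "-"),
                             character(1)))
  cc_model(w = stats::setNames(rnorm(length(keys)), keys))
}
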