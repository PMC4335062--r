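#' @useDynLib bzipspec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom methods as
#' @import tibble
"_PACKAGE"

HEPTAD <- c("a", "b", "c", "d", "e", "f", "g")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Frequent-residue alphabets at core positions of bZIP leucine zippers.
## a and d form the hydrophobic core; e and g flank it and carry charge.
CORE_ALPHABETS <- list(
  a = c("L", "N", "V", "I", "K", "A", "R", "T"),
  d = c("L", "H", "V", "M", "I"),
  e = c("E", "K", "R", "Q", "L"),
  g = c("E", "K", "R", "Q", "L")
)

phase_to_int <- function(phase) {
  if (is.character(phase)) {
    stopifnot(length(phase) == 1L, phase %in% HEPTAD)
    return(match(phase, HEPTAD) - 1L)
  }
  phase <- as.integer(phase)
  stopifnot(length(phase) == 1L, phase >= 0L, phase <= 6L)
  phase
}

#' Assign a heptad register to a coiled-coil sequence
#'
#' Labels every residue with its heptad position (`a`-`g`), cycling from the
#' given phase, and identifies the complete 7-residue blocks in
#' `(f,g,a,b,c,d,e)` order that downstream encoding and design operate on.
#'
#' @param sequence Amino-acid sequence (single string, 20-letter alphabet).
#' @param phase Heptad position of the first residue: a letter in `a`-`g` or
#'   an integer 0-6 (0 = `a`).
#' @param id,species Optional identifier and species tag.
#' @return A one-row tibble with columns `id`, `species`, `sequence`,
#'   `register`, `n_blocks` and `unblocked` (residues outside complete
#'   f-anchored blocks, leading plus trailing).
#' @examples
#' assign_register(strrep("LEKKLQA", 2), phase = "f", id = "toy")
#' @export
assign_register <- function(sequence, phase = "f", id = NULL, species = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 7L) stop("sequence must have at least 7 residues, got ", n)
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), AA20)
  if (length(bad) > 0L)
    stop("non-standard residues in sequence: ", paste(bad, collapse = ", "))
  p <- phase_to_int(phase)
  register <- paste(HEPTAD[((p + seq_len(n) - 1L) %% 7L) + 1L], collapse = "")
  blocks <- coil_blocks_str(sequence, register)
  tibble(
    id = if (is.null(id)) NA_character_ else as.character(id),
    species = as.character(species),
    sequence = sequence,
    register = register,
    n_blocks = nrow(blocks),
    unblocked = n - 7L * nrow(blocks)
  )
}

#' Validate that a register string is a clean heptad cycle
#'
#' @param register String over `a`-`g`.
#' @return Invisibly `TRUE`; throws an error on a broken cycle.
#' @export
validate_register <- function(register) {
  lab <- strsplit(register, "")[[1]]
  li <- match(lab, HEPTAD)
  if (anyNA(li)) stop("register contains labels outside a-g")
  if (length(li) > 1L) {
    step <- diff(li) %% 7L
    if (any(step != 1L)) {
      at <- which(step != 1L)[1L]
      stop("register is not a clean heptad cycle at position ", at + 1L)
    }
  }
  invisible(TRUE)
}

## Complete 7-residue windows in (f,g,a,b,c,d,e) order, anchored at the first
## f-position residue. Block indices are 1-based to match field notation such
## as "4e" (= e position of block 4).
coil_blocks_str <- function(sequence, register) {
  validate_register(register)
  res <- strsplit(sequence, "")[[1]]
  lab <- strsplit(register, "")[[1]]
  n <- length(res)
  f1 <- which(lab == "f")[1]
  if (is.na(f1)) return(tibble(block = integer(), start = integer(), heptad = character()))
  starts <- seq(from = f1, to = n - 6L, by = 7L)
  if (length(starts) == 0L || starts[1] > n - 6L)
    return(tibble(block = integer(), start = integer(), heptad = character()))
  tibble(
    block = seq_along(starts),
    start = as.integer(starts),
    heptad = vapply(starts, function(s) paste(res[s:(s + 6L)], collapse = ""), character(1))
  )
}

#' List the complete f-anchored heptad blocks of registered coils
#'
#' @param coils Tibble of registered coils (columns `id`, `sequence`,
#'   `register`), e.g. from [assign_register()] or [simulate_coils()].
#' @return Tibble with columns `id`, `block` (1-based), `start` (1-based
#'   residue index) and `heptad` (7-mer in `(f,g,a,b,c,d,e)` order).
#' @export
coil_blocks <- function(coils) {
  purrr::map_dfr(seq_len(nrow(coils)), function(i) {
    b <- coil_blocks_str(coils$sequence[i], coils$register[i])
    if (nrow(b) == 0L) return(b)
    dplyr::mutate(b, id = coils$id[i], .before = 1L)
  })
}

## Heptad matrix in the canonical a..g frame, anchored on the first complete
## f-anchored block: heptad 1 holds the a-e residues of block 1; the f,g
## residues of block k belong to heptad k-1. Rows are heptad indices
## (possibly starting at 0 or negative for leading partial heptads), columns
## are positions a-g; missing slots are NA.
heptad_matrix <- function(sequence, register) {
  validate_register(register)
  res <- strsplit(sequence, "")[[1]]
  lab <- strsplit(register, "")[[1]]
  li <- match(lab, HEPTAD) - 1L # a=0 .. g=6
  n <- length(res)
  f1 <- which(lab == "f")[1]
  if (is.na(f1) || f1 > n - 6L) stop("coil has no complete f-anchored block")
  ia <- f1 + 2L                          # the a of block 1 -> heptad 1
  h <- 1L + (seq_len(n) - ia - li) %/% 7L
  hr <- range(h)
  m <- matrix(NA_character_, nrow = hr[2] - hr[1] + 1L, ncol = 7L,
              dimnames = list(as.character(hr[1]:hr[2]), HEPTAD))
  m[cbind(h - hr[1] + 1L, li + 1L)] <- res
  m
}

## Residue at (heptad h, position pos) or NA.
hm_at <- function(m, h, pos) {
  h0 <- as.integer(rownames(m)[1])
  i <- h - h0 + 1L
  out <- rep(NA_character_, length(h))
  ok <- i >= 1L & i <= nrow(m)
  mcol <- rep_len(match(pos, HEPTAD), length(h))
  out[ok] <- m[cbind(i[ok], mcol[ok])]
  out
}

## Core-position (a,d,e,g) residue string used for identity computations.
core_residues <- function(sequence, register) {
  res <- strsplit(sequence, "")[[1]]
  lab <- strsplit(register, "")[[1]]
  res[lab %in% c("a", "d", "e", "g")]
}
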