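#' Assemble a coiled-coil interaction dataset
#'
#' Bundles registered coils with dimer affinity records, normalising each
#' record to an unordered pair, collapsing duplicate pairs to the minimum
#' K_d (reciprocal measurements of the same dimer keep the lower value), and
#' right-censoring K_d at the ceiling. Affinities are carried as log10(K_d)
#' in nM units throughout.
#'
#' @param coils Tibble of registered coils (columns `id`, `sequence`,
#'   `register`; optional `species`, `parent`).
#' @param records Tibble with columns `idA`, `idB`, `kd_nM`.
#' @param ceiling Censoring ceiling in nM (default 5000): records at or above
#'   it are non-binders with `kd_nM` set to the ceiling.
#' @return A `cc_dataset`: list with `coils`, `records` (adds `log10_kd`,
#'   `is_binder`, `is_censored`) and `ceiling`.
#' @export
as_cc_dataset <- function(coils, records, ceiling = 5000) {
  stopifnot(all(c("id", "sequence", "register") %in% names(coils)),
            all(c("idA", "idB", "kd_nM") %in% names(records)),
            ceiling > 0)
  if (anyDuplicated(coils$id)) stop("duplicate coil ids")
  if (!"species" %in% names(coils)) coils$species <- NA_character_
  missing <- setdiff(unique(c(records$idA, records$idB)), coils$id)
  if (length(missing) > 0L)
    stop("no sequence for referenced id(s): ", paste(missing, collapse = ", "))
  if (any(records$kd_nM <= 0)) stop("non-positive K_d in records")
  for (i in seq_len(nrow(coils))) validate_register(coils$register[i])
  swap <- records$idA > records$idB
  tmp <- records$idA[swap]
  records$idA[swap] <- records$idB[swap]
  records$idB[swap] <- tmp
  records <- records |>
    dplyr::group_by(.data$idA, .data$idB) |>
    dplyr::summarise(kd_nM = min(.data$kd_nM), .groups = "drop") |>
    dplyr::mutate(
      kd_nM = pmin(.data$kd_nM, ceiling),
      log10_kd = log10(.data$kd_nM),
      is_binder = .data$kd_nM < ceiling,
      is_censored = !.data$is_binder
    )
  structure(list(coils = coils, records = records, ceiling = ceiling),
            class = "cc_dataset")
}

#' @exportS3Method base::print
print.cc_dataset <- function(x, ...) {
  cat("<cc_dataset> ", nrow(x$records), " interactions among ",
      nrow(x$coils), " coils; ", sum(x$records$is_binder), " binders (K_d < ",
      x$ceiling, " nM)\n", sep = "")
  invisible(x)
}

#' Read an interaction dataset from CSV + FASTA + register annotation
#'
#' @param interactions_path CSV of dimer measurements; columns named by
#'   `columns`.
#' @param sequences_path FASTA of coil sequences; ids must match the CSV.
#' @param register_spec Either a single phase (letter `a`-`g` or integer 0-6)
#'   applied to every sequence, or the path of a sidecar TSV with columns
#'   `id`, `phase` and optionally `species`.
#' @param columns Named character vector mapping the roles `idA`, `idB`,
#'   `kd` to CSV column names (the deposited-data column layout varies).
#' @param ceiling Censoring ceiling in nM.
#' @return A `cc_dataset`.
#' @export
read_dataset <- function(interactions_path, sequences_path, register_spec = "f",
                         columns = c(idA = "idA", idB = "idB", kd = "kd_nM"),
                         ceiling = 5000) {
  raw <- readr::read_csv(interactions_path, show_col_types = FALSE)
  miss <- setdiff(unname(columns), names(raw))
  if (length(miss) > 0L)
    stop("interaction CSV lacks column(s): ", paste(miss, collapse = ", "))
  records <- tibble(idA = as.character(raw[[columns[["idA"]]]]),
                    idB = as.character(raw[[columns[["idB"]]]]),
                    kd_nM = as.numeric(raw[[columns[["kd"]]]]))
  seqs <- Biostrings::readAAStringSet(sequences_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.character(register_spec) && file.exists(register_spec)) {
    reg <- readr::read_tsv(register_spec, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    phase_of <- stats::setNames(as.character(reg$phase), reg$id)
    species_of <- if ("species" %in% names(reg))
      stats::setNames(as.character(reg$species), reg$id)
    else stats::setNames(rep(NA_character_, nrow(reg)), reg$id)
    miss <- setdiff(ids, names(phase_of))
    if (length(miss) > 0L)
      stop("register TSV lacks phase for: ", paste(miss, collapse = ", "))
  } else {
    phase_of <- stats::setNames(rep(as.character(register_spec), length(ids)), ids)
    species_of <- stats::setNames(rep(NA_character_, length(ids)), ids)
  }
  coils <- purrr::map_dfr(seq_along(ids), function(i) {
    ph <- phase_of[[ids[i]]]
    ph <- if (grepl("^[0-6]$", ph)) as.integer(ph) else ph
    assign_register(as.character(seqs[[i]]), phase = ph, id = ids[i],
                    species = species_of[[ids[i]]])
  })
  as_cc_dataset(coils, records, ceiling = ceiling)
}

#' Write a dataset back to its on-disk dialect
#'
#' Writes the interactions CSV, sequences FASTA and register sidecar TSV that
#' [read_dataset()] reads.
#'
#' @param dataset A `cc_dataset`.
#' @param interactions_path,sequences_path,registers_path Output paths.
#' @return Invisibly, the dataset.
#' @export
write_dataset <- function(dataset, interactions_path, sequences_path, registers_path) {
  readr::write_csv(dataset$records[, c("idA", "idB", "kd_nM")], interactions_path)
  seqs <- Biostrings::AAStringSet(stats::setNames(dataset$coils$sequence, dataset$coils$id))
  Biostrings::writeXStringSet(seqs, sequences_path)
  readr::write_tsv(
    tibble(id = dataset$coils$id,
           phase = substr(dataset$coils$register, 1L, 1L),
           species = dataset$coils$species),
    registers_path
  )
  invisible(dataset)
}

#' Construct a scoring model object
#'
#' @param w Named numeric vector of feature weights (names are feature keys
#'   such as `"aa:N-N"`).
#' @param C1,C2 Slack penalties used to fit the model (binders/non-binders).
#' @param epsilon Epsilon-insensitivity of the binder constraints.
#' @param E_cutoff Non-binder score floor on the log10 nM scale.
#' @param intercept Constant offset added to every score (default 0).
#' @param categories Feature categories the model was trained over.
#' @param roles Chain-role counting convention used by the encoder.
#' @return A `cc_model` object; `predict()` gives `intercept + sum(w * x)`.
#' @export
cc_model <- function(w = stats::setNames(numeric(0), character(0)),
                     C1 = 1, C2 = 1, epsilon = 0.1,
                     E_cutoff = log10(5000), intercept = 0,
                     categories = names(CC_CATEGORIES), roles = "both") {
  w <- stats::setNames(as.double(w), names(w))
  ## generic (un-categorised) keys are allowed; "cat:RES" keys must use a
  ## known category token
  keyed <- grepl(":", names(w), fixed = TRUE)
  bad <- setdiff(unique(key_category(names(w)[keyed])), names(CC_CATEGORIES))
  if (length(bad) > 0L)
    stop("unknown feature-category token(s): ", paste(bad, collapse = ", "))
  if (anyNA(match(categories, names(CC_CATEGORIES))))
    stop("unknown feature category in `categories`")
  structure(list(w = w, C1 = C1, C2 = C2, epsilon = epsilon,
                 E_cutoff = E_cutoff, intercept = intercept,
                 categories = categories, roles = roles),
            class = "cc_model")
}

#' @exportS3Method base::print
print.cc_model <- function(x, ...) {
  cat("<cc_model> ", length(x$w), " feature weights; C1=", x$C1, " C2=", x$C2,
      " epsilon=", x$epsilon, " E_cutoff=", signif(x$E_cutoff, 4),
      " intercept=", signif(x$intercept, 4), "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a scoring model as JSON
#'
#' Full double precision is preserved so `read_model(write_model(m))` is
#' bit-exact.
#'
#' @param model A `cc_model`.
#' @param path JSON file path.
#' @return `write_model` returns the path invisibly; `read_model` a
#'   `cc_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cc_model"))
  obj <- list(
    keys = names(model$w), weights = unname(model$w),
    C1 = model$C1, C2 = model$C2, epsilon = model$epsilon,
    E_cutoff = model$E_cutoff, intercept = model$intercept,
    categories = model$categories, roles = model$roles
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- as.character(obj$keys %||% character(0))
  cc_model(w = stats::setNames(as.double(obj$weights %||% numeric(0)), keys),
           C1 = obj$C1, C2 = obj$C2, epsilon = obj$epsilon,
           E_cutoff = obj$E_cutoff, intercept = obj$intercept %||% 0,
           categories = as.character(obj$categories),
           roles = obj$roles %||% "both")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
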