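#' Canonical structure handling
#'
#' Canonicalization, InChIKeys, formulas and monoisotopic masses are
#' computed with OpenBabel: the `obabel` executable (batched, stereo-aware)
#' produces canonical SMILES, InChIKey and Hill-order formula; monoisotopic
#' masses come from [ChemmineOB::exactMass_OB()]. Results are memoised per
#' session so repeated canonicalization of the same string costs nothing.
#'
#' @name structures
NULL

.ob_cache <- new.env(parent = emptyenv())

inchikey_regex <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

#' Check InChIKey syntax
#' @param x character vector.
#' @return logical vector; `NA` inputs give `FALSE`.
#' @export
is_inchikey <- function(x) !is.na(x) & grepl(inchikey_regex, x)

ob_binary <- function() {
  path <- Sys.which("obabel")
  if (!nzchar(path)) {
    stop_tpc("OpenBabel executable 'obabel' not found on PATH", "tpc_environment_error")
  }
  path
}

# One obabel invocation over all uncached SMILES. Molecules are titled by
# index so invalid inputs (dropped by -e) are detectable by absence.
ob_convert_raw <- function(smiles) {
  out <- tibble::tibble(
    query = smiles, smiles = NA_character_, inchikey = NA_character_,
    formula = NA_character_, valid = FALSE
  )
  if (length(smiles) == 0) return(out)
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles, paste0("i", seq_along(smiles))), infile)
  res <- suppressWarnings(system2(
    ob_binary(), c(shQuote(infile), "-ismi", "-ocan", "-e",
                   "--append", shQuote("InChIKey formula")),
    stdout = TRUE, stderr = FALSE
  ))
  res <- res[nzchar(res)]
  for (line in res) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) next
    fields <- strsplit(trimws(parts[2]), " +")[[1]]
    if (length(fields) < 3) next
    idx <- suppressWarnings(as.integer(sub("^i", "", fields[1])))
    if (is.na(idx)) next
    out$smiles[idx] <- parts[1]
    out$inchikey[idx] <- fields[2]
    out$formula[idx] <- fields[3]
    out$valid[idx] <- is_inchikey(fields[2])
  }
  # monoisotopic mass for everything that parsed
  out$monoisotopic_mass <- NA_real_
  ok <- which(out$valid)
  if (length(ok) > 0) {
    mols <- ChemmineOB::forEachMol("SMILES",
                                   paste(out$smiles[ok], collapse = "\n"),
                                   identity)
    masses <- unlist(ChemmineOB::exactMass_OB(mols))
    if (length(masses) == length(ok)) out$monoisotopic_mass[ok] <- masses
  }
  out[c("query", "smiles", "inchikey", "formula", "monoisotopic_mass", "valid")]
}

ob_convert <- function(smiles) {
  smiles <- as.character(smiles)
  keys <- smiles
  miss <- unique(keys[!is.na(keys) & nzchar(keys) &
                        !vapply(keys, exists, logical(1), envir = .ob_cache)])
  if (length(miss) > 0) {
    fresh <- ob_convert_raw(miss)
    for (i in seq_len(nrow(fresh))) {
      assign(fresh$query[i], fresh[i, ], envir = .ob_cache)
    }
  }
  rows <- lapply(keys, function(k) {
    if (is.na(k) || !nzchar(k)) {
      tibble::tibble(query = k, smiles = NA_character_, inchikey = NA_character_,
                     formula = NA_character_, monoisotopic_mass = NA_real_,
                     valid = FALSE)
    } else {
      get(k, envir = .ob_cache)
    }
  })
  dplyr::bind_rows(rows)
}

#' Canonicalize SMILES and compute structure descriptors
#'
#' @param smiles_in character vector of SMILES strings.
#' @param xlogp optional numeric vector of externally supplied XlogP values
#'   (e.g. from PubChem); recycled `NA` when absent. This function never
#'   computes logP silently — see [estimate_logp()] for the labeled fallback.
#' @return a tibble with one row per input: `query`, `smiles` (canonical),
#'   `inchikey`, `formula`, `monoisotopic_mass`, `xlogp`.
#'   Canonicalization is idempotent: re-canonicalizing the `smiles` column
#'   reproduces it.
#' @examples
#' \dontrun{
#' canonicalize(c("C1=CC=CC=C1", "c1ccccc1"))  # same canonical form twice
#' }
#' @export
canonicalize <- function(smiles_in, xlogp = NULL) {
  if (length(smiles_in) == 0) {
    return(tibble::tibble(query = character(), smiles = character(),
                          inchikey = character(), formula = character(),
                          monoisotopic_mass = numeric(), xlogp = numeric()))
  }
  if (any(is.na(smiles_in) | !nzchar(smiles_in))) {
    stop_tpc("canonicalize: empty or missing SMILES input", "tpc_structure_error")
  }
  res <- ob_convert(smiles_in)
  if (any(!res$valid)) {
    bad <- unique(res$query[!res$valid])
    stop_tpc(
      paste0("unparseable SMILES: ", paste(utils::head(bad, 5), collapse = ", ")),
      "tpc_structure_error", offending = bad
    )
  }
  res$xlogp <- if (is.null(xlogp)) NA_real_ else as.numeric(xlogp)
  res[c("query", "smiles", "inchikey", "formula", "monoisotopic_mass", "xlogp")]
}

# heavy-atom count from a Hill formula, H excluded
heavy_atoms_from_formula <- function(formula) {
  vapply(formula, function(f) {
    toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    total <- 0L
    for (t in toks) {
      el <- gsub("[0-9]", "", t)
      n <- suppressWarnings(as.integer(gsub("[^0-9]", "", t)))
      if (is.na(n)) n <- 1L
      if (el != "H") total <- total + n
    }
    total
  }, integer(1), USE.NAMES = FALSE)
}

contains_carbon <- function(formula) {
  grepl("C(?![a-z])", formula, perl = TRUE)
}

#' Strip salt/counterion components from a structure
#'
#' Keeps the largest organic component of a multi-component structure:
#' most heavy atoms among carbon-containing components, ties broken by
#' larger monoisotopic mass, then by lexicographically smallest canonical
#' SMILES. Single-component inputs pass through unchanged.
#'
#' @param smiles a single SMILES string.
#' @return list with `structure` (one-row tibble as from [canonicalize()])
#'   and `stripped` (`TRUE` iff components were removed).
#' @export
strip_salt <- function(smiles) {
  stopifnot(length(smiles) == 1)
  ref <- canonicalize(smiles)
  comps <- strsplit(ref$smiles, ".", fixed = TRUE)[[1]]
  if (length(comps) <= 1) {
    return(list(structure = ref, stripped = FALSE))
  }
  cref <- canonicalize(comps)
  organic <- contains_carbon(cref$formula)
  if (!any(organic)) {
    stop_tpc("strip_salt: no organic component to keep in multi-component structure",
             "tpc_structure_error", offending = smiles)
  }
  cand <- cref[organic, ]
  cand$heavy <- heavy_atoms_from_formula(cand$formula)
  ord <- order(-cand$heavy, -cand$monoisotopic_mass, cand$smiles)
  # counterion loss leaves a bare ion; report the neutral (free-base/acid) form
  keep <- canonicalize(neutralize_smiles(cand$smiles[ord[1]]))
  list(structure = keep, stripped = TRUE)
}

# protonation-state cleanup after counterion removal (OpenBabel --neutralize)
neutralize_smiles <- function(smiles) {
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(smiles, infile)
  out <- suppressWarnings(system2(
    ob_binary(), c(shQuote(infile), "-ismi", "-ocan", "-e", "--neutralize"),
    stdout = TRUE, stderr = FALSE
  ))
  out <- trimws(out[nzchar(trimws(out))])
  if (length(out) != length(smiles)) {
    stop_tpc("neutralization failed", "tpc_structure_error", offending = smiles)
  }
  out
}

#' Compare two structures at a chosen strictness level
#'
#' `exact` compares full InChIKeys; `skeleton` compares the first
#' 14-character block (stereo- and isotope-agnostic connectivity);
#' `desalted` compares full InChIKeys after [strip_salt()] on both sides.
#' `exact` implies `skeleton`.
#'
#' @param a,b SMILES strings (any notation; canonicalized internally).
#' @param level one of `"exact"`, `"skeleton"`, `"desalted"`.
#' @return logical scalar.
#' @export
structures_match <- function(a, b, level = c("exact", "skeleton", "desalted")) {
  level <- match.arg(level)
  if (level == "desalted") {
    ka <- strip_salt(a)$structure$inchikey
    kb <- strip_salt(b)$structure$inchikey
    return(ka == kb)
  }
  keys <- canonicalize(c(a, b))$inchikey
  if (level == "exact") keys[1] == keys[2]
  else substr(keys[1], 1, 14) == substr(keys[2], 1, 14)
}

#' Labeled logP fallback estimate
#'
#' OpenBabel's atom-contribution logP model. This is an explicit estimate,
#' reported under its own name; it is never substituted for an XlogP value
#' supplied in input tables.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector of estimated logP values.
#' @export
estimate_logp <- function(smiles) {
  if (length(smiles) == 0) return(numeric())
  ref <- canonicalize(smiles)
  mols <- ChemmineOB::forEachMol("SMILES", paste(ref$smiles, collapse = "\n"),
                                 identity)
  props <- ChemmineOB::prop_OB(mols)
  as.numeric(props$logP)
}

structure_index_cols <- c("cid", "smiles", "inchikey", "formula",
                          "monoisotopic_mass", "xlogp")

#' Read / write a CID-to-structure index
#'
#' The index is a CSV mapping `cid` to `smiles`, `inchikey`, `formula`,
#' `monoisotopic_mass`, `xlogp`; it is the local stand-in for structure
#' lookups that would otherwise hit a web service.
#'
#' @param file path to a CSV file.
#' @return a tibble with the columns above.
#' @export
read_structure_index <- function(file) {
  idx <- readr::read_csv(file, col_types = readr::cols(
    cid = readr::col_double(), smiles = readr::col_character(),
    inchikey = readr::col_character(), formula = readr::col_character(),
    monoisotopic_mass = readr::col_double(), xlogp = readr::col_double()
  ), na = "")
  check_schema(names(idx), structure_index_cols, "structure index")
  idx
}

#' @rdname read_structure_index
#' @param index a structure-index tibble.
#' @export
write_structure_index <- function(index, file) {
  check_schema(names(index), structure_index_cols, "structure index")
  readr::write_csv(index[structure_index_cols], file, na = "")
  invisible(file)
}

check_schema <- function(have, want, what) {
  missing <- setdiff(want, have)
  unknown <- setdiff(have, want)
  if (length(missing) > 0 || length(unknown) > 0) {
    stop_tpc(paste0(
      what, " schema mismatch",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(unknown)) paste0("; unknown: ", paste(unknown, collapse = ", "))
    ), "tpc_schema_error")
  }
  invisible(TRUE)
}

#' Build a structure index from SMILES
#'
#' Canonicalizes each structure and fills in descriptors; `xlogp` is taken
#' from the supplied values or left `NA`.
#'
#' @param cid numeric vector of compound identifiers.
#' @param smiles character vector of SMILES, same length.
#' @param xlogp optional numeric vector of partition-coefficient values.
#' @return a structure-index tibble.
#' @export
build_structure_index <- function(cid, smiles, xlogp = NULL) {
  ref <- canonicalize(smiles, xlogp = xlogp)
  tibble::tibble(cid = as.numeric(cid), smiles = ref$smiles,
                 inchikey = ref$inchikey, formula = ref$formula,
                 monoisotopic_mass = ref$monoisotopic_mass, xlogp = ref$xlogp)
}
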