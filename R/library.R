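#' Transformations-library operations
#'
#' A transformations library is a multiset of directed reaction records;
#' uniqueness is reckoned on the (predecessor CID, successor CID) pair,
#' falling back to the InChIKey pair when either CID is absent. Duplicate
#' pairs with different metadata (biosystem/enzyme/transformation type)
#' are legitimate and retained — that is what a metadata variant is.
#'
#' @name library_ops
NULL

#' Construct a transformations library
#' @param entries reactions tibble (library schema, see [read_reactions()]).
#' @param version non-empty version tag.
#' @return object of class `tp_library`.
#' @export
tp_library <- function(entries = empty_reactions(), version = "0.1") {
  check_schema(names(entries), reaction_cols, "library entries")
  stopifnot(nzchar(version))
  structure(list(entries = tibble::as_tibble(entries), version = version),
            class = "tp_library")
}

#' @export
print.tp_library <- function(x, ...) {
  cat("<tp_library> version", x$version, "—", nrow(x$entries), "entries,",
      count_unique_by_cid(x), "unique reaction pairs\n")
  invisible(x)
}

#' Read / write a transformations library CSV
#'
#' Columns: `predecessor_name`, `predecessor_cid`, `predecessor_smiles`,
#' `successor_name`, `successor_cid`, `successor_smiles`, `biosystem`,
#' `enzyme`, `transformation_type`, `evidence`, `source_name`,
#' `source_id`, `reaction_smiles`. Duplicate pair rows are retained
#' (multiset semantics).
#'
#' @param file path to CSV.
#' @param version version tag to stamp on the library read.
#' @return a `tp_library`.
#' @export
read_library <- function(file, version = "0.1") {
  tp_library(read_reactions(file), version = version)
}

#' @rdname read_library
#' @param lib a `tp_library`.
#' @export
write_library <- function(lib, file) {
  stopifnot(inherits(lib, "tp_library"))
  write_reactions(lib$entries, file)
}

# pair identity keys: CID pair when both sides have one, InChIKey pair
# otherwise (InChIKeys computed from the stored structures, memoised)
pair_keys <- function(entries, by = c("auto", "inchikey")) {
  by <- match.arg(by)
  if (nrow(entries) == 0) return(character())
  ik_pred <- canonicalize(entries$predecessor_smiles)$inchikey
  ik_succ <- canonicalize(entries$successor_smiles)$inchikey
  ik_key <- paste0("ik:", ik_pred, ">", ik_succ)
  if (by == "inchikey") return(ik_key)
  has_cid <- !is.na(entries$predecessor_cid) & !is.na(entries$successor_cid)
  ifelse(has_cid,
         paste0("cid:", entries$predecessor_cid, ">", entries$successor_cid),
         ik_key)
}

#' Number of unique reactions by CID pair
#'
#' Distinct (predecessor CID, successor CID) pairs; entries lacking a CID
#' on either side are counted by their InChIKey pair instead.
#'
#' @param lib a `tp_library`.
#' @return integer count.
#' @export
count_unique_by_cid <- function(lib) {
  stopifnot(inherits(lib, "tp_library"))
  length(unique(pair_keys(lib$entries)))
}

#' Classify curated reactions against an existing library
#'
#' Each incoming reaction is matched on its structure pair (CID-pair
#' shortcut when both CIDs are present on both sides, InChIKey pair as
#' the general route). A structure-pair match with identical normalized
#' metadata (biosystem, enzyme, transformation type; case and surrounding
#' whitespace ignored) is an `exact_duplicate`; a structure-pair match
#' with differing metadata is a `metadata_variant`; no match is `novel`.
#' Differences confined to the evidence text count as exact duplicates.
#' The three classes partition the input.
#'
#' @param new_reactions reactions tibble.
#' @param lib a `tp_library`.
#' @return object of class `tp_dedup_report`: list with tibbles `novel`,
#'   `exact_duplicate`, `metadata_variant` and integer vector `counts`.
#' @export
dedup_classify <- function(new_reactions, lib) {
  stopifnot(inherits(lib, "tp_library"))
  n <- nrow(new_reactions)
  if (n == 0) {
    return(new_dedup_report(new_reactions[0, ], new_reactions[0, ], new_reactions[0, ]))
  }
  lib_e <- lib$entries
  new_cid <- pair_cid_keys(new_reactions)
  new_ik <- pair_keys(new_reactions, by = "inchikey")
  lib_cid <- pair_cid_keys(lib_e)
  lib_ik <- if (nrow(lib_e)) pair_keys(lib_e, by = "inchikey") else character()
  meta_key <- function(e) paste(norm_meta(e$biosystem), norm_meta(e$enzyme),
                                norm_meta(e$transformation_type), sep = "\x1f")
  new_meta <- meta_key(new_reactions)
  lib_meta <- if (nrow(lib_e)) meta_key(lib_e) else character()

  class <- character(n)
  for (i in seq_len(n)) {
    hit <- (!is.na(new_cid[i]) & !is.na(lib_cid) & lib_cid == new_cid[i]) |
      lib_ik == new_ik[i]
    hit[is.na(hit)] <- FALSE
    class[i] <- if (!any(hit)) "novel"
      else if (any(lib_meta[hit] == new_meta[i])) "exact_duplicate"
      else "metadata_variant"
  }
  new_dedup_report(new_reactions[class == "novel", ],
                   new_reactions[class == "exact_duplicate", ],
                   new_reactions[class == "metadata_variant", ])
}

pair_cid_keys <- function(entries) {
  if (nrow(entries) == 0) return(character())
  ifelse(!is.na(entries$predecessor_cid) & !is.na(entries$successor_cid),
         paste0("cid:", entries$predecessor_cid, ">", entries$successor_cid),
         NA_character_)
}

new_dedup_report <- function(novel, exact, variant) {
  structure(list(
    novel = novel, exact_duplicate = exact, metadata_variant = variant,
    counts = c(novel = nrow(novel), exact_duplicate = nrow(exact),
               metadata_variant = nrow(variant))
  ), class = "tp_dedup_report")
}

#' @export
print.tp_dedup_report <- function(x, ...) {
  cat("<tp_dedup_report>", sum(x$counts), "reactions:",
      x$counts[["novel"]], "novel,",
      x$counts[["exact_duplicate"]], "exact duplicates,",
      x$counts[["metadata_variant"]], "metadata variants\n")
  invisible(x)
}

#' Merge curated reactions into a library
#'
#' Appends reactions according to the dedup classification: `novel_only`
#' adds only novel reactions; `novel_plus_variants` also adds metadata
#' variants. Exact duplicates are never added, so merging the same set
#' twice is a no-op the second time.
#'
#' @param lib a `tp_library`.
#' @param new_reactions reactions tibble.
#' @param policy `"novel_only"` or `"novel_plus_variants"`.
#' @return the merged `tp_library`; the number of skipped reactions is
#'   reported via a message.
#' @export
merge_reactions <- function(lib, new_reactions,
                            policy = c("novel_only", "novel_plus_variants")) {
  policy <- match.arg(policy)
  rep <- dedup_classify(new_reactions, lib)
  add <- rep$novel
  if (policy == "novel_plus_variants") {
    add <- dplyr::bind_rows(add, rep$metadata_variant)
  }
  skipped <- nrow(new_reactions) - nrow(add)
  if (skipped > 0) {
    rlang::inform(paste0("merge_reactions: skipped ", skipped,
                         " reaction(s) under policy '", policy, "'"))
  }
  tp_library(dplyr::bind_rows(lib$entries, add), version = lib$version)
}

suspect_cols <- c("name", "smiles", "inchikey", "formula",
                  "monoisotopic_mass", "predecessor_inchikeys")

#' Export a suspect list from a library
#'
#' One entry per distinct successor structure (unique InChIKey), with the
#' monoisotopic mass and formula recomputed from the structure — suspect
#' screening depends on mass accuracy, so stored values are not trusted.
#' Predecessor InChIKeys are collected (sorted, semicolon-joined) across
#' every reaction producing the suspect; entries are sorted by InChIKey
#' for byte-stable output.
#'
#' @param lib a `tp_library`.
#' @return tibble with `name`, `smiles`, `inchikey`, `formula`,
#'   `monoisotopic_mass`, `predecessor_inchikeys`.
#' @export
export_suspect_list <- function(lib) {
  stopifnot(inherits(lib, "tp_library"))
  e <- lib$entries
  if (nrow(e) == 0) {
    return(tibble::tibble(name = character(), smiles = character(),
                          inchikey = character(), formula = character(),
                          monoisotopic_mass = numeric(),
                          predecessor_inchikeys = character()))
  }
  succ <- canonicalize(e$successor_smiles)
  pred <- canonicalize(e$predecessor_smiles)
  tab <- tibble::tibble(
    inchikey = succ$inchikey, smiles = succ$smiles, formula = succ$formula,
    monoisotopic_mass = succ$monoisotopic_mass,
    name = e$successor_name, pred_ik = pred$inchikey
  )
  out <- tab %>%
    dplyr::group_by(.data$inchikey) %>%
    dplyr::summarise(
      name = sort(.data$name)[1],
      smiles = .data$smiles[1],
      formula = .data$formula[1],
      monoisotopic_mass = .data$monoisotopic_mass[1],
      predecessor_inchikeys = paste(sort(unique(.data$pred_ik)), collapse = ";"),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$inchikey)
  out[suspect_cols]
}

suspect_csv_header <- c(Name = "name", SMILES = "smiles", InChIKey = "inchikey",
                        Molecular_Formula = "formula",
                        Monoisotopic_Mass = "monoisotopic_mass",
                        Predecessor_InChIKeys = "predecessor_inchikeys")

#' Read / write a suspect list CSV (NORMAN-SLE-style columns)
#'
#' Columns `Name`, `SMILES`, `InChIKey`, `Molecular_Formula`,
#' `Monoisotopic_Mass`, `Predecessor_InChIKeys` (semicolon-joined).
#'
#' @param file path to CSV.
#' @return suspect tibble as from [export_suspect_list()].
#' @export
read_suspect_list <- function(file) {
  d <- readr::read_csv(file, col_types = readr::cols(
    Monoisotopic_Mass = readr::col_double(), .default = readr::col_character()
  ), na = "")
  check_schema(names(d), names(suspect_csv_header), "suspect list")
  names(d) <- suspect_csv_header[names(d)]
  d[suspect_cols]
}

#' @rdname read_suspect_list
#' @param suspects suspect tibble.
#' @export
write_suspect_list <- function(suspects, file) {
  check_schema(names(suspects), suspect_cols, "suspect list")
  out <- suspects[suspect_cols]
  names(out) <- names(suspect_csv_header)
  readr::write_csv(out, file, na = "")
  invisible(file)
}
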