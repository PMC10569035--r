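#' Curation: decisions to directed reaction records
#'
#' A curator verdict binds a candidate span to a reaction direction:
#' `product` means the matched compound is a transformation product of the
#' input compound (input -> matched), `parent` means the matched compound
#' is the precursor (matched -> input), and `reject` discards the span.
#' Decisions are a declarative CSV artifact so a curation run is
#' reproducible and diffable.
#'
#' @name curation
NULL

reaction_cols <- c("predecessor_name", "predecessor_cid", "predecessor_smiles",
                   "successor_name", "successor_cid", "successor_smiles",
                   "biosystem", "enzyme", "transformation_type", "evidence",
                   "source_name", "source_id", "reaction_smiles")

empty_reactions <- function() {
  tibble::tibble(
    predecessor_name = character(), predecessor_cid = numeric(),
    predecessor_smiles = character(), successor_name = character(),
    successor_cid = numeric(), successor_smiles = character(),
    biosystem = character(), enzyme = character(),
    transformation_type = character(), evidence = character(),
    source_name = character(), source_id = character(),
    reaction_smiles = character()
  )
}

decision_cols <- c("candidate_id", "verdict", "biosystem", "enzyme",
                   "transformation_type", "note")

#' Read / write a curation-decisions CSV
#' @param file path to CSV with columns `candidate_id`, `verdict`,
#'   `biosystem`, `enzyme`, `transformation_type`, `note`.
#' @return decisions tibble.
#' @export
read_decisions <- function(file) {
  d <- readr::read_csv(file, col_types = readr::cols(.default = readr::col_character()),
                       na = "")
  check_schema(names(d), decision_cols, "decisions table")
  d[decision_cols]
}

#' @rdname read_decisions
#' @param decisions decisions tibble.
#' @export
write_decisions <- function(decisions, file) {
  check_schema(names(decisions), decision_cols, "decisions table")
  readr::write_csv(decisions[decision_cols], file, na = "")
  invisible(file)
}

#' Apply curator decisions to a candidate table
#'
#' Produces one directed reaction per accepted candidate and a rejection
#' ledger covering everything else: rejected candidates and candidates
#' with no decision (`undecided`). Undecided candidates are never silently
#' dropped. If the same candidate appears in several decisions, the last
#' one in file order wins and a warning is raised.
#'
#' Both structures of an accepted reaction are canonicalized and the
#' reaction SMILES is generated from the stored canonical forms.
#'
#' @param candidates tibble from [flatten_candidates()].
#' @param decisions tibble from [read_decisions()].
#' @return list with `reactions` (tibble, library schema) and `ledger`
#'   (tibble with `candidate_id`, `status` in `rejected`/`undecided`,
#'   `note`). `nrow(reactions) + nrow(ledger) == nrow(candidates)`.
#' @export
apply_decisions <- function(candidates, decisions) {
  unknown <- setdiff(decisions$candidate_id, candidates$candidate_id)
  if (length(unknown) > 0) {
    stop_tpc(paste0("decisions reference unknown candidate ids: ",
                    paste(utils::head(unknown, 5), collapse = ", ")),
             "tpc_validation_error")
  }
  bad_verdict <- setdiff(unique(decisions$verdict), c("product", "parent", "reject"))
  if (length(bad_verdict) > 0) {
    stop_tpc(paste0("unknown verdicts: ", paste(bad_verdict, collapse = ", ")),
             "tpc_validation_error")
  }
  if (anyDuplicated(decisions$candidate_id)) {
    dup <- unique(decisions$candidate_id[duplicated(decisions$candidate_id)])
    rlang::warn(paste0("duplicate decisions for ",
                       length(dup), " candidate(s); last in file order wins"))
    decisions <- decisions[!duplicated(decisions$candidate_id, fromLast = TRUE), ]
  }
  merged <- dplyr::left_join(candidates, decisions, by = "candidate_id")

  accepted <- merged[!is.na(merged$verdict) & merged$verdict %in% c("product", "parent"), ]
  if (nrow(accepted) > 0 && any(!accepted$resolved_flag)) {
    bad <- accepted$candidate_id[!accepted$resolved_flag]
    stop_tpc(paste0(
      "accept verdict on unresolved structure for candidate(s) ",
      paste(utils::head(bad, 5), collapse = ", "),
      "; supply the structure via the missing-entries path instead"
    ), "tpc_validation_error")
  }

  reactions <- if (nrow(accepted) == 0) empty_reactions() else {
    is_prod <- accepted$verdict == "product"
    pred_smiles <- ifelse(is_prod, accepted$input_smiles, accepted$matched_smiles)
    succ_smiles <- ifelse(is_prod, accepted$matched_smiles, accepted$input_smiles)
    pred_can <- canonicalize(pred_smiles)$smiles
    succ_can <- canonicalize(succ_smiles)$smiles
    tibble::tibble(
      predecessor_name = ifelse(is_prod, accepted$input_name, accepted$matched_name),
      predecessor_cid = ifelse(is_prod, accepted$input_cid, accepted$matched_cid),
      predecessor_smiles = pred_can,
      successor_name = ifelse(is_prod, accepted$matched_name, accepted$input_name),
      successor_cid = ifelse(is_prod, accepted$matched_cid, accepted$input_cid),
      successor_smiles = succ_can,
      biosystem = accepted$biosystem,
      enzyme = accepted$enzyme,
      transformation_type = accepted$transformation_type,
      evidence = accepted$excerpt,
      source_name = accepted$source_name,
      source_id = accepted$source_id,
      reaction_smiles = paste0(pred_can, ">>", succ_can)
    )
  }

  rejected <- merged[!is.na(merged$verdict) & merged$verdict == "reject", ]
  undecided <- merged[is.na(merged$verdict), ]
  ledger <- dplyr::bind_rows(
    tibble::tibble(candidate_id = rejected$candidate_id, status = "rejected",
                   note = rejected$note),
    tibble::tibble(candidate_id = undecided$candidate_id, status = "undecided",
                   note = NA_character_)
  )
  list(reactions = reactions, ledger = ledger)
}

missing_entry_cols <- c("input_cid", "new_name", "new_smiles", "direction",
                        "biosystem", "enzyme", "transformation_type",
                        "evidence_excerpt")

#' Read a missing-entries CSV
#' @param file path to CSV with columns `input_cid`, `new_name`,
#'   `new_smiles`, `direction`, `biosystem`, `enzyme`,
#'   `transformation_type`, `evidence_excerpt`.
#' @return missing-entries tibble.
#' @export
read_missing_entries <- function(file) {
  d <- readr::read_csv(file, col_types = readr::cols(
    input_cid = readr::col_double(), .default = readr::col_character()
  ), na = "")
  check_schema(names(d), missing_entry_cols, "missing-entries table")
  d[missing_entry_cols]
}

#' Curate a compound the text-mining engine missed
#'
#' For transformation partners absent from the markup (e.g. a phosphate
#' ester only a human reader spots), the curator supplies a name and a
#' drawn/typed structure. The new compound carries no CID; the input
#' compound is resolved from the structure index.
#'
#' @param entry one-row tibble or named list with the missing-entry fields
#'   (see [read_missing_entries()]); an optional `new_cid` is honoured.
#' @param input_index structure-index tibble; must contain `entry$input_cid`.
#' @param input_name optional display name for the input compound.
#' @return one-row reaction tibble (library schema).
#' @export
add_missing_entry <- function(entry, input_index, input_name = NA_character_) {
  entry <- as.list(entry)
  if (is_blank(entry$new_name)) {
    stop_tpc("missing entry: new_name must be non-empty", "tpc_validation_error")
  }
  if (!entry$direction %in% c("product", "parent")) {
    stop_tpc(paste0("missing entry: direction must be 'product' or 'parent', got '",
                    entry$direction, "'"), "tpc_validation_error")
  }
  new_ref <- canonicalize(entry$new_smiles)   # errors before any record exists
  hit <- input_index[!is.na(input_index$cid) & input_index$cid == entry$input_cid, ]
  if (nrow(hit) == 0) {
    stop_tpc(paste0("missing entry: input CID ", entry$input_cid,
                    " not in structure index"), "tpc_validation_error")
  }
  input_can <- canonicalize(hit$smiles[1])$smiles
  new_cid <- as.numeric(entry$new_cid %||% NA_real_)
  is_prod <- entry$direction == "product"
  pred <- if (is_prod) list(name = input_name, cid = entry$input_cid, smiles = input_can)
          else list(name = entry$new_name, cid = new_cid, smiles = new_ref$smiles)
  succ <- if (is_prod) list(name = entry$new_name, cid = new_cid, smiles = new_ref$smiles)
          else list(name = input_name, cid = entry$input_cid, smiles = input_can)
  tibble::tibble(
    predecessor_name = as.character(pred$name), predecessor_cid = as.numeric(pred$cid),
    predecessor_smiles = pred$smiles,
    successor_name = as.character(succ$name), successor_cid = as.numeric(succ$cid),
    successor_smiles = succ$smiles,
    biosystem = as.character(entry$biosystem %||% NA_character_),
    enzyme = as.character(entry$enzyme %||% NA_character_),
    transformation_type = as.character(entry$transformation_type %||% NA_character_),
    evidence = as.character(entry$evidence_excerpt %||% NA_character_),
    source_name = as.character(entry$source_name %||% NA_character_),
    source_id = as.character(entry$source_id %||% NA_character_),
    reaction_smiles = paste0(pred$smiles, ">>", succ$smiles)
  )
}

#' Reaction SMILES from predecessor and successor structures
#'
#' @param predecessor_smiles,successor_smiles SMILES strings; canonicalized
#'   before joining.
#' @return character vector of `"A>>B"` reaction SMILES built from the
#'   canonical forms of both sides.
#' @export
make_reaction_smiles <- function(predecessor_smiles, successor_smiles) {
  paste0(canonicalize(predecessor_smiles)$smiles, ">>",
         canonicalize(successor_smiles)$smiles)
}

#' Split a reaction SMILES back into its two sides
#' @param rxn character vector of `"A>>B"` strings.
#' @return tibble with `predecessor_smiles`, `successor_smiles`.
#' @export
split_reaction_smiles <- function(rxn) {
  parts <- strsplit(rxn, ">>", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2
  if (any(bad)) {
    stop_tpc("not a one-step reaction SMILES", "tpc_validation_error")
  }
  tibble::tibble(
    predecessor_smiles = vapply(parts, `[`, character(1), 1),
    successor_smiles = vapply(parts, `[`, character(1), 2)
  )
}

validation_issue_set <- c("salt_component", "stereo_only_difference",
                          "identical_sides", "missing_metadata", "unresolved_cid")

#' Validate curated reactions
#'
#' Reports issues without mutating anything, from a closed vocabulary:
#' \describe{
#'   \item{salt_component}{either side is multi-component (contains `.`).}
#'   \item{stereo_only_difference}{the two sides share an InChIKey skeleton
#'     block but differ in the full key — typically a stereo-only change
#'     mis-curated as a transformation.}
#'   \item{identical_sides}{predecessor and successor are the same
#'     structure at exact level.}
#'   \item{missing_metadata}{biosystem, enzyme and transformation type are
#'     all absent.}
#'   \item{unresolved_cid}{either side lacks a compound identifier.}
#' }
#'
#' @param reactions reaction tibble (library schema).
#' @return list of character vectors, one per reaction row; an empty
#'   vector means the reaction is clean.
#' @export
validate_reactions <- function(reactions) {
  if (nrow(reactions) == 0) return(list())
  pred <- canonicalize(reactions$predecessor_smiles)
  succ <- canonicalize(reactions$successor_smiles)
  lapply(seq_len(nrow(reactions)), function(i) {
    issues <- character()
    if (grepl(".", pred$smiles[i], fixed = TRUE) ||
        grepl(".", succ$smiles[i], fixed = TRUE)) {
      issues <- c(issues, "salt_component")
    }
    if (pred$inchikey[i] == succ$inchikey[i]) {
      issues <- c(issues, "identical_sides")
    } else if (substr(pred$inchikey[i], 1, 14) == substr(succ$inchikey[i], 1, 14)) {
      issues <- c(issues, "stereo_only_difference")
    }
    if (is_blank(reactions$biosystem[i]) && is_blank(reactions$enzyme[i]) &&
        is_blank(reactions$transformation_type[i])) {
      issues <- c(issues, "missing_metadata")
    }
    if (is.na(reactions$predecessor_cid[i]) || is.na(reactions$successor_cid[i])) {
      issues <- c(issues, "unresolved_cid")
    }
    issues
  })
}

#' Finalize a curation run
#'
#' Applies decisions, appends curated missing entries, and refuses to
#' finalize while undecided candidates remain unless explicitly allowed.
#'
#' @inheritParams apply_decisions
#' @param missing_entries optional missing-entries tibble.
#' @param structure_index structure index for resolving missing-entry inputs.
#' @param allow_undecided proceed even when some candidates are undecided.
#' @return list with `reactions` and `ledger` as in [apply_decisions()].
#' @export
finalize_curation <- function(candidates, decisions, missing_entries = NULL,
                              structure_index = NULL, allow_undecided = FALSE) {
  res <- apply_decisions(candidates, decisions)
  undecided <- res$ledger$candidate_id[res$ledger$status == "undecided"]
  if (length(undecided) > 0 && !allow_undecided) {
    stop_tpc(paste0(length(undecided), " undecided candidate(s): ",
                    paste(utils::head(undecided, 10), collapse = ", "),
                    ". Decide them or pass allow_undecided = TRUE."),
             "tpc_undecided_error", undecided = undecided)
  }
  if (!is.null(missing_entries) && nrow(missing_entries) > 0) {
    extra <- lapply(seq_len(nrow(missing_entries)), function(i) {
      add_missing_entry(missing_entries[i, ], structure_index)
    })
    res$reactions <- dplyr::bind_rows(res$reactions, dplyr::bind_rows(extra))
  }
  res
}

#' Read / write a curated-reactions CSV (library schema)
#' @param file path to CSV.
#' @return reactions tibble.
#' @export
read_reactions <- function(file) {
  d <- readr::read_csv(file, col_types = readr::cols(
    predecessor_cid = readr::col_double(), successor_cid = readr::col_double(),
    .default = readr::col_character()
  ), na = "")
  check_schema(names(d), reaction_cols, "reactions table")
  d[reaction_cols]
}

#' @rdname read_reactions
#' @param reactions reactions tibble.
#' @export
write_reactions <- function(reactions, file) {
  check_schema(names(reactions), reaction_cols, "reactions table")
  readr::write_csv(reactions[reaction_cols], file, na = "")
  invisible(file)
}
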