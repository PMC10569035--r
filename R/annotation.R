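#' Parsing text-mined annotation JSON
#'
#' The supported input dialect follows the PubChem PUG-View annotation
#' shape: a top-level `Annotations` array whose elements carry `SourceName`,
#' `SourceID`, `Name`, `CID` and a `Data` array of values, each value
#' holding a `StringWithMarkup` array. Every `StringWithMarkup` element is
#' one text excerpt (`String`) with a `Markup` array of spans; each span
#' has `Start` (0-based character offset in Unicode code points), `Length`
#' (code-point count), optionally `CID` (the linked compound) and `Text`
#' (the matched name, cross-checked against the excerpt when present).
#' A machine-readable JSON Schema for this dialect ships under
#' `inst/schema/annotation-schema.json`.
#'
#' @name annotation
NULL

#' Parse an annotation JSON document into annotation records
#'
#' One record is produced per (compound, excerpt) pair; records whose
#' excerpt carries no markup spans are retained, since the bare excerpt
#' still feeds the missing-entry curation path. Every span is verified
#' against the excerpt text and spans are sorted by start offset.
#'
#' @param document path to a JSON file, or a JSON string.
#' @return list of annotation records; each record is a list with
#'   `input_cid`, `input_name`, `source_name`, `source_id`, `excerpt` and
#'   `spans` (a tibble with `start`, `length`, `matched_text`, `linked_cid`).
#' @export
parse_annotation_json <- function(document) {
  doc <- tryCatch(
    jsonlite::fromJSON(document, simplifyVector = FALSE),
    error = function(e) {
      stop_tpc(paste0("malformed annotation JSON: ", conditionMessage(e)),
               "tpc_parse_error")
    }
  )
  anns <- doc[["Annotations"]]
  if (is.null(anns)) {
    if (identical(doc, list()) || length(doc) == 0) return(list())
    stop_tpc("malformed annotation document: missing 'Annotations' array at $",
             "tpc_parse_error")
  }
  records <- list()
  for (i in seq_along(anns)) {
    a <- anns[[i]]
    path <- sprintf("Annotations[%d]", i)
    cid <- a[["CID"]] %||% a[["LinkedRecords"]][["CID"]][[1]]
    if (is.null(cid)) {
      stop_tpc(paste0("malformed record at ", path, ": no input CID"),
               "tpc_parse_error")
    }
    data <- a[["Data"]] %||% list()
    for (j in seq_along(data)) {
      swm <- data[[j]][["Value"]][["StringWithMarkup"]] %||% list()
      for (k in seq_along(swm)) {
        el <- swm[[k]]
        epath <- sprintf("%s.Data[%d].StringWithMarkup[%d]", path, j, k)
        excerpt <- el[["String"]]
        if (is.null(excerpt) || !nzchar(excerpt)) {
          stop_tpc(paste0("malformed record at ", epath, ": empty excerpt"),
                   "tpc_parse_error")
        }
        spans <- parse_markup(el[["Markup"]] %||% list(), excerpt, epath)
        records[[length(records) + 1]] <- list(
          input_cid = as.numeric(cid),
          input_name = as.character(a[["Name"]] %||% NA_character_),
          source_name = as.character(a[["SourceName"]] %||% NA_character_),
          source_id = as.character(a[["SourceID"]] %||% NA_character_),
          excerpt = excerpt,
          spans = spans
        )
      }
    }
  }
  records
}

parse_markup <- function(markup, excerpt, epath) {
  n <- length(markup)
  spans <- tibble::tibble(
    start = integer(n), length = integer(n),
    matched_text = character(n), linked_cid = numeric(n)
  )
  exc_len <- nchar(excerpt, type = "chars")
  for (m in seq_along(markup)) {
    mk <- markup[[m]]
    mpath <- sprintf("%s.Markup[%d]", epath, m)
    start <- mk[["Start"]]
    len <- mk[["Length"]]
    if (is.null(start) || is.null(len) || start < 0 || len < 1 ||
        start + len > exc_len) {
      stop_tpc(paste0("invalid span at ", mpath,
                      ": Start/Length out of range for excerpt"),
               "tpc_validation_error")
    }
    sub <- substr(excerpt, start + 1, start + len)
    if (!is.null(mk[["Text"]]) && !identical(mk[["Text"]], sub)) {
      stop_tpc(paste0("span/text mismatch at ", mpath, ": markup Text '",
                      mk[["Text"]], "' != excerpt substring '", sub, "'"),
               "tpc_validation_error")
    }
    spans$start[m] <- as.integer(start)
    spans$length[m] <- as.integer(len)
    spans$matched_text[m] <- sub
    spans$linked_cid[m] <- as.numeric(mk[["CID"]] %||% NA_real_)
  }
  spans[order(spans$start), ]
}

candidate_cols <- c("candidate_id", "input_cid", "input_name", "input_smiles",
                    "matched_name", "matched_cid", "matched_smiles",
                    "resolved_flag", "excerpt", "source_name", "source_id")

#' Flatten annotation records into a candidate-reaction table
#'
#' Emits one candidate row per markup span. Structures for the input
#' compound and the matched compound are resolved from a local structure
#' index; spans whose CID is absent from the index (or absent altogether)
#' are flagged unresolved, never dropped.
#'
#' @param records list of annotation records from [parse_annotation_json()].
#' @param structure_index tibble from [read_structure_index()] /
#'   [build_structure_index()].
#' @return tibble with columns `candidate_id`, `input_cid`, `input_name`,
#'   `input_smiles`, `matched_name`, `matched_cid`, `matched_smiles`,
#'   `resolved_flag`, `excerpt`, `source_name`, `source_id`.
#' @export
flatten_candidates <- function(records, structure_index) {
  lookup <- stats::setNames(structure_index$smiles,
                            as.character(structure_index$cid))
  rows <- purrr::map(records, function(r) {
    if (nrow(r$spans) == 0) return(NULL)
    input_smiles <- unname(lookup[as.character(r$input_cid)])
    tibble::tibble(
      input_cid = r$input_cid,
      input_name = r$input_name,
      input_smiles = if (is.null(input_smiles)) NA_character_ else input_smiles,
      matched_name = r$spans$matched_text,
      matched_cid = r$spans$linked_cid,
      matched_smiles = unname(lookup[as.character(r$spans$linked_cid)]),
      start = r$spans$start,
      excerpt = r$excerpt,
      source_name = r$source_name,
      source_id = r$source_id
    )
  })
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0) return(empty_candidates())
  tab$resolved_flag <- !is.na(tab$matched_smiles) & !is.na(tab$input_smiles)
  tab$candidate_id <- candidate_id(tab$input_cid, tab$source_id,
                                   tab$start, tab$matched_cid)
  if (anyDuplicated(tab$candidate_id)) {
    stop_tpc("candidate_id collision in flattened table", "tpc_internal_error")
  }
  tab[candidate_cols]
}

empty_candidates <- function() {
  tibble::tibble(
    candidate_id = character(), input_cid = numeric(), input_name = character(),
    input_smiles = character(), matched_name = character(),
    matched_cid = numeric(), matched_smiles = character(),
    resolved_flag = logical(), excerpt = character(),
    source_name = character(), source_id = character()
  )
}

candidate_col_types <- readr::cols(
  candidate_id = readr::col_character(), input_cid = readr::col_double(),
  input_name = readr::col_character(), input_smiles = readr::col_character(),
  matched_name = readr::col_character(), matched_cid = readr::col_double(),
  matched_smiles = readr::col_character(), resolved_flag = readr::col_logical(),
  excerpt = readr::col_character(), source_name = readr::col_character(),
  source_id = readr::col_character()
)

#' Read / write the candidates CSV
#'
#' Fixed column order, UTF-8, `NA` written as empty field. Write-then-read
#' is the identity on all fields including unresolved (NA) structures.
#'
#' @param file path to a CSV file.
#' @return tibble of candidate rows.
#' @export
read_candidates <- function(file) {
  tab <- readr::read_csv(file, col_types = candidate_col_types, na = "")
  check_schema(names(tab), candidate_cols, "candidates table")
  tab[candidate_cols]
}

#' @rdname read_candidates
#' @param rows candidates tibble from [flatten_candidates()].
#' @export
write_candidates <- function(rows, file) {
  check_schema(names(rows), candidate_cols, "candidates table")
  readr::write_csv(rows[candidate_cols], file, na = "")
  invisible(file)
}
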