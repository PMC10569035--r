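#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# 32-bit FNV-1a over the UTF-8 bytes of a string. Done in split 16-bit
# arithmetic so the 32x24-bit product stays within double precision.
fnv1a32 <- function(x) {
  vapply(x, function(s) {
    bytes <- utf8ToInt(enc2utf8(s))
    h <- 2166136261
    for (b in bytes) {
      h <- bitwXor_dbl(h, b %% 256)
      lo <- h %% 65536
      hi <- h %/% 65536
      h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
    }
    sprintf("%08x", as.integer(bitwAnd_int64(h)))
  }, character(1), USE.NAMES = FALSE)
}

# xor for doubles holding unsigned 32-bit values
bitwXor_dbl <- function(a, b) {
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

# reinterpret unsigned 32-bit double as signed for sprintf("%08x")
bitwAnd_int64 <- function(h) {
  if (h >= 2147483648) h - 4294967296 else h
}

#' Deterministic candidate identifier
#'
#' Hashes the identifying tuple of a candidate span (input CID, source id,
#' span start, matched CID) into a short stable key. Missing matched CIDs
#' hash as the literal "NA" so unresolved spans still get unique ids.
#'
#' @param input_cid,source_id,start,matched_cid vectors of equal length.
#' @return character vector of keys, e.g. `"cand-9f2a41c7"`.
#' @export
candidate_id <- function(input_cid, source_id, start, matched_cid) {
  key <- paste(input_cid, source_id, start, matched_cid, sep = "\x1f")
  paste0("cand-", fnv1a32(key))
}

# case + surrounding-whitespace normalization for metadata comparison;
# NA and "" compare equal (both mean "not recorded")
norm_meta <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x)] <- ""
  x
}

# treat NA and "" uniformly as absent free-text metadata
is_blank <- function(x) is.na(x) | trimws(as.character(x)) == ""

stop_tpc <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "tpcurate_error"), ...)
}
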