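#' Suspect-based TP labeling and parent-TP linkage
#'
#' The downstream, non-target-screening end of the pipeline: given a list
#' of tentatively identified compounds and a TP suspect list exported from
#' a transformations library, label which identified compounds are TPs,
#' link each labeled TP to its identified parent compound(s), and compare
#' the octanol-water partitioning (XlogP) of TPs against their parents.
#' Matching is identifier-based (InChIKey), not mass-based: the compounds
#' are already identified and MS screening happens upstream.
#'
#' @name screening
NULL

identified_cols <- c("name", "cid", "inchikey", "xlogp")

#' Read an identified-compounds CSV
#'
#' Columns `name`, `cid`, `inchikey`, `xlogp`; `cid` and `xlogp` may be
#' empty. Each compound needs at least one of `cid`/`inchikey`, and any
#' InChIKey present must be well-formed.
#'
#' @param file path to CSV.
#' @return identified-compounds tibble.
#' @export
read_identified <- function(file) {
  d <- readr::read_csv(file, col_types = readr::cols(
    name = readr::col_character(), cid = readr::col_double(),
    inchikey = readr::col_character(), xlogp = readr::col_double()
  ), na = "")
  check_schema(names(d), identified_cols, "identified compounds")
  bad <- !is.na(d$inchikey) & !is_inchikey(d$inchikey)
  if (any(bad)) {
    stop_tpc(paste0("malformed InChIKey(s): ",
                    paste(utils::head(d$inchikey[bad], 5), collapse = ", ")),
             "tpc_validation_error")
  }
  if (any(is.na(d$cid) & is.na(d$inchikey))) {
    stop_tpc("identified compounds need at least one of cid/inchikey",
             "tpc_validation_error")
  }
  d[identified_cols]
}

#' Label TPs among identified compounds
#'
#' A compound is labeled a TP iff its InChIKey matches a suspect entry at
#' the chosen level (`exact`: full key; `skeleton`: first 14-character
#' block, stereo-agnostic). Non-matching compounds are kept and labeled
#' not-TP, never dropped. When a compound matches several suspects at
#' skeleton level, the lexicographically first suspect InChIKey is
#' recorded (suspect lists are sorted, so this is deterministic).
#'
#' @param compounds identified-compounds tibble ([read_identified()]).
#' @param suspects suspect tibble ([export_suspect_list()]).
#' @param level `"exact"` or `"skeleton"`.
#' @return the compounds tibble with added columns `is_tp`,
#'   `suspect_inchikey`, `suspect_predecessors`; the matching level is
#'   attached as attribute `"match_level"`.
#' @export
label_tps <- function(compounds, suspects, level = c("exact", "skeleton")) {
  level <- match.arg(level)
  out <- tibble::as_tibble(compounds)
  out$is_tp <- FALSE
  out$suspect_inchikey <- NA_character_
  out$suspect_predecessors <- NA_character_
  if (nrow(suspects) > 0 && nrow(out) > 0) {
    suspects <- dplyr::arrange(suspects, .data$inchikey)
    skey <- if (level == "exact") suspects$inchikey else substr(suspects$inchikey, 1, 14)
    ckey <- if (level == "exact") out$inchikey else substr(out$inchikey, 1, 14)
    hit <- match(ckey, skey)   # first (sorted) suspect wins at skeleton level
    found <- !is.na(hit) & !is.na(ckey)
    out$is_tp[found] <- TRUE
    out$suspect_inchikey[found] <- suspects$inchikey[hit[found]]
    out$suspect_predecessors[found] <- suspects$predecessor_inchikeys[hit[found]]
  }
  attr(out, "match_level") <- level
  out
}

#' Link labeled TPs to identified parent compounds
#'
#' For each TP-labeled compound, every identified compound whose InChIKey
#' matches one of the suspect's predecessor keys (at the labeling match
#' level) becomes a parent; a TP with k identified parents yields k pairs.
#' TPs with no identified parent go to the orphan list. Self-pairs
#' (parent and TP are the same compound) are excluded and logged.
#'
#' @param labeled output of [label_tps()].
#' @return list with `pairs` (tibble: parent_name, parent_cid,
#'   parent_inchikey, parent_xlogp, tp_name, tp_cid, tp_inchikey,
#'   tp_xlogp, via) and `orphans` (tibble of unmatched TP compounds).
#' @export
link_parent_pairs <- function(labeled) {
  level <- attr(labeled, "match_level") %||% "exact"
  tps <- labeled[labeled$is_tp, ]
  key <- function(x) if (level == "exact") x else substr(x, 1, 14)
  comp_key <- key(labeled$inchikey)
  pairs <- list()
  orphans <- list()
  n_self <- 0L
  for (i in seq_len(nrow(tps))) {
    pred_str <- tps$suspect_predecessors[i]
    if (is.na(pred_str)) pred_str <- ""
    preds <- strsplit(pred_str, ";", fixed = TRUE)[[1]]
    preds <- preds[nzchar(preds)]
    hits <- which(comp_key %in% key(preds))
    # self-pairs excluded: a compound cannot be its own parent
    self <- !is.na(labeled$inchikey[hits]) &
      labeled$inchikey[hits] == tps$inchikey[i]
    n_self <- n_self + sum(self)
    hits <- hits[!self]
    if (length(hits) == 0) {
      orphans[[length(orphans) + 1]] <- tps[i, identified_cols]
    } else {
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        parent_name = labeled$name[hits], parent_cid = labeled$cid[hits],
        parent_inchikey = labeled$inchikey[hits],
        parent_xlogp = labeled$xlogp[hits],
        tp_name = tps$name[i], tp_cid = tps$cid[i],
        tp_inchikey = tps$inchikey[i], tp_xlogp = tps$xlogp[i],
        via = tps$suspect_inchikey[i]
      )
    }
  }
  if (n_self > 0) {
    rlang::inform(paste0("link_parent_pairs: excluded ", n_self, " self-pair(s)"))
  }
  empty_pairs <- tibble::tibble(
    parent_name = character(), parent_cid = numeric(),
    parent_inchikey = character(), parent_xlogp = numeric(),
    tp_name = character(), tp_cid = numeric(), tp_inchikey = character(),
    tp_xlogp = numeric(), via = character()
  )
  list(
    pairs = if (length(pairs)) dplyr::bind_rows(pairs) else empty_pairs,
    orphans = if (length(orphans)) dplyr::bind_rows(orphans) else
      labeled[0, identified_cols]
  )
}

#' Compare XlogP of TPs against their parents
#'
#' Paired one-sided Wilcoxon signed-rank test of the directional claim
#' that TPs are more polar (lower XlogP) than their parents. Pairs missing
#' either XlogP value are excluded and counted; zero differences are
#' dropped. The exact null distribution is used for up to 25 usable
#' pairs, the normal approximation with continuity correction beyond
#' that. Gaussian kernel densities (Silverman's rule-of-thumb bandwidth)
#' of both groups are returned for plotting. The two-sided p-value is
#' reported alongside for transparency.
#'
#' @param pairs pairs tibble from [link_parent_pairs()].
#' @return object of class `tp_xlogp_summary`: list with `n_pairs`,
#'   `n_used`, `n_excluded`, `n_zero_diff`, `median_parent`, `median_tp`,
#'   `statistic` (signed-rank V), `p_value` (one-sided, TP < parent),
#'   `p_two_sided`, `method`, and `densities` (list of two data frames
#'   `parent` and `tp` with columns `x`, `y`).
#' @export
xlogp_compare <- function(pairs) {
  usable <- !is.na(pairs$parent_xlogp) & !is.na(pairs$tp_xlogp)
  n_excluded <- sum(!usable)
  p_x <- pairs$parent_xlogp[usable]
  t_x <- pairs$tp_xlogp[usable]
  d <- t_x - p_x
  n_zero <- sum(d == 0)
  n_used <- sum(d != 0)
  if (n_used == 0) {
    stop_tpc("xlogp_compare: no usable pairs with nonzero XlogP difference",
             "tpc_validation_error")
  }
  exact <- n_used <= 25
  if (exact) {
    ex <- exact_signed_rank(d[d != 0])
    statistic <- ex$v
    p_less <- ex$p_less
    p_two <- ex$p_two
  } else {
    wt_less <- suppressWarnings(stats::wilcox.test(
      t_x, p_x, paired = TRUE, alternative = "less",
      exact = FALSE, correct = TRUE
    ))
    wt_two <- suppressWarnings(stats::wilcox.test(
      t_x, p_x, paired = TRUE, alternative = "two.sided",
      exact = FALSE, correct = TRUE
    ))
    statistic <- unname(wt_less$statistic)
    p_less <- wt_less$p.value
    p_two <- wt_two$p.value
  }
  structure(list(
    n_pairs = nrow(pairs), n_used = n_used, n_excluded = n_excluded,
    n_zero_diff = n_zero,
    median_parent = stats::median(p_x), median_tp = stats::median(t_x),
    statistic = statistic,
    p_value = p_less, p_two_sided = p_two,
    method = if (exact) "exact" else "normal approximation with continuity correction",
    densities = list(
      parent = density_df(p_x),
      tp = density_df(t_x)
    )
  ), class = "tp_xlogp_summary")
}

# Exact null distribution of the signed-rank statistic V (sum of positive
# ranks) under random signs, via the generating function prod(1 + x^r_i).
# Tied absolute differences get midranks; doubling keeps exponents integer,
# so ties are handled exactly rather than by approximation.
exact_signed_rank <- function(d) {
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1)   # counts[k+1] = #assignments with 2V == k
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
    counts <- counts + shifted
  }
  counts <- counts / sum(counts)
  v2 <- as.integer(round(2 * v))
  p_less <- sum(counts[seq_len(v2 + 1)])
  p_greater <- sum(counts[(v2 + 1):(total + 1)])
  list(v = v, p_less = p_less, p_greater = p_greater,
       p_two = min(1, 2 * min(p_less, p_greater)))
}

density_df <- function(x) {
  if (length(x) < 2) return(data.frame(x = numeric(), y = numeric()))
  d <- stats::density(x, bw = "nrd0", kernel = "gaussian")
  data.frame(x = d$x, y = d$y)
}

#' @export
print.tp_xlogp_summary <- function(x, ...) {
  cat("<tp_xlogp_summary>\n",
      " pairs: ", x$n_pairs, " (", x$n_used, " used, ", x$n_excluded,
      " missing XlogP, ", x$n_zero_diff, " zero differences)\n",
      " median XlogP: parent ", format(x$median_parent, digits = 3),
      ", TP ", format(x$median_tp, digits = 3), "\n",
      " Wilcoxon signed-rank (TP < parent, ", x$method, "): V = ",
      x$statistic, ", p = ", format(x$p_value, digits = 4),
      " (two-sided ", format(x$p_two_sided, digits = 4), ")\n", sep = "")
  invisible(x)
}
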