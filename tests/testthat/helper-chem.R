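# shared chemistry constants and independent oracles

# chloro-s-triazine herbicides and their shared hydroxy TP
TERBUTHYLAZINE <- "CCNc1nc(Cl)nc(NC(C)(C)C)n1"
TERBUTRYN <- "CCNc1nc(SC)nc(NC(C)(C)C)n1"
TERBUTHYLAZINE_2_OH <- "CCNc1nc(O)nc(NC(C)(C)C)n1"

L_ALANINE <- "N[C@@H](C)C(=O)O"
D_ALANINE <- "N[C@H](C)C(=O)O"

# independent monoisotopic-mass oracle: sum of most-abundant-isotope masses
iso_mass <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
              S = 31.97207069, Cl = 34.96885271, Na = 22.98976928)

formula_mass <- function(formula) {
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  sum(vapply(toks, function(t) {
    el <- gsub("[0-9]", "", t)
    n <- suppressWarnings(as.integer(gsub("[^0-9]", "", t)))
    if (is.na(n)) n <- 1L
    iso_mass[[el]] * n
  }, numeric(1)))
}

# brute-force one-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the ranked absolute differences (alternative: less)
brute_wilcox_less_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  total <- 0L
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    v <- sum(r[signs])
    total <- total + 1L
    if (v <= v_obs) hits <- hits + 1L
  }
  hits / total
}

# wrap a vector of differences as a pairs tibble for xlogp_compare
diffs_as_pairs <- function(parent, tp) {
  tibble::tibble(
    parent_name = paste0("p", seq_along(parent)), parent_cid = seq_along(parent),
    parent_inchikey = NA_character_, parent_xlogp = parent,
    tp_name = paste0("t", seq_along(tp)), tp_cid = 1000 + seq_along(tp),
    tp_inchikey = NA_character_, tp_xlogp = tp, via = NA_character_
  )
}

# minimal one-row reaction table builder for validation tests
mk_reaction <- function(pred_smiles, succ_smiles, pred_cid = 1, succ_cid = 2,
                        biosystem = "human", enzyme = NA_character_,
                        type = "oxidation") {
  tibble::tibble(
    predecessor_name = "pred", predecessor_cid = pred_cid,
    predecessor_smiles = pred_smiles,
    successor_name = "succ", successor_cid = succ_cid,
    successor_smiles = succ_smiles,
    biosystem = biosystem, enzyme = enzyme, transformation_type = type,
    evidence = "text", source_name = "HSDB", source_id = "X-1",
    reaction_smiles = paste0(pred_smiles, ">>", succ_smiles)
  )
}

reaction_key_set <- function(reactions) {
  if (nrow(reactions) == 0) return(character())
  pik <- canonicalize(reactions$predecessor_smiles)$inchikey
  sik <- canonicalize(reactions$successor_smiles)$inchikey
  sort(unique(paste(pik, sik, reactions$biosystem, sep = "|")))
}
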