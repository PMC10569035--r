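#' Deterministic fixtures with planted ground truth
#'
#' Generators for annotation JSON, decision files, transformation
#' libraries and screening tables, each returning a ledger that fully
#' determines the expected output of every pipeline stage. Fixture
#' chemistry uses homologous series of real, simple structures (1-alkanols,
#' n-alkanoic acids, n-alkylbenzenes, 1-aminoalkanes plus their oxidation,
#' hydroxylation, acetylation and hydrolysis partners), so canonicalization
#' and mass code paths run on chemically valid inputs; random SMILES
#' strings would mostly be invalid. All randomness flows from the single
#' `seed` argument; the generators never touch the global RNG state.
#'
#' @name fixtures
NULL

# Parent pool: three homologous families, each with two transformation
# products and (for two families) a known precursor. CIDs are synthetic
# but stable: parents 10000+, TP1 20000+, TP2 30000+, precursors 40000+.
fixture_parent_pool <- function() {
  mk <- function(family, ns, name_fmt, smi, tp1_fmt, tp1, tp1_type,
                 tp2_fmt, tp2, tp2_type, prec_fmt = NULL, prec = NULL,
                 prec_type = NA_character_) {
    tibble::tibble(
      family = family, n = ns,
      name = sprintf(name_fmt, ns), smiles = vapply(ns, smi, character(1)),
      tp1_name = sprintf(tp1_fmt, ns), tp1_smiles = vapply(ns, tp1, character(1)),
      tp1_type = tp1_type,
      tp2_name = sprintf(tp2_fmt, ns), tp2_smiles = vapply(ns, tp2, character(1)),
      tp2_type = tp2_type,
      prec_name = if (is.null(prec_fmt)) NA_character_ else sprintf(prec_fmt, ns),
      prec_smiles = if (is.null(prec)) NA_character_ else
        vapply(ns, prec, character(1)),
      prec_type = prec_type
    )
  }
  pool <- dplyr::bind_rows(
    mk("alkanol", 2:81, "alkan-1-ol-C%02d",
       function(n) paste0(strrep("C", n), "O"),
       "alkanoic-acid-C%02d", function(n) paste0(strrep("C", n - 1), "C(=O)O"),
       "oxidation",
       "alkanal-C%02d", function(n) paste0(strrep("C", n - 1), "C=O"),
       "oxidation",
       "alkyl-acetate-C%02d", function(n) paste0(strrep("C", n), "OC(C)=O"),
       "ester hydrolysis"),
    mk("alkylbenzene", 1:80, "alkylbenzene-C%02d",
       function(n) paste0(strrep("C", n), "c1ccccc1"),
       "phenylalkan-1-ol-C%02d",
       function(n) paste0("OC", strrep("C", n - 1), "c1ccccc1"),
       "hydroxylation",
       "phenylalkanal-C%02d",
       function(n) paste0("O=C", strrep("C", n - 1), "c1ccccc1"),
       "oxidation"),
    mk("alkylamine", 1:80, "aminoalkane-C%02d",
       function(n) paste0(strrep("C", n), "N"),
       "alkyl-acetamide-C%02d", function(n) paste0(strrep("C", n), "NC(C)=O"),
       "acetylation",
       "alkyl-hydroxylamine-C%02d", function(n) paste0(strrep("C", n), "NO"),
       "hydroxylation",
       "nitroalkane-C%02d", function(n) paste0(strrep("C", n), "[N+](=O)[O-]"),
       "reduction")
  )
  i <- seq_len(nrow(pool))
  pool$cid <- 10000 + i
  pool$tp1_cid <- 20000 + i
  pool$tp2_cid <- 30000 + i
  pool$prec_cid <- ifelse(is.na(pool$prec_smiles), NA_real_, 40000 + i)
  pool
}

# Distractor compounds (chemical names that appear in metabolism text but
# take no part in the transformation) and per-parent unresolved conjugates
# (structures deliberately absent from the structure index).
fixture_distractor_pool <- function() {
  n <- 1:80
  tibble::tibble(
    name = sprintf("alkane-1-thiol-C%02d", n),
    smiles = paste0(strrep("C", n), "S"),
    cid = 50000 + n
  )
}

fixture_biosystems <- c("human", "rat", "soil", "activated sludge",
                        "water-sediment system")
fixture_enzymes <- c("CYP3A4", "CYP2D6", "carboxylesterase", NA_character_)

#' Generate an annotation fixture with planted reactions
#'
#' Emits a PUG-View-style annotation JSON, a matching structure index, a
#' ground-truth decisions table and a ledger. Spans are of three kinds:
#' true transformation mentions (verdict `product` or `parent`),
#' distractor mentions (verdict `reject`) and unresolved mentions (a
#' conjugate whose CID is withheld from the structure index; verdict
#' `reject`). Applying the ground-truth decisions to the flattened
#' candidates reproduces exactly the ledger's planted reaction set.
#'
#' @param seed integer; the only source of randomness.
#' @param n_compounds number of input compounds (max 240).
#' @param n_excerpts excerpts per compound.
#' @param n_spans total markup spans across all excerpts.
#' @param true_fraction fraction of spans that are true transformation
#'   mentions; the default 0.2 mirrors the rate at which text-mined
#'   chemical names correspond to valid reactions in curated HSDB text.
#' @param unresolved_rate fraction of spans pointing at compounds missing
#'   from the structure index.
#' @param dir optional directory; when given, writes `annotation.json`,
#'   `structure_index.csv`, `decisions.csv` and `ledger.json` there.
#' @return list with `annotation_json` (string), `structure_index`
#'   (tibble), `decisions` (tibble) and `ledger` (list; includes the
#'   `planted_reactions` tibble keyed by predecessor/successor InChIKey
#'   and biosystem).
#' @export
gen_annotation_fixture <- function(seed, n_compounds = 50, n_excerpts = 3,
                                   n_spans = 400, true_fraction = 0.2,
                                   unresolved_rate = 0.05, dir = NULL) {
  n_true <- round(true_fraction * n_spans)
  n_unres <- round(unresolved_rate * n_spans)
  n_dist <- n_spans - n_true - n_unres
  if (n_dist < 0 || n_compounds < 1 || n_excerpts < 1) {
    stop_tpc("infeasible fixture parameters", "tpc_validation_error")
  }
  pool <- fixture_parent_pool()
  if (n_compounds > nrow(pool)) {
    stop_tpc(paste0("n_compounds exceeds pool size ", nrow(pool)),
             "tpc_validation_error")
  }
  distractors <- fixture_distractor_pool()

  withr::with_seed(seed, {
    compounds <- pool[sample(nrow(pool), n_compounds), ]
    compounds$biosystem <- sample(fixture_biosystems, n_compounds, replace = TRUE)

    # distribute spans over excerpts, then span types over spans
    n_exc <- n_compounds * n_excerpts
    per_exc <- rep(n_spans %/% n_exc, n_exc)
    extra <- n_spans %% n_exc
    if (extra > 0) {
      bump <- sample(n_exc, extra)
      per_exc[bump] <- per_exc[bump] + 1
    }
    span_types <- sample(c(rep("true", n_true), rep("distractor", n_dist),
                           rep("unresolved", n_unres)))

    ann <- list()
    decision_rows <- list()
    planted <- list()
    unresolved_used <- list()
    true_count <- integer(n_compounds)  # per-compound true-mention counter
    si <- 0L
    for (ci in seq_len(n_compounds)) {
      cmp <- compounds[ci, ]
      for (ei in seq_len(n_excerpts)) {
        k <- per_exc[(ci - 1) * n_excerpts + ei]
        source_id <- sprintf("HSDB-%d-%d", cmp$cid, ei)
        text <- sprintf("Study %d: in %s, %s", ei, cmp$biosystem, cmp$name)
        markup <- list()
        if (k > 0) for (sj in seq_len(k)) {
          si <- si + 1L
          type <- span_types[si]
          if (type == "true") {
            true_count[ci] <- true_count[ci] + 1L
            slot <- ((true_count[ci] - 1L) %% 3L) + 1L
            if (slot == 2L && is.na(cmp$prec_smiles)) slot <- 3L
            if (slot == 1L) {
              mention <- cmp$tp1_name; mcid <- cmp$tp1_cid
              verdict <- "product"; tt <- cmp$tp1_type
              lead <- " is oxidized to "
              pred <- cmp; succ_name <- cmp$tp1_name
              reaction <- list(pred_smiles = cmp$smiles, succ_smiles = cmp$tp1_smiles,
                               pred_cid = cmp$cid, succ_cid = cmp$tp1_cid)
            } else if (slot == 2L) {
              mention <- cmp$prec_name; mcid <- cmp$prec_cid
              verdict <- "parent"; tt <- cmp$prec_type
              lead <- " is formed from "
              reaction <- list(pred_smiles = cmp$prec_smiles, succ_smiles = cmp$smiles,
                               pred_cid = cmp$prec_cid, succ_cid = cmp$cid)
            } else {
              mention <- cmp$tp2_name; mcid <- cmp$tp2_cid
              verdict <- "product"; tt <- cmp$tp2_type
              lead <- " is further converted to "
              reaction <- list(pred_smiles = cmp$smiles, succ_smiles = cmp$tp2_smiles,
                               pred_cid = cmp$cid, succ_cid = cmp$tp2_cid)
            }
            enzyme <- sample(fixture_enzymes, 1)
            planted[[length(planted) + 1]] <- tibble::tibble(
              predecessor_smiles = reaction$pred_smiles,
              successor_smiles = reaction$succ_smiles,
              predecessor_cid = reaction$pred_cid,
              successor_cid = reaction$succ_cid,
              biosystem = cmp$biosystem, enzyme = enzyme,
              transformation_type = tt
            )
          } else if (type == "distractor") {
            drow <- distractors[sample(nrow(distractors), 1), ]
            mention <- drow$name; mcid <- drow$cid
            verdict <- "reject"; tt <- NA_character_; enzyme <- NA_character_
            lead <- "; co-exposure with "
          } else {
            mention <- paste0(cmp$name, "-sulfate")
            mcid <- 90000 + cmp$cid
            verdict <- "reject"; tt <- NA_character_; enzyme <- NA_character_
            lead <- " forming the conjugate "
            unresolved_used[[length(unresolved_used) + 1]] <-
              tibble::tibble(name = mention, cid = mcid,
                             smiles = paste0(cmp$smiles, "S(=O)(=O)O"))
          }
          text <- paste0(text, lead)
          start <- nchar(text, type = "chars")
          text <- paste0(text, mention)
          markup[[length(markup) + 1]] <- list(
            Start = start, Length = nchar(mention, type = "chars"),
            CID = mcid, Text = mention
          )
          decision_rows[[length(decision_rows) + 1]] <- tibble::tibble(
            candidate_id = candidate_id(cmp$cid, source_id, start, mcid),
            verdict = verdict,
            biosystem = if (verdict == "reject") NA_character_ else cmp$biosystem,
            enzyme = if (verdict == "reject") NA_character_ else enzyme,
            transformation_type = tt,
            note = if (type == "unresolved") "structure not in index" else
              NA_character_
          )
        }
        text <- paste0(text, ".")
        ann[[length(ann) + 1]] <- list(
          SourceName = "HSDB", SourceID = source_id,
          Name = cmp$name, CID = cmp$cid,
          Data = list(list(Value = list(StringWithMarkup = list(
            list(String = text, Markup = markup)
          ))))
        )
      }
    }

    # structure index: parents, TPs, precursors, distractors — NOT the
    # unresolved conjugates
    idx_rows <- dplyr::bind_rows(
      tibble::tibble(cid = compounds$cid, smiles = compounds$smiles),
      tibble::tibble(cid = compounds$tp1_cid, smiles = compounds$tp1_smiles),
      tibble::tibble(cid = compounds$tp2_cid, smiles = compounds$tp2_smiles),
      tibble::tibble(cid = compounds$prec_cid, smiles = compounds$prec_smiles),
      tibble::tibble(cid = distractors$cid, smiles = distractors$smiles)
    )
    idx_rows <- idx_rows[!is.na(idx_rows$cid), ]
    index <- build_structure_index(idx_rows$cid, idx_rows$smiles,
                                   xlogp = estimate_logp(idx_rows$smiles))

    decisions <- dplyr::bind_rows(decision_rows)
    planted_tab <- dplyr::bind_rows(planted)
    if (nrow(planted_tab) > 0) {
      planted_tab$predecessor_inchikey <- canonicalize(planted_tab$predecessor_smiles)$inchikey
      planted_tab$successor_inchikey <- canonicalize(planted_tab$successor_smiles)$inchikey
      planted_tab <- dplyr::distinct(planted_tab)
    }
    ledger <- list(
      seed = seed, n_compounds = n_compounds, n_excerpts = n_excerpts,
      n_spans = n_spans, n_true_spans = n_true, n_distractor_spans = n_dist,
      n_unresolved_spans = n_unres,
      n_decisions = nrow(decisions),
      planted_reactions = planted_tab
    )
    annotation_json <- jsonlite::toJSON(list(Annotations = ann),
                                        auto_unbox = TRUE, pretty = TRUE,
                                        na = "null")
    out <- list(annotation_json = as.character(annotation_json),
                structure_index = index, decisions = decisions,
                ledger = ledger)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(out$annotation_json, file.path(dir, "annotation.json"))
    write_structure_index(out$structure_index, file.path(dir, "structure_index.csv"))
    write_decisions(out$decisions, file.path(dir, "decisions.csv"))
    jsonlite::write_json(out$ledger[setdiff(names(out$ledger), "planted_reactions")],
                         file.path(dir, "ledger.json"), auto_unbox = TRUE)
  }
  out
}

fixture_reaction_pool <- function() {
  pool <- fixture_parent_pool()
  dplyr::bind_rows(
    tibble::tibble(
      predecessor_name = pool$name, predecessor_cid = pool$cid,
      predecessor_smiles = pool$smiles,
      successor_name = pool$tp1_name, successor_cid = pool$tp1_cid,
      successor_smiles = pool$tp1_smiles,
      transformation_type = pool$tp1_type
    ),
    tibble::tibble(
      predecessor_name = pool$name, predecessor_cid = pool$cid,
      predecessor_smiles = pool$smiles,
      successor_name = pool$tp2_name, successor_cid = pool$tp2_cid,
      successor_smiles = pool$tp2_smiles,
      transformation_type = pool$tp2_type
    )
  )
}

finish_reactions <- function(tab, biosystem, enzyme, source_id,
                             evidence = "fixture evidence sentence") {
  tab$biosystem <- biosystem
  tab$enzyme <- enzyme
  tab$evidence <- evidence
  tab$source_name <- "HSDB"
  tab$source_id <- source_id
  tab$reaction_smiles <- paste0(canonicalize(tab$predecessor_smiles)$smiles, ">>",
                                canonicalize(tab$successor_smiles)$smiles)
  tab$predecessor_smiles <- canonicalize(tab$predecessor_smiles)$smiles
  tab$successor_smiles <- canonicalize(tab$successor_smiles)$smiles
  tab[reaction_cols]
}

#' Generate a library fixture with planted dedup classes
#'
#' Builds a transformations library and a curated candidate set whose
#' dedup classification is known by construction: `n_candidates` minus
#' the overlaps are novel pairs absent from the library,
#' `n_overlap_exact` candidates are library rows with identical metadata
#' (only the evidence text differs — an evidence-only difference is an
#' exact duplicate), and `n_overlap_variant` candidates are library pairs
#' with an altered biosystem.
#'
#' @param seed integer seed.
#' @param n_entries library size.
#' @param n_candidates size of the curated set.
#' @param n_overlap_exact,n_overlap_variant planted overlap counts.
#' @return list with `library` (a `tp_library`), `candidates` (reactions
#'   tibble) and `ledger`.
#' @export
gen_library_fixture <- function(seed, n_entries = 200, n_candidates = 25,
                                n_overlap_exact = 3, n_overlap_variant = 2) {
  n_novel <- n_candidates - n_overlap_exact - n_overlap_variant
  pool <- fixture_reaction_pool()
  if (n_novel < 0 || n_entries + n_novel > nrow(pool)) {
    stop_tpc("infeasible library-fixture parameters", "tpc_validation_error")
  }
  withr::with_seed(seed, {
    pool <- pool[sample(nrow(pool)), ]
    lib_tab <- pool[seq_len(n_entries), ]
    lib_tab <- finish_reactions(
      lib_tab,
      biosystem = sample(fixture_biosystems, n_entries, replace = TRUE),
      enzyme = sample(fixture_enzymes, n_entries, replace = TRUE),
      source_id = sprintf("LIB-%04d", seq_len(n_entries))
    )
    lib <- tp_library(lib_tab, version = "fixture-0.1")

    novel <- pool[n_entries + seq_len(n_novel), ]
    novel <- finish_reactions(
      novel,
      biosystem = sample(fixture_biosystems, n_novel, replace = TRUE),
      enzyme = sample(fixture_enzymes, n_novel, replace = TRUE),
      source_id = sprintf("NEW-%04d", seq_len(n_novel))
    )
    exact_idx <- sample(n_entries, n_overlap_exact)
    exact <- lib_tab[exact_idx, ]
    exact$evidence <- "re-curated evidence wording"  # evidence-only difference
    variant_idx <- sample(setdiff(seq_len(n_entries), exact_idx), n_overlap_variant)
    variant <- lib_tab[variant_idx, ]
    variant$biosystem <- vapply(variant$biosystem, function(b) {
      sample(setdiff(fixture_biosystems, b), 1)
    }, character(1))

    candidates <- dplyr::bind_rows(novel, exact, variant)
    candidates <- candidates[sample(nrow(candidates)), ]
    list(
      library = lib, candidates = candidates,
      ledger = list(seed = seed, n_entries = as.integer(n_entries),
                    n_novel = as.integer(n_novel),
                    n_exact = as.integer(n_overlap_exact),
                    n_variant = as.integer(n_overlap_variant))
    )
  })
}

#' Generate a screening fixture with planted TPs, pairs and orphans
#'
#' Plants `n_tp` transformation products among `n_compounds` identified
#' compounds. The first `n_linkable_pairs` TPs have their parent compound
#' in the identified list (one parent each); the remaining `n_orphans`
#' TPs do not. TP XlogP is the parent's XlogP minus `shift` plus Gaussian
#' noise with standard deviation `noise_sd`; parents draw from N(3, 1.5),
#' typical of moderately lipophilic environmental organics.
#'
#' @param seed integer seed.
#' @param n_compounds total identified compounds.
#' @param n_tp planted TPs; must equal `n_linkable_pairs + n_orphans`.
#' @param n_linkable_pairs TPs with an identified parent.
#' @param n_orphans TPs without one.
#' @param shift mean XlogP drop from parent to TP (log units).
#' @param noise_sd standard deviation of the XlogP noise.
#' @return list with `identified` (tibble), `suspects` (tibble),
#'   `library` (the mini `tp_library` behind the suspects) and `ledger`.
#' @export
gen_screening_fixture <- function(seed, n_compounds = 436, n_tp = 72,
                                  n_linkable_pairs = 36, n_orphans = 36,
                                  shift = 1.0, noise_sd = 0.5) {
  if (n_tp != n_linkable_pairs + n_orphans) {
    stop_tpc("n_tp must equal n_linkable_pairs + n_orphans",
             "tpc_validation_error")
  }
  pool <- fixture_parent_pool()
  if (n_tp > nrow(pool)) {
    stop_tpc("n_tp exceeds structure pool", "tpc_validation_error")
  }
  n_background <- n_compounds - n_tp - n_linkable_pairs
  if (n_background < 0) {
    stop_tpc("n_compounds too small for planted TPs and parents",
             "tpc_validation_error")
  }
  distractors <- fixture_distractor_pool()
  withr::with_seed(seed, {
    pick <- pool[sample(nrow(pool), n_tp), ]
    rxn <- tibble::tibble(
      predecessor_name = pick$name, predecessor_cid = pick$cid,
      predecessor_smiles = pick$smiles,
      successor_name = pick$tp1_name, successor_cid = pick$tp1_cid,
      successor_smiles = pick$tp1_smiles,
      transformation_type = pick$tp1_type
    )
    rxn <- finish_reactions(
      rxn,
      biosystem = sample(fixture_biosystems, n_tp, replace = TRUE),
      enzyme = sample(fixture_enzymes, n_tp, replace = TRUE),
      source_id = sprintf("SCR-%04d", seq_len(n_tp))
    )
    lib <- tp_library(rxn, version = "screen-fixture-0.1")
    suspects <- export_suspect_list(lib)

    parent_xlogp <- stats::rnorm(n_tp, mean = 3, sd = 1.5)
    tp_xlogp <- parent_xlogp - shift + stats::rnorm(n_tp, 0, noise_sd)
    tp_ik <- canonicalize(pick$tp1_smiles)$inchikey
    parent_ik <- canonicalize(pick$smiles)$inchikey

    linkable <- seq_len(n_linkable_pairs)
    identified <- dplyr::bind_rows(
      tibble::tibble(name = pick$tp1_name, cid = pick$tp1_cid,
                     inchikey = tp_ik, xlogp = tp_xlogp),
      tibble::tibble(name = pick$name[linkable], cid = pick$cid[linkable],
                     inchikey = parent_ik[linkable],
                     xlogp = parent_xlogp[linkable])
    )
    # background: unused parents + thiol distractors, none of them suspects
    unused <- pool[!pool$cid %in% pick$cid, ]
    prec <- pool[!is.na(pool$prec_smiles), ]
    bg_pool <- dplyr::bind_rows(
      tibble::tibble(name = unused$name, cid = unused$cid, smiles = unused$smiles),
      tibble::tibble(name = prec$prec_name, cid = prec$prec_cid,
                     smiles = prec$prec_smiles),
      tibble::tibble(name = distractors$name, cid = distractors$cid,
                     smiles = distractors$smiles)
    )
    if (n_background > nrow(bg_pool)) {
      stop_tpc("not enough background structures for n_compounds",
               "tpc_validation_error")
    }
    bg <- bg_pool[sample(nrow(bg_pool), n_background), ]
    bg_tab <- tibble::tibble(
      name = bg$name, cid = bg$cid,
      inchikey = canonicalize(bg$smiles)$inchikey,
      xlogp = stats::rnorm(n_background, mean = 3, sd = 1.5)
    )
    identified <- dplyr::bind_rows(identified, bg_tab)
    identified <- identified[sample(nrow(identified)), ]

    ledger <- list(
      seed = seed, n_compounds = n_compounds, n_tp = n_tp,
      n_linkable_pairs = n_linkable_pairs, n_orphans = n_orphans,
      shift = shift, noise_sd = noise_sd,
      tp_inchikeys = tp_ik,
      pair_table = tibble::tibble(
        parent_inchikey = parent_ik[linkable],
        tp_inchikey = tp_ik[linkable],
        parent_xlogp = parent_xlogp[linkable],
        tp_xlogp = tp_xlogp[linkable]
      )
    )
    list(identified = identified, suspects = suspects, library = lib,
         ledger = ledger)
  })
}

#' Materialize a complete fixture workspace on disk
#'
#' Writes every artifact the pipeline consumes: `annotation.json`,
#' `structure_index.csv`, `decisions.csv`, `library.csv` and
#' `identified.csv`, all derived from one seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return `dir`, invisibly.
#' @export
make_fixture_workspace <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- gen_annotation_fixture(seed, dir = dir)
  libfix <- gen_library_fixture(seed)
  write_library(libfix$library, file.path(dir, "library.csv"))
  scr <- gen_screening_fixture(seed)
  readr::write_csv(scr$identified, file.path(dir, "identified.csv"), na = "")
  invisible(dir)
}
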