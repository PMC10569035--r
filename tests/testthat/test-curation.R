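mk_candidates <- function() {
  idx <- build_structure_index(
    cid = c(100, 200, 300, 400),
    smiles = c("CCO", "CC(=O)O", "CCCO", "CCCC(=O)O")
  )
  excerpt <- "ethanol is oxidized to acetic acid; propanol relates to butyric acid"
  doc <- jsonlite::toJSON(list(Annotations = list(list(
    SourceName = "HSDB", SourceID = "HSDB-100", Name = "ethanol", CID = 100,
    Data = list(list(Value = list(StringWithMarkup = list(list(
      String = excerpt,
      Markup = list(
        list(Start = 23, Length = 11, CID = 200),
        list(Start = 36, Length = 8, CID = 300),
        list(Start = 56, Length = 12, CID = 999)  # not in index
      )
    )))))
  ))), auto_unbox = TRUE)
  list(candidates = flatten_candidates(parse_annotation_json(doc), idx),
       index = idx)
}

mk_decision <- function(candidate_id, verdict, biosystem = "human",
                        enzyme = "ADH1B", type = "oxidation",
                        note = NA_character_) {
  tibble::tibble(candidate_id = candidate_id, verdict = verdict,
                 biosystem = biosystem, enzyme = enzyme,
                 transformation_type = type, note = note)
}

test_that("product and parent verdicts orient the reaction correctly", {
  fix <- mk_candidates()
  cand <- fix$candidates

  res <- apply_decisions(cand, mk_decision(cand$candidate_id[1], "product"))
  expect_equal(nrow(res$reactions), 1)
  r <- res$reactions
  expect_identical(r$predecessor_smiles, canonicalize("CCO")$smiles)
  expect_identical(r$successor_smiles, canonicalize("CC(=O)O")$smiles)
  expect_identical(r$reaction_smiles, make_reaction_smiles("CCO", "CC(=O)O"))
  expect_identical(r$biosystem, "human")

  # parent verdict swaps predecessor and successor, nothing else
  flipped <- apply_decisions(cand, mk_decision(cand$candidate_id[1], "parent"))$reactions
  expect_identical(flipped$predecessor_smiles, r$successor_smiles)
  expect_identical(flipped$successor_smiles, r$predecessor_smiles)
  expect_identical(flipped$predecessor_cid, r$successor_cid)
  expect_identical(flipped$biosystem, r$biosystem)
  expect_identical(flipped$evidence, r$evidence)
})

test_that("rejections and undecided candidates land in the ledger", {
  fix <- mk_candidates()
  cand <- fix$candidates
  dec <- dplyr::bind_rows(
    mk_decision(cand$candidate_id[1], "product"),
    mk_decision(cand$candidate_id[2], "reject", note = "not a TP")
  )
  res <- apply_decisions(cand, dec)
  expect_equal(nrow(res$reactions), 1)
  expect_equal(nrow(res$ledger), 2)
  expect_setequal(res$ledger$status, c("rejected", "undecided"))
  # conservation
  expect_equal(nrow(res$reactions) + nrow(res$ledger), nrow(cand))
})

test_that("bad decisions fail loudly", {
  fix <- mk_candidates()
  cand <- fix$candidates
  expect_error(apply_decisions(cand, mk_decision("cand-ffffffff", "product")),
               class = "tpc_validation_error")
  expect_error(apply_decisions(cand, mk_decision(cand$candidate_id[1], "maybe")),
               class = "tpc_validation_error")
  # accepting the unresolved candidate points at the missing-entry path
  err <- expect_error(
    apply_decisions(cand, mk_decision(cand$candidate_id[3], "product")),
    class = "tpc_validation_error"
  )
  expect_match(conditionMessage(err), "missing-entr")
})

test_that("duplicate decisions warn and the last one wins", {
  fix <- mk_candidates()
  cand <- fix$candidates
  dec <- dplyr::bind_rows(
    mk_decision(cand$candidate_id[1], "product"),
    mk_decision(cand$candidate_id[1], "reject")
  )
  expect_warning(res <- apply_decisions(cand, dec), "last in file order")
  expect_equal(nrow(res$reactions), 0)
  expect_identical(res$ledger$status[res$ledger$candidate_id == cand$candidate_id[1]],
                   "rejected")
})

test_that("missing entries create oriented records with canonical structures", {
  idx <- build_structure_index(135398513, "C1=NC2=C(N1COCCO)N=C(NC2=O)N")
  entry <- list(input_cid = 135398513, new_name = "acyclovir diphosphate",
                new_smiles = "C1=NC2=C(N1COCCOP(=O)(O)OP(=O)(O)O)N=C(NC2=O)N",
                direction = "product", biosystem = "human",
                enzyme = "guanylate kinase", transformation_type = "phosphorylation",
                evidence_excerpt = "further phosphorylated")
  r <- add_missing_entry(entry, idx, input_name = "acyclovir")
  expect_identical(r$successor_name, "acyclovir diphosphate")
  expect_true(is.na(r$successor_cid))     # new compound, no CID yet
  expect_identical(r$predecessor_cid, 135398513)
  expect_identical(r$predecessor_smiles,
                   canonicalize("C1=NC2=C(N1COCCO)N=C(NC2=O)N")$smiles)

  entry$direction <- "parent"
  rev <- add_missing_entry(entry, idx, input_name = "acyclovir")
  expect_identical(rev$predecessor_name, r$successor_name)
  expect_identical(rev$successor_name, r$predecessor_name)

  entry$direction <- "product"
  entry$new_smiles <- "xx(("
  expect_error(add_missing_entry(entry, idx), class = "tpc_structure_error")
})

test_that("reaction SMILES are canonical on both sides and splittable", {
  rxn <- make_reaction_smiles("OCC", "OC(C)=O")
  expect_identical(rxn, paste0(canonicalize("CCO")$smiles, ">>",
                               canonicalize("CC(=O)O")$smiles))
  sides <- split_reaction_smiles(rxn)
  expect_identical(sides$predecessor_smiles, canonicalize("CCO")$smiles)
  expect_identical(sides$successor_smiles, canonicalize("CC(=O)O")$smiles)
  expect_error(split_reaction_smiles("CCO"), class = "tpc_validation_error")
})

test_that("validation flags salts, stereo-only pairs and degenerate records", {
  rxn <- dplyr::bind_rows(
    mk_reaction("CC(=O)[O-].[Na+]", "CCO"),                 # salt predecessor
    mk_reaction(L_ALANINE, D_ALANINE),                       # stereo-only
    mk_reaction("CCO", "CCO"),                               # identical sides
    mk_reaction("CCO", "CC(=O)O", biosystem = NA_character_,
                enzyme = NA_character_, type = NA_character_),
    mk_reaction("CCO", "CC(=O)O", succ_cid = NA_real_),
    mk_reaction("CCO", "CC(=O)O")                            # clean
  )
  issues <- validate_reactions(rxn)
  expect_identical(issues[[1]], "salt_component")
  expect_identical(issues[[2]], "stereo_only_difference")
  expect_identical(issues[[3]], "identical_sides")
  expect_identical(issues[[4]], "missing_metadata")
  expect_identical(issues[[5]], "unresolved_cid")
  expect_identical(issues[[6]], character(0))
})

test_that("finalize refuses undecided candidates unless allowed", {
  fix <- mk_candidates()
  cand <- fix$candidates
  dec <- mk_decision(cand$candidate_id[1], "product")
  expect_error(finalize_curation(cand, dec), class = "tpc_undecided_error")
  res <- finalize_curation(cand, dec, allow_undecided = TRUE)
  expect_equal(nrow(res$reactions), 1)
})

test_that("ground-truth decisions recover the fixture's planted reaction set", {
  for (s in c(2, 11)) {
    fix <- gen_annotation_fixture(seed = s, n_compounds = 20, n_spans = 150)
    cand <- flatten_candidates(parse_annotation_json(fix$annotation_json),
                               fix$structure_index)
    res <- apply_decisions(cand, fix$decisions)
    expect_equal(nrow(res$reactions) + nrow(res$ledger), nrow(cand))
    expect_identical(
      reaction_key_set(res$reactions),
      sort(unique(paste(fix$ledger$planted_reactions$predecessor_inchikey,
                        fix$ledger$planted_reactions$successor_inchikey,
                        fix$ledger$planted_reactions$biosystem, sep = "|")))
    )
    expect_equal(sum(res$ledger$status == "undecided"), 0)
  }
})

test_that("decision and reaction CSVs round-trip", {
  fix <- mk_candidates()
  cand <- fix$candidates
  dec <- mk_decision(cand$candidate_id[1], "product")
  f <- withr::local_tempfile(fileext = ".csv")
  write_decisions(dec, f)
  expect_equal(read_decisions(f), dec)

  rxn <- apply_decisions(cand, dec)$reactions
  write_reactions(rxn, f)
  expect_equal(read_reactions(f), rxn)
})
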