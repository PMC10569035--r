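test_that("library CSV round-trips with multiset semantics", {
  fix <- gen_library_fixture(seed = 5, n_entries = 30, n_candidates = 10,
                             n_overlap_exact = 2, n_overlap_variant = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_library(fix$library, f)
  back <- read_library(f, version = fix$library$version)
  expect_equal(back$entries, fix$library$entries)

  # duplicate pair rows are retained on read
  dup <- tp_library(dplyr::bind_rows(fix$library$entries,
                                     fix$library$entries[1, ]))
  write_library(dup, f)
  expect_equal(nrow(read_library(f)$entries), 31)

  # empty library with a valid header reads back empty
  write_library(tp_library(), f)
  expect_equal(nrow(read_library(f)$entries), 0)

  # schema mismatch errors name the columns
  tab <- fix$library$entries
  names(tab)[1] <- "pred_name"
  readr::write_csv(tab, f)
  err <- expect_error(read_library(f), class = "tpc_schema_error")
  expect_match(conditionMessage(err), "predecessor_name")
})

test_that("unique-by-CID counting collapses duplicate pairs, not variants", {
  base <- mk_reaction("CCO", "CC(=O)O", 1, 2)
  lib <- tp_library(dplyr::bind_rows(
    base,
    mk_reaction("CCO", "CC(=O)O", 1, 2, biosystem = "rat"),  # same pair
    mk_reaction("CCCO", "CCC(=O)O", 3, 4),
    mk_reaction("CCCCO", "CCCC(=O)O", NA_real_, NA_real_),   # keyed by inchikey
    mk_reaction("CCCCO", "CCCC(=O)O", NA_real_, NA_real_)
  ))
  expect_equal(count_unique_by_cid(lib), 3)
  expect_equal(count_unique_by_cid(tp_library()), 0)

  fix <- gen_library_fixture(seed = 2, n_entries = 40, n_candidates = 5,
                             n_overlap_exact = 0, n_overlap_variant = 0)
  # fixture pairs are all distinct, so count equals entry count
  expect_equal(count_unique_by_cid(fix$library), 40)
})

test_that("dedup classifies planted novel/exact/variant counts exactly", {
  fix <- gen_library_fixture(seed = 1)
  rep <- dedup_classify(fix$candidates, fix$library)
  expect_equal(unname(rep$counts["novel"]), fix$ledger$n_novel)
  expect_equal(unname(rep$counts["exact_duplicate"]), fix$ledger$n_exact)
  expect_equal(unname(rep$counts["metadata_variant"]), fix$ledger$n_variant)

  # vacuous and self matches
  empty_rep <- dedup_classify(fix$candidates, tp_library())
  expect_equal(unname(empty_rep$counts["novel"]), nrow(fix$candidates))
  self_rep <- dedup_classify(fix$library$entries, fix$library)
  expect_equal(unname(self_rep$counts["novel"]), 0)
  expect_equal(unname(self_rep$counts["metadata_variant"]), 0)
})

test_that("dedup falls back to InChIKey pairs when CIDs are absent", {
  lib <- tp_library(mk_reaction("CCO", "CC(=O)O", 1, 2))
  nocid <- mk_reaction("OCC", "OC(C)=O", NA_real_, NA_real_)  # same structures
  rep <- dedup_classify(nocid, lib)
  expect_equal(unname(rep$counts["exact_duplicate"]), 1)

  # same pair, different biosystem -> metadata variant
  variant <- mk_reaction("OCC", "OC(C)=O", NA_real_, NA_real_, biosystem = "soil")
  expect_equal(unname(dedup_classify(variant, lib)$counts["metadata_variant"]), 1)

  # evidence-only difference is still an exact duplicate
  ev <- mk_reaction("CCO", "CC(=O)O", 1, 2)
  ev$evidence <- "completely different wording"
  expect_equal(unname(dedup_classify(ev, lib)$counts["exact_duplicate"]), 1)

  # metadata comparison ignores case and surrounding whitespace
  spaced <- mk_reaction("CCO", "CC(=O)O", 1, 2, biosystem = "  HUMAN ")
  expect_equal(unname(dedup_classify(spaced, lib)$counts["exact_duplicate"]), 1)
})

test_that("merging adds novel pairs once and is idempotent", {
  fix <- gen_library_fixture(seed = 9)
  lib <- fix$library
  merged <- suppressMessages(merge_reactions(lib, fix$candidates, "novel_only"))
  expect_equal(nrow(merged$entries), nrow(lib$entries) + fix$ledger$n_novel)
  expect_equal(count_unique_by_cid(merged),
               count_unique_by_cid(lib) + fix$ledger$n_novel)

  again <- suppressMessages(merge_reactions(merged, fix$candidates, "novel_only"))
  expect_equal(again$entries, merged$entries)

  withvar <- suppressMessages(merge_reactions(lib, fix$candidates,
                                              "novel_plus_variants"))
  expect_equal(nrow(withvar$entries),
               nrow(lib$entries) + fix$ledger$n_novel + fix$ledger$n_variant)

  expect_error(merge_reactions(lib, fix$candidates, "everything"))
})

test_that("merge order does not change the unique-pair set", {
  fix <- gen_library_fixture(seed = 4, n_entries = 40, n_candidates = 20,
                             n_overlap_exact = 2, n_overlap_variant = 2)
  a <- fix$candidates[1:10, ]
  b <- fix$candidates[11:20, ]
  lib <- fix$library
  ab <- suppressMessages(merge_reactions(merge_reactions(lib, a), b))
  ba <- suppressMessages(merge_reactions(merge_reactions(lib, b), a))
  expect_setequal(tpcurate:::pair_keys(ab$entries), tpcurate:::pair_keys(ba$entries))
})

test_that("suspect export collapses shared TPs and recomputes mass", {
  # one TP reached from two parents -> one suspect entry, two predecessors
  lib <- tp_library(dplyr::bind_rows(
    mk_reaction(TERBUTHYLAZINE, TERBUTHYLAZINE_2_OH, 27389, NA_real_,
                biosystem = "soil", type = "hydrolysis"),
    mk_reaction(TERBUTRYN, TERBUTHYLAZINE_2_OH, 17674, NA_real_,
                biosystem = "soil", type = "hydrolysis")
  ))
  sus <- export_suspect_list(lib)
  expect_equal(nrow(sus), 1)
  preds <- strsplit(sus$predecessor_inchikeys, ";")[[1]]
  expect_setequal(preds, canonicalize(c(TERBUTHYLAZINE, TERBUTRYN))$inchikey)

  expect_equal(nrow(export_suspect_list(tp_library())), 0)

  # mass is recomputed from the structure, not copied from anywhere
  gly <- tp_library(mk_reaction("NCC(=O)O.O", "NCC(=O)O", 1, 750))
  sus2 <- export_suspect_list(gly)
  row <- sus2[sus2$inchikey == canonicalize("NCC(=O)O")$inchikey, ]
  expect_equal(row$monoisotopic_mass, 75.0320, tolerance = 1e-3)

  # suspect-list CSV round-trip (NORMAN-style headers)
  f <- withr::local_tempfile(fileext = ".csv")
  write_suspect_list(sus, f)
  expect_equal(read_suspect_list(f), sus)
})

test_that("suspect entries never share an InChIKey and exports are sorted", {
  fix <- gen_library_fixture(seed = 12, n_entries = 120, n_candidates = 5,
                             n_overlap_exact = 0, n_overlap_variant = 0)
  sus <- export_suspect_list(fix$library)
  expect_equal(anyDuplicated(sus$inchikey), 0)
  expect_identical(sus$inchikey, sort(sus$inchikey))
  # one entry per distinct successor structure
  succ_ik <- canonicalize(fix$library$entries$successor_smiles)$inchikey
  expect_equal(nrow(sus), length(unique(succ_ik)))
})
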