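# helper: theoretical spectrum of a species/adduct from the rule table
synth_spectrum <- function(species, adduct, polarity,
                           precursor_int = 0.3) {
  fr <- suppressWarnings(expected_fragments(species, adduct, polarity))
  prec <- mz_of_adduct(formula_from_species(species), adduct)
  data.frame(mz = c(fr$mz, prec),
             intensity = c(rep(1000, nrow(fr)), 1000 * precursor_int))
}

test_that("database enumeration matches the class grid", {
  db <- build_database("PC", "positive", n_range = c(30, 36),
                       d_range = c(0, 3), include_ether = FALSE,
                       include_ox = FALSE)
  expect_equal(length(unique(db$name)), 28)  # 7 x 4 grid
  expect_setequal(unique(db$adduct),
                  c("[M+H]+", "[M+Na]+", "[M+NH4]+"))
  expect_false(is.unsorted(db$mz))
})

test_that("negative-mode database excludes TAG and sterols", {
  db <- build_database(polarity = "negative")
  expect_false(any(db$class %in% c("TAG", "CE", "Chol")))
  expect_true(all(db$polarity == "negative"))
})

test_that("search recovers the generating species with head-group evidence", {
  cfg <- run_config()
  db <- build_database(polarity = "positive")
  pc <- lipid_species("PC", 34, 1)
  spec <- synth_spectrum(pc, "[M+H]+", "positive")
  prec <- mz_of_adduct(formula_from_species(pc), "[M+H]+")
  cands <- search_spectrum(spec, prec, "positive", db, cfg)
  expect_gt(nrow(cands), 0)
  expect_equal(cands$name[1], "PC 34:1")
  expect_true(cands$head_seen[1])
  # precursor 20 ppm off tolerance: the species is no longer found
  dbpc <- build_database("PC", "positive", n_range = c(30, 36),
                         include_ether = FALSE, include_ox = FALSE)
  expect_equal(nrow(search_spectrum(spec, prec * (1 + 20e-6),
                                    "positive", dbpc, cfg)), 0)
})

test_that("chimeric spectra return candidates for both species", {
  cfg <- run_config()
  db <- build_database(polarity = "positive")
  pc <- lipid_species("PC", 34, 1)
  pe <- lipid_species("PE", 37, 1)  # exact isobar of PC 34:1
  spec <- rbind(synth_spectrum(pc, "[M+H]+", "positive"),
                synth_spectrum(pe, "[M+H]+", "positive"))
  prec <- mz_of_adduct(formula_from_species(pc), "[M+H]+")
  cands <- search_spectrum(spec, prec, "positive", db, cfg)
  passed <- apply_filters(cands, "positive")
  expect_true(all(c("PC 34:1", "PE 37:1") %in%
                    passed$name[passed$accepted]))
})

test_that("curation filters implement the acceptance rules", {
  cfg <- run_config()
  db <- build_database(polarity = "positive")
  # rule 1: sodiated PC without the protonated feature and without the
  # sodium-specific neutral losses is rejected
  pc <- lipid_species("PC", 34, 1)
  prec_na <- mz_of_adduct(formula_from_species(pc), "[M+Na]+")
  bare <- data.frame(mz = c(184.0733, prec_na),
                     intensity = c(1000, 300))
  cands <- search_spectrum(bare, prec_na, "positive", db, cfg)
  f <- apply_filters(cands, "positive", mh_feature_seen = FALSE)
  pcrow <- f[f$name == "PC 34:1", ]
  expect_false(pcrow$accepted)
  expect_match(pcrow$rejected_by, "pc_adduct")
  # with both sodiated losses present it passes
  full <- synth_spectrum(pc, "[M+Na]+", "positive")
  cands2 <- search_spectrum(full, prec_na, "positive", db, cfg)
  f2 <- apply_filters(cands2, "positive", mh_feature_seen = FALSE)
  expect_true(f2[f2$name == "PC 34:1", ]$accepted)
  # with the protonated feature observed it passes even without them
  f3 <- apply_filters(cands, "positive", mh_feature_seen = TRUE)
  expect_true(f3[f3$name == "PC 34:1", ]$accepted)

  # rule 2: PE spectrum containing the 141.0193 neutral loss passes;
  # removing the required loss flips it to rejected
  pe <- lipid_species("PE", 34, 1)
  spec_pe <- synth_spectrum(pe, "[M+H]+", "positive")
  prec_pe <- mz_of_adduct(formula_from_species(pe), "[M+H]+")
  c_pe <- search_spectrum(spec_pe, prec_pe, "positive", db, cfg)
  f_pe <- apply_filters(c_pe, "positive")
  expect_true(f_pe[f_pe$name == "PE 34:1", ]$accepted)
  nl_mz <- prec_pe - 141.0191
  stripped <- spec_pe[abs(spec_pe$mz - nl_mz) > 0.01, ]
  c_st <- search_spectrum(stripped, prec_pe, "positive", db, cfg)
  f_st <- apply_filters(c_st, "positive")
  expect_false(f_st[f_st$name == "PE 34:1", ]$accepted)

  # rule 4: cholesteryl ester accepted when the precursor dominates
  ce <- lipid_species("CE", 18, 1)
  prec_ce <- mz_of_adduct(formula_from_species(ce), "[M+NH4]+")
  ce_spec <- data.frame(mz = prec_ce, intensity = 5000)
  c_ce <- search_spectrum(ce_spec, prec_ce, "positive", db, cfg)
  f_ce <- apply_filters(c_ce, "positive")
  expect_true(any(f_ce$accepted[f_ce$class == "CE"]))

  # rule 5: TAG with three distinct chains but a single chain fragment
  tag <- lipid_species("TAG", 52, 2,
                       chains = list(c(16, 0), c(18, 1), c(18, 1)))
  prec_tag <- mz_of_adduct(formula_from_species(tag), "[M+NH4]+")
  fr <- expected_fragments(tag, "[M+NH4]+", "positive")
  one_chain <- fr[fr$kind == "chain_nl", ][1, ]
  tag_spec <- data.frame(mz = c(one_chain$mz, prec_tag),
                         intensity = c(1000, 300))
  c_tag <- search_spectrum(tag_spec, prec_tag, "positive", db, cfg)
  f_tag <- apply_filters(c_tag, "positive")
  tg_row <- f_tag[f_tag$name == "TAG 52:2", ]
  expect_false(tg_row$accepted)
  two_chain <- fr[fr$kind == "chain_nl", ][1:2, ]
  tag_spec2 <- data.frame(mz = c(two_chain$mz, prec_tag),
                          intensity = c(1000, 900, 300))
  c_tag2 <- search_spectrum(tag_spec2, prec_tag, "positive", db, cfg)
  f_tag2 <- apply_filters(c_tag2, "positive")
  expect_true(f_tag2[f_tag2$name == "TAG 52:2", ]$accepted)
})

test_that("negative mode requires a chain carboxylate", {
  cfg <- run_config(polarity = "negative")
  db <- build_database(polarity = "negative")
  pg <- lipid_species("PG", 32, 2, chains = list(c(16, 1), c(16, 1)))
  spec <- synth_spectrum(pg, "[M-H]-", "negative")
  prec <- mz_of_adduct(formula_from_species(pg), "[M-H]-")
  f <- apply_filters(search_spectrum(spec, prec, "negative", db, cfg),
                     "negative")
  expect_true(f[f$name == "PG 32:2", ]$accepted)
  # strip the carboxylates
  cx <- expected_fragments(pg, "[M-H]-", "negative")
  cx <- cx$mz[cx$kind == "chain_carboxylate"]
  stripped <- spec[!sapply(spec$mz, function(m)
    any(abs(m - cx) < 0.01)), ]
  f2 <- apply_filters(search_spectrum(stripped, prec, "negative", db,
                                      cfg), "negative")
  expect_false(f2[f2$name == "PG 32:2", ]$accepted)
})

test_that("tightening tolerances never enlarges the accepted set", {
  db <- build_database(polarity = "positive")
  pe <- lipid_species("PE", 36, 2)
  spec <- synth_spectrum(pe, "[M+H]+", "positive")
  prec <- mz_of_adduct(formula_from_species(pe), "[M+H]+")
  accepted_at <- function(prec_ppm, frag_ppm) {
    cfg <- run_config(prec_ppm = prec_ppm, frag_ppm = frag_ppm)
    c0 <- search_spectrum(spec, prec, "positive", db, cfg)
    sum(apply_filters(c0, "positive")$accepted)
  }
  loose <- accepted_at(5, 10)
  tight <- accepted_at(2, 4)
  tighter <- accepted_at(0.5, 1)
  expect_gte(loose, tight)
  expect_gte(tight, tighter)
})

test_that("identification levels produce the three documented name forms", {
  cfg <- run_config(polarity = "negative")
  db <- build_database(polarity = "negative")
  pg <- lipid_species("PG", 32, 2, chains = list(c(16, 1), c(16, 1)))
  spec <- synth_spectrum(pg, "[M-H]-", "negative")
  prec <- mz_of_adduct(formula_from_species(pg), "[M-H]-")
  best <- apply_filters(search_spectrum(spec, prec, "negative", db,
                                        cfg), "negative")
  best <- best[best$accepted & best$name == "PG 32:2", ][1, ]
  ln <- assign_level_and_name(best)
  expect_equal(ln$level, "full")
  expect_equal(ln$name, "PG 16:1_16:1")
  # species-level fallback: PC in positive mode has no chain evidence
  dbp <- build_database(polarity = "positive")
  pc <- lipid_species("PC", 32, 1)
  specp <- synth_spectrum(pc, "[M+H]+", "positive")
  precp <- mz_of_adduct(formula_from_species(pc), "[M+H]+")
  bestp <- apply_filters(search_spectrum(specp, precp, "positive",
                                         dbp, run_config()), "positive")
  bestp <- bestp[bestp$accepted & bestp$name == "PC 32:1", ][1, ]
  lnp <- assign_level_and_name(bestp)
  expect_equal(lnp$level, "species")
  expect_equal(lnp$name, "PC 32:1")
  # partial level: ceramide with sphingoid evidence only carries an @
  cer <- lipid_species("Cer", 44, 1, chains = list(c(18, 1), c(26, 0)))
  spec_c <- synth_spectrum(cer, "[M+H]+", "positive")
  prec_c <- mz_of_adduct(formula_from_species(cer), "[M+H]+")
  best_c <- apply_filters(search_spectrum(spec_c, prec_c, "positive",
                                          dbp, run_config()), "positive")
  best_c <- best_c[best_c$accepted & best_c$class == "Cer", ][1, ]
  ln_c <- assign_level_and_name(best_c)
  expect_equal(ln_c$level, "partial")
  expect_equal(ln_c$name, "Cer d18:1_26:0@")
})

test_that("deduplication merges adducts and keeps distant isomers apart", {
  ann <- data.frame(
    feature_id = 1:4,
    name = c("PC 34:1", "PC 34:1", "TAG 52:2", "TAG 52:2"),
    level = "species",
    species_name = c("PC 34:1", "PC 34:1", "TAG 52:2", "TAG 52:2"),
    class = c("PC", "PC", "TAG", "TAG"),
    category = c("GP", "GP", "GL", "GL"),
    adduct = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M+NH4]+"),
    mz = c(760.59, 782.57, 876.80, 876.80),
    rt_s = c(500, 500.8, 900, 1020),  # TAGs 2 min apart
    ook0 = 1.3, ccs = c(281, 284, 311, 311),
    intensity = c(1e5, 2e4, 5e4, 4e4),
    adduct_group = c(1L, 1L, 2L, 3L), entry_id = NA_integer_,
    n_matched = 1L, mean_ppm = 0.1, n_candidates = 1L, n_rejected = 0L)
  uni <- deduplicate(ann, rt_tol_s = 3)
  expect_equal(nrow(uni), 3)
  pc <- uni[uni$species_name == "PC 34:1", ]
  expect_equal(pc$n_adducts, 2L)
  expect_equal(sum(uni$species_name == "TAG 52:2"), 2)
  # merging everything regardless of retention collapses the isomers
  uni2 <- deduplicate(ann, rt_tol_s = 3, split_isomers = FALSE)
  expect_equal(nrow(uni2), 2)
  expect_lte(nrow(uni), nrow(ann))
})
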