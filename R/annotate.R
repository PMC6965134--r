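# Rule-based lipid identification from linked MS/MS spectra: in-silico
# database, spectrum search, acceptance/rejection filters, three-level
# nomenclature, and deduplication to unique lipids.

.DB_N_RANGES <- list(
  TAG = c(36, 72), DAG = c(24, 48), MAG = c(12, 26),
  PC = c(24, 48), PE = c(24, 48), PA = c(24, 48), PS = c(24, 48),
  PI = c(24, 48), PG = c(24, 48), LPC = c(12, 26),
  Cer = c(30, 48), SM = c(30, 48), HexCer = c(30, 48),
  CE = c(12, 26), Chol = c(0, 0)
)

#' Build an in-silico lipid database
#'
#' Enumerates species-level entries (class x total carbons x double
#' bonds, plus ether variants of PC/PE and +O/+2O oxidised GP variants)
#' crossed with the polarity's adduct list, indexed for ppm lookup.
#' TAG and sterol classes are excluded from the negative-mode database,
#' and chain-level interpretation of GP entries later enforces an even
#' carbon count on at least one acyl chain.
#'
#' @param classes class labels to include; default all supported.
#' @param polarity `"positive"` or `"negative"`.
#' @param n_range optional `c(min, max)` override of total carbons
#'   (applied to all classes).
#' @param d_range `c(min, max)` total double bonds.
#' @param include_ether,include_ox include ether PC/PE and oxidised GP
#'   variants.
#' @param adducts adduct table.
#' @return data.frame sorted by `mz` with columns `name`, `class`,
#'   `category`, `n`, `d`, `ether`, `ox`, `formula`, `adduct`, `z`,
#'   `mz`, `polarity`.
#' @export
build_database <- function(classes = names(.DB_N_RANGES),
                           polarity = "positive",
                           n_range = NULL, d_range = c(0, 12),
                           include_ether = TRUE, include_ox = TRUE,
                           adducts = default_adducts()) {
  if (length(classes) == 0) stop("class list must not be empty")
  polarity <- match.arg(polarity, c("positive", "negative"))
  if (polarity == "negative") {
    drop <- vapply(classes, function(cl)
      cl == "TAG" || .CLASS_TEMPLATES[[cl]]$category == "ST", logical(1))
    classes <- classes[!drop]
  }
  ad <- adducts[adducts$polarity == polarity, , drop = FALSE]
  rows <- list()
  for (cl in classes) {
    rng <- n_range %||2% .DB_N_RANGES[[cl]]
    nn <- if (cl == "Chol") 0 else seq(rng[1], rng[2])
    variants <- list(list(ether = FALSE, ox = 0L))
    if (include_ether && cl %in% c("PC", "PE"))
      variants <- c(variants, list(list(ether = TRUE, ox = 0L)))
    if (include_ox && .CLASS_TEMPLATES[[cl]]$category == "GP")
      variants <- c(variants, list(list(ether = FALSE, ox = 1L)),
                    list(list(ether = FALSE, ox = 2L)))
    for (v in variants) {
      for (n in nn) {
        dmax <- min(d_range[2], floor(n / 2))
        for (d in seq(d_range[1], dmax)) {
          sp <- lipid_species(cl, n, d, ether = v$ether, ox = v$ox)
          f <- formula_from_species(sp)
          m <- monoisotopic_mass(f)
          rows[[length(rows) + 1]] <- data.frame(
            name = species_name(sp), class = cl,
            category = sp$category, n = n, d = d,
            ether = v$ether, ox = v$ox, formula = format(f),
            adduct = ad$name, z = abs(ad$charge),
            mz = (m + ad$delta_mass) / abs(ad$charge),
            polarity = polarity)
          if (cl == "Chol") break
        }
        if (cl == "Chol") break
      }
    }
  }
  db <- do.call(rbind, rows)
  db <- db[db$mz > 0, ]
  db <- db[order(db$mz), ]
  rownames(db) <- NULL
  db
}

`%||2%` <- function(a, b) if (is.null(a)) b else a

# plausible single acyl chains used for fragment-driven chain
# inference; unsaturation is capped at the physiological envelope
# (no more than (c - 8) / 2 double bonds: 16:1..16:4, 18:0..18:5,
# 20:0..20:6, 22:0..22:7)
.CHAIN_GRID <- local({
  g <- expand.grid(c = 8:26, b = 0:7)
  g[g$b <= pmax(0, (g$c - 8) / 2), ]
})
.chain_plausible <- function(c, b)
  c >= 8 & c <= 26 & b >= 0 & b <= pmax(0, (c - 8) / 2)

# chain fragments observable in a spectrum for one class/polarity:
# returns matched chains as data.frame(c, b, mz, ppm)
.match_chain_fragments <- function(spectrum, class, category, polarity,
                                   prec_mz, adduct, frag_ppm) {
  out <- NULL
  for (i in seq_len(nrow(.CHAIN_GRID))) {
    cc <- .CHAIN_GRID$c[i]; bb <- .CHAIN_GRID$b[i]
    if (bb > cc / 2) next
    fmz <- if (polarity == "negative") {
      .chain_carboxylate_mz(cc, bb)
    } else if (category == "GL") {
      loss <- monoisotopic_mass(.chain_acid_formula(cc, bb))
      if (grepl("NH4", adduct, fixed = TRUE))
        loss <- loss + monoisotopic_mass(chem_formula(N = 1, H = 3))
      prec_mz - loss
    } else if (category == "SP") {
      if (cc < 16 || cc > 20 || bb > 2) NA_real_ else
        .sphingoid_ion_mz(cc, bb)  # long-chain-base fragment
    } else NA_real_
    if (is.na(fmz) || fmz <= 0) next
    tol <- frag_ppm * 1e-6 * fmz
    hit <- which(abs(spectrum$mz - fmz) <= tol)
    if (length(hit) > 0) {
      hit <- hit[which.max(spectrum$intensity[hit])]
      out <- rbind(out, data.frame(
        c = cc, b = bb, mz = fmz,
        ppm = ppm_error(spectrum$mz[hit], fmz)))
    }
  }
  out
}

# decompose (n, d) into n_chains chains using evidenced chains first;
# returns list(chains = list of c(c, b), evidenced = logical vector) or
# NULL when no decomposition fits
.infer_chains <- function(class, n, d, matched) {
  k <- .CLASS_TEMPLATES[[class]]$n_chains
  if (k == 0) return(NULL)
  if (k == 1) {
    ev <- !is.null(matched) && any(matched$c == n & matched$b == d)
    return(list(chains = list(c(n, d)), evidenced = ev))
  }
  mt <- if (is.null(matched)) data.frame(c = numeric(0), b = numeric(0))
        else matched
  cat <- .CLASS_TEMPLATES[[class]]$category
  if (k == 2) {
    # pairs of evidenced chains
    if (nrow(mt) > 0) {
      for (i in seq_len(nrow(mt))) for (j in seq_len(nrow(mt))) {
        if (mt$c[i] + mt$c[j] == n && mt$b[i] + mt$b[j] == d) {
          if (cat == "GP" && mt$c[i] %% 2 == 1 && mt$c[j] %% 2 == 1) next
          return(list(chains = list(c(mt$c[i], mt$b[i]),
                                    c(mt$c[j], mt$b[j])),
                      evidenced = c(TRUE, TRUE)))
        }
      }
      # one evidenced chain, remainder inferred
      for (i in seq_len(nrow(mt))) {
        rc <- n - mt$c[i]; rb <- d - mt$b[i]
        if (.chain_plausible(rc, rb)) {
          if (cat == "GP" && mt$c[i] %% 2 == 1 && rc %% 2 == 1) next
          return(list(chains = list(c(mt$c[i], mt$b[i]), c(rc, rb)),
                      evidenced = c(TRUE, FALSE)))
        }
      }
    }
    return(list(chains = NULL, evidenced = logical(0)))
  }
  # k == 3 (TAG): combinations of evidenced chains
  if (nrow(mt) > 0) {
    idx <- seq_len(nrow(mt))
    for (i in idx) for (j in idx) for (l in idx) {
      if (mt$c[i] + mt$c[j] + mt$c[l] == n &&
          mt$b[i] + mt$b[j] + mt$b[l] == d)
        return(list(chains = list(c(mt$c[i], mt$b[i]),
                                  c(mt$c[j], mt$b[j]),
                                  c(mt$c[l], mt$b[l])),
                    evidenced = c(TRUE, TRUE, TRUE)))
    }
    for (i in idx) for (j in idx) {
      rc <- n - mt$c[i] - mt$c[j]; rb <- d - mt$b[i] - mt$b[j]
      if (.chain_plausible(rc, rb))
        return(list(chains = list(c(mt$c[i], mt$b[i]),
                                  c(mt$c[j], mt$b[j]), c(rc, rb)),
                    evidenced = c(TRUE, TRUE, FALSE)))
    }
    for (i in idx) {
      rc <- n - mt$c[i]; rb <- d - mt$b[i]
      if (rc >= 16 && rc <= 52 && rb >= 0 && rb <= max(0, (rc - 16) / 2))
        return(list(chains = list(c(mt$c[i], mt$b[i])),
                    evidenced = TRUE))
    }
  }
  list(chains = NULL, evidenced = logical(0))
}

#' Search a spectrum against the lipid database
#'
#' All database entries whose precursor m/z lies within the precursor
#' tolerance are considered; class fragment rules are matched at the
#' fragment tolerance and chain-parameterised fragments are matched
#' against a grid of plausible acyl chains. Candidates carry evidence
#' flags used by [apply_filters()].
#'
#' @param spectrum data.frame `mz`/`intensity`.
#' @param precursor_mz precursor m/z.
#' @param polarity ionisation mode.
#' @param db from [build_database()].
#' @param config a [run_config()] (ppm tolerances).
#' @return data.frame of candidates (possibly empty): database columns
#'   plus `n_matched`, `mean_ppm`, `head_seen`, `n_chains_seen`,
#'   `chain_name`, `precursor_base_peak`, `matched_nl59`,
#'   `matched_nl183`.
#' @export
search_spectrum <- function(spectrum, precursor_mz, polarity, db,
                            config = run_config()) {
  stopifnot(nrow(spectrum) > 0)
  tol <- config$prec_ppm * 1e-6 * precursor_mz
  lo <- findInterval(precursor_mz - tol, db$mz) + 1
  hi <- findInterval(precursor_mz + tol, db$mz)
  if (hi < lo) return(db[0, ])
  cand <- db[lo:hi, , drop = FALSE]
  cand <- cand[cand$polarity == polarity, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  base_mz <- spectrum$mz[which.max(spectrum$intensity)]
  res <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cd <- cand[i, ]
    sp <- lipid_species(cd$class, cd$n, cd$d, ether = cd$ether,
                        ox = cd$ox)
    fr <- suppressWarnings(expected_fragments(sp, cd$adduct, polarity))
    fixed <- fr[fr$kind %in% c("diagnostic", "neutral_loss"), ,
                drop = FALSE]
    n_matched <- 0L; n_anchored <- 0L; ppms <- numeric(0)
    head_seen <- FALSE; nl59 <- FALSE; nl183 <- FALSE
    req_rules <- fixed$required
    req_seen <- FALSE; has_req <- any(req_rules)
    if (nrow(fixed) > 0) {
      for (fi in seq_len(nrow(fixed))) {
        ft <- config$frag_ppm * 1e-6 * fixed$mz[fi]
        hitf <- which(abs(spectrum$mz - fixed$mz[fi]) <= ft)
        if (length(hitf) > 0) {
          n_matched <- n_matched + 1L
          if (fixed$kind[fi] == "neutral_loss")
            n_anchored <- n_anchored + 1L
          ppms <- c(ppms, min(abs(ppm_error(spectrum$mz[hitf],
                                            fixed$mz[fi]))))
          if (fixed$required[fi]) req_seen <- TRUE
          head_seen <- head_seen || fixed$required[fi]
          dl <- precursor_mz - fixed$mz[fi]
          if (abs(dl - 59.0735) < 0.01) nl59 <- TRUE
          if (abs(dl - 183.0660) < 0.01) nl183 <- TRUE
        }
      }
    }
    chains <- .match_chain_fragments(spectrum, cd$class, cd$category,
                                     polarity, precursor_mz, cd$adduct,
                                     config$frag_ppm)
    dec <- .infer_chains(cd$class, cd$n, cd$d, chains)
    n_chains_seen <- if (is.null(dec)) 0L else sum(dec$evidenced)
    if (!is.null(chains)) {
      n_matched <- n_matched + nrow(chains)
      if (polarity == "positive" && cd$category == "GL")
        n_anchored <- n_anchored + nrow(chains)  # acyl neutral losses
      ppms <- c(ppms, abs(chains$ppm))
    }
    chain_name <- NA_character_
    if (!is.null(dec) && !is.null(dec$chains) &&
        length(dec$chains) == .CLASS_TEMPLATES[[cd$class]]$n_chains) {
      parts <- vapply(seq_along(dec$chains), function(ci) {
        ch <- dec$chains[[ci]]
        pre <- if (cd$category == "SP" && ci == 1) "d" else ""
        paste0(pre, ch[1], ":", ch[2],
               if (dec$evidenced[ci]) "" else "@")
      }, character(1))
      chain_name <- paste0(cd$class, " ",
                           if (cd$ether) "O-" else "",
                           paste(parts, collapse = "_"),
                           if (cd$ox > 0) paste0(";O", if (cd$ox > 1)
                             cd$ox else "") else "")
    }
    cd$n_matched <- n_matched
    cd$n_anchored <- n_anchored
    cd$mod_penalty <- as.integer(cd$ether) + cd$ox
    cd$prec_ppm <- ppm_error(precursor_mz, cd$mz)
    cd$mean_ppm <- if (length(ppms)) mean(ppms) else NA_real_
    cd$head_seen <- req_seen
    cd$has_required_head <- has_req
    cd$n_chains_seen <- n_chains_seen
    cd$n_chains_distinct <- if (is.null(chains)) 0L else
      nrow(unique(chains[, c("c", "b")]))
    cd$chain_name <- chain_name
    cd$precursor_base_peak <- abs(base_mz - precursor_mz) <=
      config$frag_ppm * 1e-6 * precursor_mz * 2 + 0.005
    cd$matched_nl59 <- nl59
    cd$matched_nl183 <- nl183
    res[[i]] <- cd
  }
  out <- do.call(rbind, res)
  # rank: most matched fragments; precursor-anchored evidence (neutral
  # losses computed from this precursor) over shared diagnostic ions,
  # which any co-isolated lipid of the same head group can contribute;
  # unmodified species over ether/oxidised variants at equal evidence
  # (parsimony); then precursor and fragment mass error
  out[order(-out$n_matched, -out$n_anchored, abs(out$prec_ppm),
            out$mod_penalty, out$mean_ppm), , drop = FALSE]
}

#' Acceptance filters for annotation candidates
#'
#' Automates the study's manual curation rules as hard predicates:
#' \enumerate{
#' \item ammoniated/sodiated PC ions are rejected unless the
#'   protonated feature was observed (`mh_feature_seen`) or both
#'   sodium-specific neutral losses (trimethylamine, phosphocholine)
#'   matched;
#' \item GP, ST and SP candidates require their head-group diagnostic
#'   ion or neutral loss when one is defined for the class;
#' \item neutral glycosphingolipids/ceramides require the
#'   N''-type (long-chain-base) fragment;
#' \item sterol candidates are accepted when the precursor is the base
#'   peak even without the diagnostic ion;
#' \item TAG (DAG) candidates with three (two) unique chains require at
#'   least two (one) matched chain fragments;
#' \item in negative mode every candidate requires at least one
#'   fatty-acyl chain fragment.
#' }
#'
#' @param candidates from [search_spectrum()].
#' @param polarity ionisation mode.
#' @param mh_feature_seen logical (per candidate or scalar): was a
#'   co-eluting protonated feature of the same species observed?
#' @return candidates with `accepted` and `rejected_by` audit columns.
#' @export
apply_filters <- function(candidates, polarity,
                          mh_feature_seen = FALSE) {
  if (nrow(candidates) == 0) {
    candidates$accepted <- logical(0)
    candidates$rejected_by <- character(0)
    return(candidates)
  }
  mh <- rep_len(mh_feature_seen, nrow(candidates))
  acc <- rep(TRUE, nrow(candidates))
  why <- rep(NA_character_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i, ]
    # rule 1: unlikely PC ion species
    if (cd$class %in% c("PC", "LPC") &&
        cd$adduct %in% c("[M+Na]+", "[M+NH4]+")) {
      if (!mh[i] && !(cd$matched_nl59 && cd$matched_nl183)) {
        acc[i] <- FALSE; why[i] <- "pc_adduct_without_MH_or_Na_losses"
        next
      }
    }
    # rules 2-4: head-group evidence (sterol base-peak override)
    if (cd$has_required_head && !cd$head_seen) {
      if (cd$category == "ST" && cd$precursor_base_peak) {
        # sterol accepted on precursor dominance
      } else {
        acc[i] <- FALSE
        why[i] <- if (cd$category == "SP")
          "missing_n_type_fragment" else "missing_head_group_evidence"
        next
      }
    }
    if (cd$category == "ST" && !cd$head_seen &&
        !cd$precursor_base_peak) {
      acc[i] <- FALSE; why[i] <- "sterol_precursor_not_base_peak"
      next
    }
    # rule 5: glycerolipid chain evidence
    if (cd$class == "TAG") {
      ok <- cd$n_chains_distinct >= 2 ||
        (cd$n_chains_distinct == 1 && cd$n %% 3 == 0 && cd$d %% 3 == 0)
      if (!ok) {
        acc[i] <- FALSE; why[i] <- "tag_needs_two_chain_fragments"
        next
      }
    }
    if (cd$class == "DAG" && cd$n_chains_distinct < 1) {
      acc[i] <- FALSE; why[i] <- "dag_needs_one_chain_fragment"
      next
    }
    # rule 6: negative mode chain requirement
    if (polarity == "negative" && cd$n_chains_seen < 1 &&
        cd$n_chains_distinct < 1) {
      acc[i] <- FALSE; why[i] <- "negative_mode_needs_chain_fragment"
      next
    }
  }
  candidates$accepted <- acc
  candidates$rejected_by <- why
  candidates
}

#' Identification level and reported name
#'
#' Fully resolved chain-level names when every chain is evidenced by
#' fragments, partially resolved names with `@` marking uncharacterised
#' chains, and species-level short names otherwise.
#'
#' @param candidate one accepted candidate row.
#' @return list with `level` (`"full"`, `"partial"`, `"species"`) and
#'   `name`.
#' @export
assign_level_and_name <- function(candidate) {
  k <- .CLASS_TEMPLATES[[candidate$class]]$n_chains
  if (k > 0 && !is.na(candidate$chain_name)) {
    if (candidate$n_chains_seen >= k)
      return(list(level = "full", name = candidate$chain_name))
    if (candidate$n_chains_seen >= 1)
      return(list(level = "partial", name = candidate$chain_name))
  }
  list(level = "species", name = candidate$name)
}

#' Annotate features with linked MS/MS spectra
#'
#' Runs [search_spectrum()] and [apply_filters()] over every feature
#' with a summed spectrum, ranks surviving candidates (most matched
#' fragments, then lowest mean fragment ppm) and reports the best one
#' per feature with its identification level and audit trail. The
#' protonated-feature context for the PC adduct rule is derived from
#' co-eluting features.
#'
#' @param features output of [assign_msms()] (with attached spectra).
#' @param db from [build_database()]; built on the fly when `NULL`.
#' @param config a [run_config()].
#' @return data.frame: one row per annotated feature (`feature_id`,
#'   `name`, `level`, `class`, `adduct`, `mz`, `rt_s`, `ook0`, `ccs`,
#'   `intensity`, `n_matched`, `mean_ppm`, `n_candidates`,
#'   `n_rejected`), with the per-feature rejection audit attached as
#'   attribute `"audit"`.
#' @export
annotate_features <- function(features, db = NULL,
                              config = run_config()) {
  polarity <- config$polarity
  if (is.null(db)) db <- build_database(polarity = polarity)
  spectra <- attr(features, "spectra")
  out <- list()
  audit <- list()
  feat_mz_sorted <- sort(features$mz)
  for (i in seq_len(nrow(features))) {
    spec <- spectra[[as.character(features$feature_id[i])]]
    if (is.null(spec) || nrow(spec) == 0) next
    cands <- search_spectrum(spec, features$mz[i], polarity, db, config)
    if (nrow(cands) == 0) next
    # PC rule context: co-eluting [M+H]+ feature of the same species
    mh_seen <- vapply(seq_len(nrow(cands)), function(ci) {
      cd <- cands[ci, ]
      if (!cd$adduct %in% c("[M+Na]+", "[M+NH4]+")) return(FALSE)
      mh_mz <- monoisotopic_mass(cd$formula) + .PROTON_MASS
      sel <- which(abs(features$mz - mh_mz) <=
                     config$prec_ppm * 1e-6 * mh_mz)
      any(abs(features$rt_s[sel] - features$rt_s[i]) <=
            features$rt_fwhm_s[i])
    }, logical(1))
    cands <- apply_filters(cands, polarity, mh_feature_seen = mh_seen)
    audit[[length(audit) + 1]] <- cbind(
      feature_id = features$feature_id[i],
      cands[, c("name", "adduct", "accepted", "rejected_by",
                "n_matched")])
    ok <- cands[cands$accepted, , drop = FALSE]
    if (nrow(ok) == 0) next
    # curation: two different species tied on all evidence cannot be
    # told apart; reject rather than guess
    if (nrow(ok) > 1 && ok$name[2] != ok$name[1] &&
        ok$n_matched[2] == ok$n_matched[1] &&
        ok$n_anchored[2] == ok$n_anchored[1] &&
        ok$mod_penalty[2] == ok$mod_penalty[1] &&
        abs(abs(ok$prec_ppm[2]) - abs(ok$prec_ppm[1])) < 0.5) next
    best <- ok[1, ]
    ln <- assign_level_and_name(best)
    out[[length(out) + 1]] <- data.frame(
      feature_id = features$feature_id[i],
      name = ln$name, level = ln$level,
      species_name = best$name, class = best$class,
      category = best$category, adduct = best$adduct,
      mz = features$mz[i], rt_s = features$rt_s[i],
      ook0 = features$ook0[i], ccs = features$ccs[i],
      intensity = features$intensity[i],
      adduct_group = features$adduct_group[i] %||2% NA_integer_,
      entry_id = features$entry_id[i],
      n_matched = best$n_matched, mean_ppm = best$mean_ppm,
      n_candidates = nrow(cands),
      n_rejected = sum(!cands$accepted))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(feature_id = integer(0), name = character(0),
               level = character(0), species_name = character(0),
               class = character(0), category = character(0),
               adduct = character(0), mz = numeric(0), rt_s = numeric(0),
               ook0 = numeric(0), ccs = numeric(0),
               intensity = numeric(0), adduct_group = integer(0),
               entry_id = integer(0), n_matched = integer(0),
               mean_ppm = numeric(0), n_candidates = integer(0),
               n_rejected = integer(0))
  rownames(res) <- NULL
  attr(res, "audit") <- if (length(audit)) do.call(rbind, audit) else NULL
  res
}

#' Deduplicate annotations to unique lipids
#'
#' Adducts, isomers and co-eluting peaks that carry the same
#' species-level annotation are grouped into one unique lipid when
#' their retention apexes co-elute within `rt_tol_s`; same-name
#' annotations at clearly distinct retention times are kept separate as
#' potential isomers when `split_isomers` is `TRUE`, or merged
#' regardless of retention time when it is `FALSE`.
#'
#' @param annotations from [annotate_features()].
#' @param rt_tol_s co-elution tolerance (s); default half the median
#'   feature RT FWHM recorded during annotation, falling back to 3 s.
#' @param split_isomers keep same-name groups at distinct retention
#'   times separate.
#' @return data.frame of unique lipids: `name`, `level`, `class`,
#'   `rt_s`, `n_features`, `n_adducts`, `adducts`, `mz`, `ccs`
#'   (of the most intense feature), `intensity` (summed), `entry_id`.
#' @export
deduplicate <- function(annotations, rt_tol_s = 3, split_isomers = TRUE) {
  if (nrow(annotations) == 0) {
    return(data.frame(name = character(0), level = character(0),
                      class = character(0), rt_s = numeric(0),
                      n_features = integer(0), n_adducts = integer(0),
                      adducts = character(0), mz = numeric(0),
                      ccs = numeric(0), intensity = numeric(0),
                      entry_id = integer(0)))
  }
  lvl_rank <- c(full = 3, partial = 2, species = 1)
  out <- list()
  for (nm in unique(annotations$species_name)) {
    grp <- annotations[annotations$species_name == nm, , drop = FALSE]
    grp <- grp[order(grp$rt_s), ]
    cl <- if (split_isomers)
      cumsum(c(TRUE, diff(grp$rt_s) > rt_tol_s)) else
        rep(1L, nrow(grp))
    for (g in split(seq_len(nrow(grp)), cl)) {
      sub <- grp[g, , drop = FALSE]
      top <- which.max(sub$intensity)
      best_lvl <- sub[which.max(lvl_rank[sub$level]), ]
      out[[length(out) + 1]] <- data.frame(
        name = best_lvl$name, level = best_lvl$level,
        species_name = nm, class = sub$class[1],
        rt_s = stats::median(sub$rt_s),
        n_features = nrow(sub),
        n_adducts = length(unique(sub$adduct)),
        adducts = paste(sort(unique(sub$adduct)), collapse = ";"),
        mz = sub$mz[top], ccs = sub$ccs[top],
        ook0 = sub$ook0[top],
        intensity = sum(sub$intensity),
        entry_id = sub$entry_id[top])
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$rt_s, res$name), ]
  rownames(res) <- NULL
  res
}
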