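## Virtual-screening layer: activity labeling at the 1 uM cutoff,
## fingerprint activity classifiers, the Muegge drug-likeness filter,
## clamp interpolation, composite Score 1-5, two-tier hit triage, and the
## gene-expression rank-similarity score.

#' Label activity records at the 1 uM threshold
#'
#' A compound is `active` iff its best (lowest) measured Ki/Kd/IC50 is
#' strictly below 1 uM; measured-but-worse or unmeasured compounds are
#' `inactive`; records already labeled `decoy` pass through unchanged.
#'
#' @param records data.frame with columns `smiles`, `measure_type`
#'   (Ki/Kd/IC50), `value_um` (numeric, NA = undetermined), and optionally
#'   `label` (pre-set `"decoy"` rows are preserved).
#' @param threshold_um Activity cutoff (default 1).
#' @return The data.frame with a `label` factor
#'   (active/inactive/decoy).
#' @export
label_activity <- function(records, threshold_um = 1) {
  stopifnot(is.data.frame(records), all(c("smiles", "value_um") %in%
                                          names(records)))
  if (any(records$value_um < 0, na.rm = TRUE)) {
    stop_digera("negative activity values are not permissible",
                class = "digera_validation_error")
  }
  prior <- if ("label" %in% names(records)) as.character(records$label)
           else rep(NA_character_, nrow(records))
  best <- vapply(split(records$value_um, records$smiles), function(v) {
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  }, numeric(1))
  best_per_row <- best[records$smiles]
  label <- ifelse(!is.na(best_per_row) & best_per_row < threshold_um,
                  "active", "inactive")
  label[!is.na(prior) & prior == "decoy"] <- "decoy"
  records$label <- factor(label, levels = c("active", "inactive", "decoy"))
  records
}

classification_metrics <- function(truth, pred, positive = "active") {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  c(accuracy = (tp + tn) / length(truth), precision = precision,
    recall = recall, f1 = f1, mcc = mcc)
}

#' Fit a fingerprint activity classifier with cross-validated reporting
#'
#' Binary classification of active vs inactive/decoy on combined
#' fingerprint blocks.  The data are split 80/20 stratified on the label,
#' the training portion is evaluated by k-fold cross-validation, and
#' accuracy, precision, recall, F1 and MCC are reported for train,
#' validation (CV) and test.
#'
#' @param fingerprints Numeric matrix (compounds x bits).
#' @param labels Factor or character; `"active"` is the positive class.
#' @param family `"rf"` (random forest), `"xgb"` (gradient boosting), or
#'   `"lgbm"` (histogram/leaf-wise gradient boosting).
#' @param n_folds Cross-validation folds on the training split (default
#'   10).
#' @param n_estimators,max_depth,learning_rate Tree settings.
#' @param seed RNG seed.
#' @return List of class `activity_classifier` with the fitted model and a
#'   `report` data.frame.
#' @export
fit_activity_classifier <- function(fingerprints, labels,
                                    family = c("rf", "xgb", "lgbm"),
                                    n_folds = 10L, n_estimators = 100L,
                                    max_depth = 6L, learning_rate = 0.3,
                                    seed = 1L) {
  family <- match.arg(family)
  stopifnot(is.matrix(fingerprints), nrow(fingerprints) == length(labels))
  y <- factor(ifelse(as.character(labels) == "active", "active", "other"),
              levels = c("active", "other"))
  if (nlevels(droplevels(y)) < 2L) {
    stop_digera("training data contain a single class",
                class = "digera_validation_error")
  }
  split <- stratified_split(as.character(y), test_fraction = 0.2,
                            seed = seed)
  min_class <- min(table(y[split$train]))
  if (n_folds > min_class) {
    stop_digera("n_folds (", n_folds, ") exceeds the minority class size (",
                min_class, ") in the training split",
                class = "digera_validation_error")
  }

  fit_one <- function(idx) {
    X <- fingerprints[idx, , drop = FALSE]
    yy <- y[idx]
    if (family == "rf") {
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      ranger::ranger(x = df, y = yy, num.trees = n_estimators,
                     probability = TRUE, seed = seed, num.threads = 1L,
                     verbose = FALSE)
    } else {
      params <- list(objective = "binary:logistic",
                     max_depth = as.integer(max_depth),
                     eta = learning_rate, nthread = 1L)
      if (family == "lgbm") {
        params$tree_method <- "hist"
        params$grow_policy <- "lossguide"
      }
      xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(X, label = as.integer(yy == "active")),
        nrounds = n_estimators, verbose = 0
      )
    }
  }
  predict_one <- function(model, X) {
    if (family == "rf") {
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      p <- stats::predict(model, data = df, num.threads = 1L)$predictions
      p[, "active"]
    } else {
      stats::predict(model, xgboost::xgb.DMatrix(X))
    }
  }
  to_label <- function(p) ifelse(p >= 0.5, "active", "other")

  # k-fold CV on the training split
  train_idx <- split$train
  folds <- with_seed(seed, {
    unsplit_order <- sample(train_idx)
    split(unsplit_order, rep_len(seq_len(n_folds), length(unsplit_order)))
  })
  cv_metrics <- t(vapply(folds, function(held) {
    fit <- fit_one(setdiff(train_idx, held))
    classification_metrics(y[held],
                           to_label(predict_one(fit,
                                                fingerprints[held, ,
                                                             drop = FALSE])))
  }, numeric(5)))

  final <- fit_one(train_idx)
  train_m <- classification_metrics(
    y[train_idx],
    to_label(predict_one(final, fingerprints[train_idx, , drop = FALSE])))
  test_m <- classification_metrics(
    y[split$test],
    to_label(predict_one(final, fingerprints[split$test, , drop = FALSE])))
  report <- rbind(
    data.frame(set = "train", t(train_m)),
    data.frame(set = "validation", t(colMeans(cv_metrics))),
    data.frame(set = "test", t(test_m))
  )
  structure(
    list(model = final, family = family, report = report,
         predict_prob = function(X) predict_one(final, X),
         split = split),
    class = "activity_classifier"
  )
}

#' @export
print.activity_classifier <- function(x, ...) {
  cat("Activity classifier [", x$family, "]\n", sep = "")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Muegge drug-likeness filter
#'
#' Eight-rule screen: molecular weight within \[200, 600\], LogP <= 6, at
#' most 6 hydrogen-bond donors, at most 12 acceptors, at most 15 rotatable
#' bonds, at most 7 aromatic rings, at least 2 heteroatoms, at least 5
#' carbon atoms.  All violated rules are reported.
#'
#' @param smiles A single SMILES string (must parse).
#' @return List of class `muegge_report`: the eight properties, `pass`,
#'   and `violated_rules`.
#' @export
muegge_filter <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  p <- mol_properties(smiles)
  if (!p$valid[1]) {
    stop_digera("cannot evaluate unparseable SMILES: ", smiles,
                class = "digera_featurization_error")
  }
  violated <- character(0)
  if (p$mw > 600) violated <- c(violated, "MW>600")
  if (p$mw < 200) violated <- c(violated, "MW<200")
  if (p$logp > 6) violated <- c(violated, "LogP>6")
  if (p$h_donors > 6) violated <- c(violated, "HBD>6")
  if (p$h_acceptors > 12) violated <- c(violated, "HBA>12")
  if (p$rot_bonds > 15) violated <- c(violated, "RotB>15")
  if (p$aromatic_rings > 7) violated <- c(violated, "AromaticRings>7")
  if (p$heteroatoms < 2) violated <- c(violated, "Heteroatoms<2")
  if (p$carbons < 5) violated <- c(violated, "Carbons<5")
  structure(
    list(smiles = smiles, mw = p$mw, logp = p$logp, h_donors = p$h_donors,
         h_acceptors = p$h_acceptors, rot_bonds = p$rot_bonds,
         aromatic_rings = p$aromatic_rings, heteroatoms = p$heteroatoms,
         carbons = p$carbons, pass = length(violated) == 0L,
         violated_rules = violated),
    class = "muegge_report"
  )
}

#' @export
print.muegge_report <- function(x, ...) {
  cat("Muegge filter:", if (x$pass) "PASS" else
    paste("FAIL (", paste(x$violated_rules, collapse = ", "), ")"), "\n")
  invisible(x)
}

#' Clamped linear interpolation to \[0, 1\]
#'
#' 0 at or below `lo`, 1 at or above `hi`, linear in between.  Used to map
#' predicted LogS (bounds -8, -4) and Caco-2 permeability (bounds -6.85,
#' -5.15) onto the common score scale.
#'
#' @param x Numeric vector.
#' @param lo,hi Interpolation bounds (`lo < hi`).
#' @return Numeric vector in \[0, 1\].
#' @export
clamp_interpolate <- function(x, lo, hi) {
  assert_scalar_number(lo); assert_scalar_number(hi)
  if (lo >= hi) {
    stop_digera("lo (", lo, ") must be below hi (", hi, ")",
                class = "digera_validation_error")
  }
  pmin(1, pmax(0, (x - lo) / (hi - lo)))
}

#' Compose the multi-objective screening scores
#'
#' Components on \[0, 1\]: `s_target` (target-specificity probability),
#' `s_ra` (synthetic accessibility), `s_sol` (clamped LogS), `s_perm`
#' (mean of the HIA probability and the clamped Caco-2 value), `s_dl`
#' (drug-likeness raw score divided by 100), `s_ge` (gene-expression rank
#' similarity).  Score 1 = `s_target`; each further score is the flat
#' arithmetic mean of one more component: Score 2 = mean(target, ra, sol),
#' Score 3 adds permeability, Score 4 adds drug-likeness, Score 5 adds the
#' gene-expression score.
#'
#' @param card Named list or one-row data.frame with the components needed
#'   for the requested level.  Raw inputs may be given instead as
#'   `logs_raw`, `caco2_raw`, `hia_prob`, `dl_raw` and are converted.
#' @param level Highest score to compose (default 5).
#' @return List of class `score_card` with components and `score1` ..
#'   `score<level>`.
#' @export
compose_scores <- function(card, level = 5L) {
  card <- as.list(card)
  if (is.null(card$s_sol) && !is.null(card$logs_raw)) {
    card$s_sol <- clamp_interpolate(card$logs_raw, -8, -4)
  }
  if (is.null(card$s_perm) && !is.null(card$caco2_raw) &&
      !is.null(card$hia_prob)) {
    card$s_perm <- mean(c(card$hia_prob,
                          clamp_interpolate(card$caco2_raw, -6.85, -5.15)))
  }
  if (is.null(card$s_dl) && !is.null(card$dl_raw)) {
    card$s_dl <- card$dl_raw / 100
  }
  needed <- list(
    c("s_target"),
    c("s_target", "s_ra", "s_sol"),
    c("s_target", "s_ra", "s_sol", "s_perm"),
    c("s_target", "s_ra", "s_sol", "s_perm", "s_dl"),
    c("s_target", "s_ra", "s_sol", "s_perm", "s_dl", "s_ge")
  )
  level <- as.integer(level)
  stopifnot(level >= 1L, level <= 5L)
  for (lv in seq_len(level)) {
    comps <- needed[[lv]]
    missing_c <- comps[vapply(comps, function(nm) is.null(card[[nm]]),
                              logical(1))]
    if (length(missing_c)) {
      stop_digera("score", lv, " needs missing component(s): ",
                  paste(missing_c, collapse = ", "),
                  class = "digera_validation_error")
    }
    vals <- unlist(card[comps])
    if (any(vals < 0 | vals > 1)) {
      stop_digera("score components must lie in [0, 1]",
                  class = "digera_validation_error")
    }
    card[[paste0("score", lv)]] <- mean(vals)
  }
  structure(card, class = "score_card")
}

#' Two-tier hit triage
#'
#' Retains candidates whose target-specificity, synthetic-accessibility,
#' solubility and permeability components clear the stringent threshold
#' (default 0.9) and whose drug-likeness and gene-expression components
#' clear the lenient threshold (default 0.5); survivors are ranked by
#' Score 5 (descending; ties by input order) and the top `top_n` returned.
#'
#' @param cards List of composed [compose_scores()] cards (level 5).
#' @param strict_threshold Threshold for s_target, s_ra, s_sol, s_perm.
#' @param lenient_threshold Threshold for s_dl, s_ge.
#' @param top_n Maximum number of hits returned (default all survivors).
#' @return data.frame of surviving cards, ranked.
#' @export
triage_hits <- function(cards, strict_threshold = 0.9,
                        lenient_threshold = 0.5, top_n = Inf) {
  stopifnot(is.list(cards))
  rows <- lapply(seq_along(cards), function(i) {
    cd <- cards[[i]]
    if (is.null(cd$score5)) {
      stop_digera("card ", i, " is not composed to score5",
                  class = "digera_validation_error")
    }
    data.frame(idx = i, smiles = cd$smiles %||% NA_character_,
               s_target = cd$s_target, s_ra = cd$s_ra, s_sol = cd$s_sol,
               s_perm = cd$s_perm, s_dl = cd$s_dl, s_ge = cd$s_ge,
               score5 = cd$score5, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  keep <- df$s_target >= strict_threshold & df$s_ra >= strict_threshold &
    df$s_sol >= strict_threshold & df$s_perm >= strict_threshold &
    df$s_dl >= lenient_threshold & df$s_ge >= lenient_threshold
  df <- df[keep, , drop = FALSE]
  df <- df[order(-df$score5, df$idx), , drop = FALSE]
  if (is.finite(top_n)) df <- utils::head(df, top_n)
  rownames(df) <- NULL
  df
}

#' Gene-expression rank-similarity score
#'
#' Spearman similarity between a predicted gene ranking and a reference
#' experimental ranking (e.g. a known inhibitor's profile), mapped to
#' \[0, 1\] via `(rho + 1) / 2` so it can enter the composite scores.
#'
#' @param pred_rank,reference_rank Rank vectors over the same gene order.
#' @return Similarity in \[0, 1\].
#' @export
gene_rank_score <- function(pred_rank, reference_rank) {
  (spearman_rank_similarity(pred_rank, reference_rank) + 1) / 2
}
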