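# Activity labeling, classifiers, Muegge filter, composite scores, triage.

test_that("activity labels follow the strict 1 uM rule", {
  rec <- data.frame(
    smiles = c("a", "b", "c", "d"),
    measure_type = c("IC50", "Ki", NA, "Kd"),
    value_um = c(0.5, 2, NA, 1.0),
    stringsAsFactors = FALSE
  )
  out <- label_activity(rec)
  expect_equal(as.character(out$label), c("active", "inactive", "inactive",
                                          "inactive"))  # boundary 1.0 uM
  dec <- data.frame(smiles = "e", measure_type = NA, value_um = NA,
                    label = "decoy", stringsAsFactors = FALSE)
  expect_equal(as.character(label_activity(dec)$label), "decoy")
  expect_error(label_activity(data.frame(smiles = "f", value_um = -1)),
               class = "digera_validation_error")
  # best-of-multiple-measurements decides
  multi <- data.frame(smiles = c("g", "g"), measure_type = c("Ki", "IC50"),
                      value_um = c(5, 0.2), stringsAsFactors = FALSE)
  expect_true(all(label_activity(multi)$label == "active"))
})

test_that("separable synthetic classes are classified perfectly", {
  gs <- gen_activity_set(120, 120, 240, separation = 0.5, seed = 3)
  for (fam in c("xgb", "lgbm")) {
    cls <- fit_activity_classifier(gs$fingerprints, gs$records$label,
                                   family = fam, n_folds = 5,
                                   n_estimators = 60, seed = 2)
    expect_equal(cls$report$f1[cls$report$set == "test"], 1.0)
  }
  cls_rf <- fit_activity_classifier(gs$fingerprints, gs$records$label,
                                    family = "rf", n_folds = 5,
                                    n_estimators = 100, seed = 2)
  expect_gte(cls_rf$report$f1[cls_rf$report$set == "test"], 0.99)
  expect_named(cls_rf$report, c("set", "accuracy", "precision", "recall",
                                "f1", "mcc"))
})

test_that("indistinguishable classes score MCC near zero", {
  gs <- gen_activity_set(500, 250, 250, separation = 0, seed = 4)
  cls <- fit_activity_classifier(gs$fingerprints, gs$records$label,
                                 family = "lgbm", n_folds = 5,
                                 n_estimators = 40, seed = 2)
  expect_lt(abs(cls$report$mcc[cls$report$set == "test"]), 0.1)
})

test_that("impossible fold counts raise a validation error", {
  gs <- gen_activity_set(8, 40, 0, separation = 1, seed = 5)
  expect_error(
    fit_activity_classifier(gs$fingerprints, gs$records$label,
                            family = "xgb", n_folds = 10, seed = 1),
    "minority", class = "digera_validation_error")
})

test_that("the Muegge filter applies all eight rules", {
  eth <- muegge_filter("CCO")
  expect_false(eth$pass)
  expect_true(all(c("MW<200", "Carbons<5", "Heteroatoms<2") %in%
                    eth$violated_rules))
  # heavy molecule beyond the 600 cap
  heavy <- muegge_filter(paste0("CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC",
                                "C(=O)OCCN"))
  expect_false(heavy$pass)
  expect_true("MW>600" %in% heavy$violated_rules)
  expect_true("LogP>6" %in% heavy$violated_rules)
  expect_error(muegge_filter("C1CC"), class = "digera_featurization_error")
})

test_that("Muegge report matches an independent property panel", {
  # dodecanoic acid C12H24O2: the panel is recomputed here from the
  # formula-level facts (12 carbons, 2 oxygens) plus the property layer
  rep_la <- muegge_filter("CCCCCCCCCCCC(=O)O")
  expect_equal(rep_la$carbons, 12)
  expect_equal(rep_la$heteroatoms, 2)
  expect_equal(rep_la$mw, 200.32, tolerance = 0.01)
  expect_equal(rep_la$h_donors, 1)
  expect_equal(rep_la$rot_bonds, 10)
  expect_equal(rep_la$aromatic_rings, 0)
  # MW 200.32 > 200 and every other rule satisfied -> pass
  expect_true(rep_la$pass)
  expect_equal(rep_la$pass, length(rep_la$violated_rules) == 0)
})

test_that("Muegge decisions are invariant to kekulization variants", {
  a <- muegge_filter("c1ccc2ccccc2c1CCCCCCCN")
  b <- muegge_filter("C1=CC=C2C=CC=CC2=C1CCCCCCCN")
  expect_equal(a$pass, b$pass)
  expect_equal(a$aromatic_rings, b$aromatic_rings)
  expect_equal(a$mw, b$mw, tolerance = 1e-6)
})

test_that("clamp interpolation obeys its endpoint contracts", {
  # solubility bounds
  expect_equal(clamp_interpolate(-8.5, -8, -4), 0)
  expect_equal(clamp_interpolate(-8, -8, -4), 0)
  expect_equal(clamp_interpolate(-4, -8, -4), 1)
  expect_equal(clamp_interpolate(-6, -8, -4), 0.5)
  # permeability bounds
  expect_equal(clamp_interpolate(-5.15, -6.85, -5.15), 1)
  expect_equal(clamp_interpolate(-6.85, -6.85, -5.15), 0)
  expect_equal(clamp_interpolate(-7.5, -6.85, -5.15), 0)
  expect_error(clamp_interpolate(0, 2, 1), class = "digera_validation_error")
  # non-decreasing, continuous, idempotent on [0,1] with unit bounds
  x <- seq(-10, 2, by = 0.01)
  y <- clamp_interpolate(x, -8, -4)
  expect_true(all(diff(y) >= 0))
  u <- seq(0, 1, by = 0.05)
  expect_equal(clamp_interpolate(u, 0, 1), u)
})

test_that("score composition is flat averaging with documented conversions", {
  all_one <- compose_scores(list(s_target = 1, s_ra = 1, s_sol = 1,
                                 s_perm = 1, s_dl = 1, s_ge = 1))
  for (lv in 1:5) expect_equal(all_one[[paste0("score", lv)]], 1)
  two <- compose_scores(list(s_target = 0.9, s_ra = 0.6, s_sol = 0.9),
                        level = 2)
  expect_equal(two$score2, 0.8)
  conv <- compose_scores(list(s_target = 0.5, s_ra = 0.5, logs_raw = -6,
                              caco2_raw = -5.15, hia_prob = 0.6,
                              dl_raw = 80, s_ge = 0.5))
  expect_equal(conv$s_sol, 0.5)
  expect_equal(conv$s_perm, 0.8)   # mean(0.6, 1)
  expect_equal(conv$s_dl, 0.8)     # raw 80 / 100
  expect_error(compose_scores(list(s_target = 1), level = 2), "s_ra",
               class = "digera_validation_error")
})

test_that("composed scores are monotone in every component", {
  set.seed(12)
  base <- list(s_target = 0.5, s_ra = 0.5, s_sol = 0.5, s_perm = 0.5,
               s_dl = 0.5, s_ge = 0.5)
  ref <- compose_scores(base)
  for (comp in names(base)) {
    up <- base
    up[[comp]] <- 0.9
    out <- compose_scores(up)
    for (lv in 1:5) {
      expect_gte(out[[paste0("score", lv)]], ref[[paste0("score", lv)]])
    }
  }
})

test_that("two-tier triage filters and ranks like a sort oracle", {
  keep <- compose_scores(list(smiles = "keep", s_target = 0.95, s_ra = 0.95,
                              s_sol = 0.95, s_perm = 0.95, s_dl = 0.6,
                              s_ge = 0.55))
  drop_sol <- compose_scores(list(smiles = "drop", s_target = 0.95,
                                  s_ra = 0.95, s_sol = 0.85, s_perm = 0.95,
                                  s_dl = 0.95, s_ge = 0.95))
  hits <- triage_hits(list(keep, drop_sol))
  expect_equal(hits$smiles, "keep")

  set.seed(8)
  cards <- lapply(1:100, function(i) {
    compose_scores(list(smiles = paste0("m", i),
                        s_target = runif(1, 0.5, 1), s_ra = runif(1, 0.5, 1),
                        s_sol = runif(1, 0.5, 1), s_perm = runif(1, 0.5, 1),
                        s_dl = runif(1), s_ge = runif(1)))
  })
  hits <- triage_hits(cards, top_n = 10)
  # sort oracle over survivors
  df <- do.call(rbind, lapply(cards, function(cd) {
    data.frame(smiles = cd$smiles, s_target = cd$s_target, s_ra = cd$s_ra,
               s_sol = cd$s_sol, s_perm = cd$s_perm, s_dl = cd$s_dl,
               s_ge = cd$s_ge, score5 = cd$score5)
  }))
  surv <- df[df$s_target >= 0.9 & df$s_ra >= 0.9 & df$s_sol >= 0.9 &
               df$s_perm >= 0.9 & df$s_dl >= 0.5 & df$s_ge >= 0.5, ]
  surv <- surv[order(-surv$score5), ]
  expect_equal(hits$smiles, head(surv$smiles, 10))
})

test_that("gene rank similarity maps Spearman onto [0, 1]", {
  r <- random_rank_vector(100, seed = 3)
  expect_equal(gene_rank_score(r, r), 1)
  expect_equal(gene_rank_score(101 - r, r), 0)
  set.seed(9)
  draws <- replicate(1000, {
    gene_rank_score(sample(15), sample(15))
  })
  expect_equal(mean(draws), 0.5, tolerance = 0.02)
  expect_error(gene_rank_score(r, r[1:10]),
               class = "digera_validation_error")
})
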