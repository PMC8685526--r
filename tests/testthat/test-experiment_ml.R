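test_that("the design grid is the exact Cartesian product", {
  profs <- synthetic_profiles(127)
  des <- build_design(profs)
  expect_equal(nrow(des), 127 * 2 * 4)
  one <- build_design(profs[1, ], sizes = "normal", conditions = "basal")
  expect_equal(nrow(one), 1)
  # basal rows carry the raw profile multipliers
  basal <- des[des$condition == "basal", ]
  expect_equal(basal$m_gNa, rep(profs$m_gNa, each = 2))
  # drug rows fold the conductance factors onto the mapped channels
  ver <- des[des$condition == "verapamil" & des$tissue == "normal", ]
  expect_equal(ver$m_gCaL, profs$m_gCaL / 6, tolerance = 1e-12)
  expect_equal(ver$m_gK1, profs$m_gK1)
  dup <- rbind(profs[1, ], profs[1, ])
  expect_error(build_design(dup), "duplicate")
})

test_that("the forest recovers a single-threshold rule", {
  tab <- gen_outcome_table(1000, generator_rule(list(
    afpop:::rule_clause(list("m_gK1", 1.09, ">")))), seed = 21)
  clf <- train_classifier(tab, seed = 2)
  expect_gte(clf$holdout_accuracy, 0.98)
  imp <- sort(clf$importances, decreasing = TRUE)
  expect_equal(names(imp)[1], "m_gK1")
  expect_gte(imp[1], 2 * imp[2])
  expect_length(clf$cv_scores, 5)
  expect_true(all(clf$cv_scores >= 0 & clf$cv_scores <= 1))
  expect_equal(sum(clf$importances), 1, tolerance = 1e-9)
})

test_that("label-independent features give only majority-class accuracy", {
  set.seed(9)
  tab <- gen_outcome_table(800, generator_rule(list(
    afpop:::rule_clause(list("m_gK1", 1.25, ">")))), seed = 31)
  tab$label <- sample(tab$label)   # break the feature-label link
  clf <- train_classifier(tab, seed = 4)
  p_maj <- max(table(tab$label)) / nrow(tab)
  sigma <- sqrt(p_maj * (1 - p_maj) / length(clf$forest$y))
  expect_lt(abs(clf$holdout_accuracy - p_maj), 5 * sigma + 0.02)
})

test_that("splits and CV are seed-deterministic", {
  tab <- gen_outcome_table(500, generator_rule(list(
    afpop:::rule_clause(list("m_gCaL", 1.3, ">"))), label_noise = 0.05),
    seed = 13)
  a <- train_classifier(tab, seed = 11)
  b <- train_classifier(tab, seed = 11)
  expect_identical(a$train_idx, b$train_idx)
  expect_identical(a$cv_scores, b$cv_scores)
  expect_identical(a$holdout_accuracy, b$holdout_accuracy)
  expect_error(train_classifier(within(tab, label <- factor("induced",
    levels = c("non_inducible", "induced")))), "degenerate")
})

test_that("predictions return labels with coherent probabilities", {
  tab <- gen_outcome_table(600, generator_rule(list(
    afpop:::rule_clause(list("m_gNa", 1.2, ">")))), seed = 17)
  clf <- train_classifier(tab, seed = 5)
  pr <- predict_inducibility(clf, tab[1:20, ])
  expect_true(all(pr$p_induced + pr$p_non_inducible == 1))
  deep <- tab[tab$m_gNa > 1.6, ][1, ]
  prd <- predict_inducibility(clf, deep)
  expect_equal(prd$label, "induced")
  expect_gt(prd$p_induced, 0.9)
  expect_error(predict_inducibility(clf, tab[, 1:3]), "schema")
})

test_that("the interpretability tree exposes thresholds and paths", {
  # separable single feature: one split at ~1.09
  tab <- gen_outcome_table(2000, generator_rule(list(
    afpop:::rule_clause(list("m_gK1", 1.09, ">")))), seed = 23)
  dp <- extract_decision_paths(tab)
  expect_equal(dp$root$feature, "m_gK1")
  expect_equal(dp$root$threshold, 1.09, tolerance = 0.05)
  expect_true(all(vapply(dp$paths, function(p) nrow(p$conditions), 0) >= 1))
  # depth bound respected
  expect_lte(max(vapply(dp$paths, function(p) nrow(p$conditions), 0)), 7)
  # row_path routes a row to a consistent leaf
  row <- tab[5, ]
  p <- row_path(dp, row)
  expect_equal(p$leaf_label, as.character(row$label))
  # sunburst export is nested JSON with the root variable on ring 1
  tmp <- tempfile(fileext = ".json")
  write_sunburst(dp, tmp)
  sb <- jsonlite::read_json(tmp)
  expect_equal(sb$name, "m_gK1")
  expect_named(sb$children, c("left", "right"))
})

test_that("both induced-AF archetypes are recovered from the preset rule", {
  tab <- gen_outcome_table(2000, "archetypes", seed = 7)
  dp <- extract_decision_paths(tab)
  proto1 <- data.frame(m_gNa = 1.8, m_iNaK = 1, m_gK1 = 1.6, m_gCaL = 1,
                       m_gKur = 0.7, m_iKCa = 1, m_Na_o = 1, m_K_o = 1.8,
                       m_D = 0.7, tissue_area = 16)
  proto2 <- data.frame(m_gNa = 1.8, m_iNaK = 1.8, m_gK1 = 0.7, m_gCaL = 1.8,
                       m_gKur = 1, m_iKCa = 1.8, m_Na_o = 1, m_K_o = 0.7,
                       m_D = 1, tissue_area = 16)
  p1 <- row_path(dp, proto1)
  p2 <- row_path(dp, proto2)
  expect_equal(p1$leaf_label, "induced")
  expect_equal(p2$leaf_label, "induced")
  # each archetype path carries the gK1 condition in its own direction
  g1 <- p1$conditions[p1$conditions$feature == "m_gK1", ]
  g2 <- p2$conditions[p2$conditions$feature == "m_gK1", ]
  expect_true(any(g1$direction == ">="))
  expect_true(any(g2$direction == "<"))
})
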