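test_that("ground-truth labeling follows the reference rule exactly", {
  ref <- data.frame(pathway_id = c("p1", "p2", "p3"),
                    adjusted_p = c(0.04, 0.06, 0.06),
                    overlap = c(0L, 3L, 0L))
  lab <- label_ground_truth(ref)
  expect_equal(lab$label, c("true", "false", "excluded"))
  dup <- rbind(ref, ref[1, ])
  expect_error(label_ground_truth(dup), "duplicate")
  bad <- ref; bad$adjusted_p[1] <- 0
  expect_error(label_ground_truth(bad), "\\(0,1\\]")
})

test_that("roc_auc matches brute-force pair counting and tie conventions", {
  labels <- label_ground_truth(data.frame(
    pathway_id = sprintf("p%d", 1:8),
    adjusted_p = c(0.01, 0.02, 0.03, 0.04, 0.2, 0.3, 0.2, 0.9),
    overlap = rep(1L, 8)))
  # hand-set tool p-values with a tie across classes
  p <- c(p1 = 0.001, p2 = 0.01, p3 = 0.2, p4 = 0.05,
         p5 = 0.2, p6 = 0.5, p7 = 0.03, p8 = 0.9)
  roc <- roc_auc(p, labels)
  truth <- labels$label == "true"
  expect_equal(roc$auc, auc_oracle(-p[labels$pathway_id], truth))
  # curve anchored at (0,0) and (1,1), monotone
  expect_equal(unlist(roc$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc$points[nrow(roc$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$points$fpr) >= 0) && all(diff(roc$points$tpr) >= 0))

  # perfect separation and all-tied scores
  sep <- setNames(c(0.01, 0.02, 0.5, 0.6), sprintf("p%d", 1:4))
  lab2 <- label_ground_truth(data.frame(pathway_id = sprintf("p%d", 1:4),
                                        adjusted_p = c(0.01, 0.02, 0.5, 0.6),
                                        overlap = 1L))
  expect_equal(roc_auc(sep, lab2)$auc, 1.0)
  expect_equal(roc_auc(setNames(rep(0.5, 4), sprintf("p%d", 1:4)), lab2)$auc, 0.5)
  expect_error(roc_auc(sep, lab2[1:2, ]), "at least one")
})

test_that("roc_auc complement/monotone-transform invariants; missing pathways score worst", {
  set.seed(61)
  labels <- label_ground_truth(data.frame(
    pathway_id = sprintf("p%02d", 1:30),
    adjusted_p = c(runif(10, 0.001, 0.05), runif(20, 0.051, 1)),
    overlap = 1L))
  p <- setNames(runif(30, 0.0011, 0.999), sprintf("p%02d", 1:30))
  auc <- roc_auc(p, labels)$auc
  expect_equal(roc_auc(setNames(1 - p + 0.0005, names(p)), labels)$auc,
               1 - auc, tolerance = 1e-12)
  expect_equal(roc_auc(setNames(p^3, names(p)), labels)$auc, auc)
  # dropping a true pathway from the tool's results: it gets p = 1
  p_miss <- p[names(p) != "p01"]
  manual <- p; manual["p01"] <- 1
  expect_equal(roc_auc(p_miss, labels)$auc, roc_auc(manual, labels)$auc)
})

test_that("ttest_curve returns nine p-values with the stated conventions", {
  const <- ttest_curve(rep(2.5, 40))
  expect_equal(const$fractions, seq(10L, 90L, 10L))
  expect_length(const$p_values, 9L)
  expect_equal(const$p_values, rep(1, 9))
  expect_equal(const$average_p, 1)

  lin <- ttest_curve(seq(10, 0, length.out = 100))
  expect_lt(lin$average_p, 0.01)

  expect_error(ttest_curve(1:9), "at least 10")
  # one-sided variant is at most the two-sided for top-heavy scores
  one <- ttest_curve(seq(10, 0, length.out = 100), alternative = "greater")
  expect_true(all(one$p_values <= lin$p_values + 1e-12))
})

test_that("ttest_curve averages near 0.5 on exchangeable scores, lower when rank-associated", {
  set.seed(62)
  base <- rnorm(100)
  perms <- replicate(200, ttest_curve(sample(base))$average_p)
  expect_gt(mean(perms), 0.35)
  expect_lt(mean(perms), 0.65)
  # paired comparison: an associated sequence beats its own permutations
  set.seed(63)
  wins <- 0L
  for (i in 1:50) {
    assoc <- sort(rnorm(60, sd = 1), decreasing = TRUE) + rnorm(60, sd = 0.5)
    p_assoc <- ttest_curve(assoc)$average_p
    p_perm <- ttest_curve(sample(assoc))$average_p
    wins <- wins + (p_assoc < p_perm)
  }
  expect_gt(wins, 40L)
})

test_that("synthetic ground truth yields the designed AUC separation", {
  b <- generate_fixture(fixture_spec(seed = 64))
  labels <- label_ground_truth(b$truth)
  expect_setequal(labels$pathway_id[labels$label == "true"],
                  b$manifest$true_pathways)
  # population-level property of the default effect (implied AUC ~0.96):
  # a single 10-vs-40 realization has ~0.05 sampling noise, so assert on
  # the mean across seeds
  aucs <- vapply(64:68, function(s) {
    bs <- generate_fixture(fixture_spec(seed = s))
    roc_auc(bs$tool_scores, label_ground_truth(bs$truth))$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.9)
})
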