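# planted activity fixture: pathways x samples with a shifted first pathway
planted_activity <- function(n_path = 12, n_samples = 60, delta = 2, seed = 81) {
  set.seed(seed)
  act <- matrix(rnorm(n_path * n_samples), n_path, n_samples,
                dimnames = list(sprintf("P%02d", seq_len(n_path)),
                                sprintf("s%02d", seq_len(n_samples))))
  poor <- rep(c(FALSE, TRUE), each = n_samples / 2)
  act[1, poor] <- act[1, poor] + delta
  list(act = act, groups = toy_groups(colnames(act), poor))
}

test_that("AUC equals the Mann-Whitney rank statistic", {
  set.seed(82)
  scores <- rnorm(50)
  pos <- rbinom(50, 1, 0.4) == 1
  a <- auc_score(scores, pos)
  # rank-sum oracle via wilcox.test
  w <- wilcox.test(scores[pos], scores[!pos], exact = FALSE)$statistic
  expect_equal(a, unname(w) / (sum(pos) * sum(!pos)), tolerance = 1e-10)
  skip_if_not_installed("pROC")
  pr <- suppressMessages(pROC::auc(pROC::roc(pos, scores, direction = "<",
                                             quiet = TRUE)))
  expect_equal(a, as.numeric(pr), tolerance = 1e-10)
})

test_that("t-test ranking puts a planted pathway first and flat ones last", {
  pa <- planted_activity()
  rk <- rank_by_ttest(pa$act, pa$groups)
  expect_identical(rk$pathway_id[1], "P01")
  expect_identical(attr(rk, "method"), "ttest")
  expect_identical(rk$rank, seq_len(nrow(pa$act)))

  # a pathway identical in both groups lands last with p = 1
  act <- pa$act
  act["P12", ] <- rep(c(1, 2, 3), 20)
  rk2 <- rank_by_ttest(act, pa$groups)
  expect_identical(rk2$pathway_id[nrow(act)], "P12")
  expect_equal(rk2$score[nrow(act)], 1)

  # ranking content is invariant to pathway input order
  rk3 <- rank_by_ttest(pa$act[sample(nrow(pa$act)), ], pa$groups)
  expect_identical(rk3$pathway_id, rk$pathway_id)
})

test_that("greedy selection keeps informative features and honours max_n", {
  pa <- planted_activity(delta = 4)
  rk <- rank_by_ttest(pa$act, pa$groups)
  sel <- greedy_select(rk, pa$act, pa$groups, max_n = 5, seed = 83)
  expect_identical(sel[1], "P01")
  sel1 <- greedy_select(rk, pa$act, pa$groups, max_n = 1, seed = 83)
  expect_identical(sel1, "P01")

  # a pure-noise feature cannot displace a perfectly separating one
  set.seed(84)
  act <- rbind(P_good = c(rnorm(30, -3), rnorm(30, 3)),
               P_noise = rnorm(60))
  colnames(act) <- sprintf("s%02d", 1:60)
  g <- toy_groups(colnames(act), rep(c(FALSE, TRUE), each = 30))
  rk2 <- rank_by_ttest(act, g)
  sel2 <- greedy_select(rk2, act, g, max_n = 2, seed = 85)
  expect_identical(sel2, "P_good")
})

test_that("cross-validation is calibrated, separable-aware and deterministic", {
  # null: labels independent of all features; averaged over dataset
  # realisations since any single finite dataset carries spurious
  # feature-label correlation that legitimately lifts its own CV AUC
  set.seed(87)
  null_aucs <- vapply(1:3, function(i) {
    act <- matrix(rnorm(8 * 150), 8, 150,
                  dimnames = list(paste0("P", 1:8), sprintf("s%03d", 1:150)))
    g <- toy_groups(colnames(act), rbinom(150, 1, 0.5) == 1)
    cross_validate(act, g, repeats = 2, folds = 5, max_n = 3,
                   seed = i)$summary$auc_mean
  }, numeric(1))
  expect_lt(abs(mean(null_aucs) - 0.5), 0.1)

  set.seed(86)
  act <- matrix(rnorm(8 * 80), 8, 80,
                dimnames = list(paste0("P", 1:8), sprintf("s%02d", 1:80)))
  g <- toy_groups(colnames(act), rep(c(FALSE, TRUE), 40))
  cv <- cross_validate(act, g, repeats = 3, folds = 5, max_n = 3, seed = 87)
  expect_equal(nrow(cv$metrics), 15)
  expect_length(cv$feature_sets, 15)

  # perfectly separable data
  pa <- planted_activity(delta = 8)
  cv2 <- cross_validate(pa$act, pa$groups, repeats = 2, folds = 5,
                        max_n = 3, seed = 88)
  expect_gt(cv2$summary$auc_mean, 0.95)
  expect_gt(cv2$summary$accuracy_mean, 0.9)

  # determinism
  cv3 <- cross_validate(pa$act, pa$groups, repeats = 2, folds = 5,
                        max_n = 3, seed = 88)
  expect_identical(cv2$metrics, cv3$metrics)
  expect_identical(cv2$feature_sets, cv3$feature_sets)

  expect_true(all(cv$metrics$auc >= 0 & cv$metrics$auc <= 1))
  expect_true(all(cv$metrics$accuracy >= 0 & cv$metrics$accuracy <= 1))
})

test_that("feature consolidation applies the strict more-than-3 rule", {
  sets <- c(replicate(10, c("A", "B"), simplify = FALSE),
            replicate(3, "C", simplify = FALSE),
            replicate(4, "D", simplify = FALSE),
            replicate(33, character(0), simplify = FALSE))
  out <- consolidate_features(sets)
  expect_setequal(out$pathway_id, c("A", "B", "D"))
  expect_equal(out$count[out$pathway_id == "A"], 10)
  expect_equal(unique(out$n_sets), 50)
  expect_false("C" %in% out$pathway_id) # exactly 3 -> dropped

  # monotone: raising min_count never adds features
  for (k in c(1, 4, 6, 11)) {
    expect_true(all(consolidate_features(sets, k)$pathway_id %in%
                      consolidate_features(sets, k - 1)$pathway_id |
                      k == 1))
  }
})

test_that("mean/median baselines summarise significant member z-scores", {
  genes <- c("A", "B", "C")
  ez <- toy_omics(rbind(c(1, 3), c(5, 7), c(0, 0)), "expression",
                  kind = "zscored", genes = genes, samples = c("s1", "s2"))
  mz <- toy_omics(rbind(c(2, 2), c(4, 4), c(6, 6)), "methylation",
                  kind = "zscored", genes = genes, samples = c("s1", "s2"))
  st <- data.frame(gene = rep(genes, 2),
                   layer = rep(c("expression", "methylation"), each = 3),
                   p_value = c(0.01, 0.02, 0.9, 0.9, 0.9, 0.01),
                   effect = 1, test = "x")
  pdb <- list(PW = c("A", "B", "C"), PW1 = "A")
  bm <- baseline_activity(pdb, st, ez, mz, "mean")
  # members: A_e, B_e, C_m -> column means of rows (1,3), (5,7), (6,6)
  expect_equal(unname(bm["PW", ]), c(mean(c(1, 5, 6)), mean(c(3, 7, 6))))
  expect_equal(unname(bm["PW1", ]), c(1, 3)) # single member = its z values
  bmed <- baseline_activity(pdb, st, ez, mz, "median")
  expect_equal(unname(bmed["PW", ]), c(5, 6))

  # loop oracle on a randomised instance
  set.seed(89)
  st$p_value <- runif(6)
  bm2 <- baseline_activity(pdb, st, ez, mz, "mean", alpha = 0.6)
  sig <- st[st$p_value < 0.6, ]
  rows <- rbind(unclass(ez)[sig$gene[sig$layer == "expression"], , drop = FALSE],
                unclass(mz)[sig$gene[sig$layer == "methylation"], , drop = FALSE])
  expect_equal(unname(bm2["PW", ]), unname(colMeans(rows)))
})

test_that("profile concatenation suffixes ids and aligns samples", {
  a <- matrix(1:6, 2, 3, dimnames = list(c("P1", "P2"), c("s1", "s2", "s3")))
  b <- matrix(7:15, 3, 3, dimnames = list(c("P1", "P3", "P4"),
                                          c("s3", "s1", "s2")))
  cc <- drw_concat(a, b)
  expect_equal(nrow(cc), 5)
  expect_false(anyDuplicated(rownames(cc)) > 0)
  expect_equal(unname(cc["P1_meth", "s3"]), 7) # aligned by sample id
  b_bad <- b[, 1:2]
  expect_error(drw_concat(a, b_bad), "sample sets differ")
})

test_that("Simpson coefficient equals its set-theoretic definition", {
  expect_equal(simpson_coefficient(c("a", "b", "c"), c("b", "c", "d", "e")), 2 / 3)
  expect_equal(simpson_coefficient(c("a", "b"), c("a", "b", "c")), 1)
  expect_equal(simpson_coefficient("a", "b"), 0)
  expect_equal(simpson_coefficient(character(0), "a"), 0)
  m <- simpson_matrix(list(A = c("x", "y")), list(B = "x", C = "z"))
  expect_equal(unname(m), matrix(c(1, 0), 1, 2))
})
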