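test_that("scale_activities centers and scales rows with population sd", {
  A <- rbind(a = c(1, 3), b = c(2, 2))
  expect_warning(S <- scale_activities(A), "constant")
  expect_equal(S["a", ], c(-1, 1))
  expect_equal(S["b", ], c(0, 0))
  set.seed(1)
  A2 <- matrix(rnorm(50), 5, 10,
               dimnames = list(paste0("r", 1:5), paste0("s", 1:10)))
  S2 <- scale_activities(A2)
  expect_equal(scale_activities(S2), S2, tolerance = 1e-12)  # idempotent
  expect_equal(unname(rowMeans(S2)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(rowMeans(S2^2)), rep(1, 5), tolerance = 1e-12)
})

test_that("rank-sum exact path reproduces the hand enumeration", {
  r <- rank_sum_test(c(3, 4, 5), c(1, 2), "greater")
  expect_equal(r$method, "exact")
  expect_equal(r$statistic, 12)
  expect_equal(r$p_value, 1 / 10)  # only the observed split of C(5,2) = 10
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_gte(same$p_value, 0.5)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum exact path equals full enumeration for all small splits", {
  set.seed(42)
  for (rep in 1:25) {
    N <- sample(4:10, 1)
    nx <- sample(1:(N - 1), 1)
    vals <- sample(1:5, N, replace = TRUE)  # heavy ties on purpose
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    for (alt in c("greater", "less")) {
      expect_equal(rank_sum_test(x, y, alt)$p_value, wilcox_enum(x, y, alt))
    }
  }
})

test_that("normal approximation agrees with enumeration and wilcox.test", {
  set.seed(7)
  for (rep in 1:20) {
    vals <- rnorm(12)
    x <- vals[1:6]; y <- vals[7:12]
    p_enum <- wilcox_enum(x, y, "greater")
    p_norm <- rank_sum_test(x, y, "greater", exact_max = 0)$p_value
    expect_lt(abs(p_enum - p_norm), 0.02)
  }
  # tie-corrected continuity-corrected normal path matches stats::wilcox.test
  set.seed(8)
  x <- rnorm(25); y <- rnorm(30, 0.3)
  ours <- rank_sum_test(x, y, "greater")$p_value
  ref <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("BH adjustment equals the reference step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(99)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_reference(p), tolerance = 1e-12)
  }
})

test_that("mp_differential matches the exhaustive Wilcoxon toy and flags nulls", {
  A <- matrix(c(5, 4, 3, 1, 2), 1, 5,
              dimnames = list("f1", paste0("s", 1:5)))
  labels <- data.frame(spot_id = paste0("s", 1:5),
                       mp_label = c("in", "in", "out", "out", "out"))
  res <- mp_differential(A, labels, "tf", "x", min_spots = 2)
  got <- res[res$mp_label == "in", ]
  expect_equal(got$p_value, wilcox_enum(c(5, 4), c(3, 1, 2), "greater"))
  expect_equal(got$mean_diff, mean(c(5, 4)) - mean(c(3, 1, 2)))
  # an identically-zero feature has zero mean difference and p >= 0.5
  A0 <- rbind(A, f0 = 0)
  res0 <- mp_differential(A0, labels, "tf", "x", min_spots = 2)
  z <- res0[res0$feature_id == "f0" & res0$mp_label == "in", ]
  expect_equal(z$mean_diff, 0)
  expect_gte(z$p_value, 0.5)
  expect_true(all(res0$adj_p >= res0$p_value))
})

test_that("mp_differential skips tiny metaprograms with a warning", {
  set.seed(3)
  A <- matrix(rnorm(20), 2, 10,
              dimnames = list(c("f1", "f2"), paste0("s", 1:10)))
  labels <- data.frame(spot_id = paste0("s", 1:10),
                       mp_label = c(rep("big", 8), "tiny", "tiny"))
  expect_warning(res <- mp_differential(A, labels, "tf"), "tiny")
  expect_false("tiny" %in% res$mp_label)
})

test_that("planted metaprogram shift attains the family's smallest adjusted p", {
  hits <- 0
  for (seed in 1:10) {
    s <- sim_sample(n_rows = 12, n_cols = 12, n_genes = 60, n_regulators = 6,
                    sd_fraction = 0, n_programs = 3,
                    shift = list(mp = "MP1", regulator = "reg02", delta = 1),
                    seed = seed)
    res <- mp_differential(scale_activities(s$truth$A), s$labels, "tf")
    top <- res[which.min(res$adj_p), ]
    if (top$mp_label == "MP1" && top$feature_id == "reg02") hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("consensus_select counts qualifying samples and ranks by mean difference", {
  mk <- function(sid, feat, diff, p) {
    data.frame(sample_id = sid, mp_label = "MP1", feature_id = feat,
               feature_kind = "tf", mean_diff = diff, statistic = 0,
               p_value = p, adj_p = p, stringsAsFactors = FALSE)
  }
  res <- rbind(mk("s1", "fA", 0.9, 1e-5), mk("s2", "fA", 0.8, 1e-5),
               mk("s3", "fA", 0.1, 0.5),
               mk("s1", "fB", 0.5, 1e-5), mk("s2", "fB", 0.4, 0.5),
               mk("s3", "fB", 0.2, 0.5))
  # fA qualifies in 2 samples, fB in 1
  c2 <- consensus_select(res, 0.001, 0.3, min_samples = 2, top_k = 5)
  expect_equal(c2$feature_id, "fA")
  c3 <- consensus_select(res, 0.001, 0.3, min_samples = 3, top_k = 5)
  expect_equal(nrow(c3), 0)
  expect_error(consensus_select(res, min_samples = 4), "exceeds")
  # positive_only drops qualifiers with negative mean difference
  resn <- rbind(mk("s1", "fC", -0.9, 1e-5), mk("s2", "fC", -0.8, 1e-5))
  expect_equal(nrow(consensus_select(resn, 0.001, 0.3, 2, 5,
                                     positive_only = TRUE)), 0)
  expect_equal(consensus_select(resn, 0.001, 0.3, 2, 5)$direction, "negative")
})

test_that("consensus_select is monotone in its thresholds", {
  set.seed(17)
  res <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(sample_id = paste0("s", i), mp_label = "MP1",
               feature_id = paste0("f", 1:20), feature_kind = "tf",
               mean_diff = rnorm(20, 0.3, 0.4), statistic = 0,
               p_value = runif(20, 0, 0.01), adj_p = runif(20, 0, 0.01),
               stringsAsFactors = FALSE)
  }))
  base <- consensus_select(res, 0.005, 0.3, 3, 20)
  stricter_p <- consensus_select(res, 0.001, 0.3, 3, 20)
  stricter_d <- consensus_select(res, 0.005, 0.5, 3, 20)
  stricter_n <- consensus_select(res, 0.005, 0.3, 5, 20)
  for (s in list(stricter_p, stricter_d, stricter_n)) {
    expect_true(all(s$feature_id %in% base$feature_id))
  }
})

test_that("drug scores are target means, order-invariant, with coverage report", {
  m <- toy_counts(list(c(2, 4, 6), c(1, 3, 5)), gene_ids = c("g1", "g2", "g3"))
  e <- structure(list(values = m, layer = "sqrt"), class = "expr_mat")
  map <- data.frame(drug_id = c("d1", "d2", "d2", "d3"),
                    drug_name = c("mono", "duo", "duo", "ghost"),
                    target_gene = c("g1", "g1", "g2", "gX"),
                    stringsAsFactors = FALSE)
  expect_warning(sc <- drug_scores(e, map), "no target")
  expect_identical(sc[, "d1"], m[, "g1"])        # single target: bit-identical
  expect_equal(sc["s1", "d2"], 3)                # mean(2, 4)
  expect_false("d3" %in% colnames(sc))
  cov <- attr(sc, "coverage")
  expect_equal(cov$n_present[cov$drug_id == "d3"], 0)
  map_rev <- map[rev(seq_len(nrow(map))), ]
  expect_equal(suppressWarnings(drug_scores(e, map_rev))[, colnames(sc)], sc,
               ignore_attr = TRUE)
  # brute-force per-spot oracle on a random instance
  set.seed(12)
  M <- matrix(runif(80), 8, 10,
              dimnames = list(paste0("s", 1:8), paste0("g", 1:10)))
  eM <- structure(list(values = M, layer = "sqrt"), class = "expr_mat")
  mapM <- data.frame(drug_id = rep(paste0("d", 1:4), each = 3),
                     drug_name = "x",
                     target_gene = paste0("g", sample(1:10, 12, replace = TRUE)),
                     stringsAsFactors = FALSE)
  scM <- drug_scores(eM, mapM)
  for (d in colnames(scM)) {
    tg <- unique(mapM$target_gene[mapM$drug_id == d])
    for (s in rownames(M)) {
      expect_equal(scM[s, d], mean(M[s, tg]), tolerance = 1e-12)
    }
  }
  expect_error(drug_scores(eM, mapM[0, ]), "empty")
})

test_that("regulator-drug correlations retain by the any-sample rule", {
  set.seed(5)
  n <- 30
  act <- matrix(rnorm(2 * n), 2, n,
                dimnames = list(c("r1", "r2"), paste0("s", 1:n)))
  sc <- matrix(rnorm(n * 2), n, 2,
               dimnames = list(paste0("s", 1:n), c("d1", "d2")))
  sc[, 1] <- act["r1", ]  # perfect dependence -> rho = 1
  tab <- regulator_drug_correlation(act, sc, retain_abs_rho = 0.3)
  expect_equal(tab$rho[tab$regulator == "r1" & tab$drug == "d1"], 1)
  expect_true(tab$retained[tab$regulator == "r1" & tab$drug == "d1"])
  # a pair weak in every sample is dropped
  two <- regulator_drug_correlation(
    list(a = act, b = act),
    list(a = sc, b = sc), retain_abs_rho = 0.3)
  weak <- two[two$regulator == "r2" & two$drug == "d2", ]
  expect_equal(weak$retained, rep(all(abs(weak$rho) >= 0.3), 2))
})

test_that("metaprogram proportions sum to one per sample", {
  lab <- data.frame(sample_id = c(rep("s1", 4), rep("s2", 2)),
                    mp_label = c("a", "a", "b", "c", "a", "a"))
  pr <- mp_proportions(lab)
  expect_equal(pr["s1", ], c(a = 0.5, b = 0.25, c = 0.25))
  expect_equal(pr["s2", ], c(a = 1, b = 0, c = 0))
  expect_equal(unname(rowSums(pr)), c(1, 1))
  # permutation invariance
  pr2 <- mp_proportions(lab[sample(1:6), ])
  expect_equal(pr2, pr)
})
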