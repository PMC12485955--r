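test_that("spearman_rho handles monotone, reversed, tied and constant input", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(as.numeric(spearman_rho(x, x)), 1)
  expect_equal(as.numeric(spearman_rho(sort(x), rev(sort(x)))), -1)
  got <- spearman_rho(c(1, 2, 2, 4), c(10, 20, 30, 40))
  expect_equal(as.numeric(got), spearman_brute(c(1, 2, 2, 4), c(10, 20, 30, 40)))
  cst <- spearman_rho(rep(2, 5), 1:5)
  expect_equal(as.numeric(cst), 0)
  expect_true(attr(cst, "tie"))
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  # invariance under strictly monotone transforms
  set.seed(4)
  for (rep in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    base <- as.numeric(spearman_rho(a, b))
    expect_equal(as.numeric(spearman_rho(exp(a), b)), base)
    expect_equal(as.numeric(spearman_rho(a, b^3 + 2 * b)), base)
  }
})

test_that("kNN smoothing averages the nearest neighborhood deterministically", {
  m <- toy_counts(list(c(0, 10), c(6, 20), c(12, 60)),
                  spot_ids = c("a", "b", "c"), gene_ids = c("g1", "g2"))
  e <- structure(list(values = m, layer = "sqrt"), class = "expr_mat")
  pos <- data.frame(spot_id = c("a", "b", "c"), x = c(0, 1, 2.5), y = 0)
  sm <- smooth_expression(e, pos, k_neighbors = 1, include_self = TRUE)
  # middle spot's nearer neighbor is "a" (distance 1 vs 1.5)
  expect_equal(as.matrix(sm)["b", "g1"], mean(c(6, 0)))
  expect_equal(as.matrix(sm)["c", "g1"], mean(c(12, 6)))
  # k = 0 with self is the identity; constant genes never change
  expect_equal(as.matrix(smooth_expression(e, pos, 0)), m)
  ec <- structure(list(values = cbind(m, gC = 7), layer = "sqrt"),
                  class = "expr_mat")
  smc <- smooth_expression(ec, pos, 1)
  expect_equal(unname(as.matrix(smc)[, "gC"]), rep(7, 3))
  expect_error(smooth_expression(e, pos, 3), "smaller")
  # exact distance tie broken toward the lexicographically smaller id
  pos_tie <- data.frame(spot_id = c("a", "b", "c"), x = c(-1, 0, 1), y = 0)
  smt <- smooth_expression(e, pos_tie, 1)
  expect_equal(as.matrix(smt)["b", "g1"], mean(c(6, 0)))
})

test_that("focal_network tags layers, excludes the focal TF, applies retention", {
  set.seed(6)
  n <- 40
  ids <- sprintf("s%02d", 1:n)
  act <- matrix(rnorm(3 * n), 3, n,
                dimnames = list(c("TFfocal", "TFcopy", "TFnoise"), ids))
  act["TFcopy", ] <- act["TFfocal", ]  # planted rho = 1 partner
  pw <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("pwA", "pwB"), ids))
  pos <- data.frame(spot_id = ids, x = seq_len(n), y = 0)
  expr <- structure(list(values = matrix(
    rpois(n * 4, 8), n, 4, dimnames = list(ids, c("gL", "gR", "gT", "gOff"))),
    layer = "sqrt"), class = "expr_mat")
  expr$values[, "gOff"] <- 0  # fails the expressed-fraction filter
  dsc <- matrix(rnorm(n), n, 1, dimnames = list(ids, "d1"))
  lr <- data.frame(ligand_gene = "gL", receptor_gene = "gR")
  net <- focal_network("TFfocal",
                       list(s1 = list(tf = act, pathway = pw, expr = expr,
                                      positions = pos, drugs = dsc)),
                       lr_pairs = lr, k_neighbors = 2)
  expect_false("TFfocal" %in% net$partner_id[net$layer == "TF"])
  expect_setequal(net$partner_id[net$layer == "L"], "gL")
  expect_setequal(net$partner_id[net$layer == "R"], "gR")
  expect_setequal(net$partner_id[net$layer == "P"], c("pwA", "pwB"))
  expect_setequal(net$partner_id[net$layer == "D"], "d1")
  expect_false("gOff" %in% net$partner_id)
  copy <- net[net$partner_id == "TFcopy" & net$layer == "TF", ]
  expect_equal(copy$rho, 1)
  expect_true(copy$retained)
  expect_error(focal_network("nope", list(s1 = list(tf = act))), "absent")
})

test_that("independent-noise partners are rarely retained at threshold 0.3", {
  retained <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    ids <- sprintf("s%03d", 1:n)
    act <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("focal", "noise"), ids))
    net <- focal_network("focal", list(s1 = list(tf = act)),
                         retain_abs_rho = 0.3)
    if (net$retained[net$partner_id == "noise"]) retained <- retained + 1
  }
  expect_lt(retained, 5)
})

test_that("focal_network output is independent of sample-list processing order", {
  set.seed(13)
  n <- 30
  ids <- sprintf("s%02d", 1:n)
  mk <- function() matrix(rnorm(3 * n), 3, n,
                          dimnames = list(c("focal", "t1", "t2"), ids))
  s1 <- list(tf = mk()); s2 <- list(tf = mk())
  n1 <- focal_network("focal", list(a = s1, b = s2))
  n2 <- focal_network("focal", list(b = s2, a = s1))
  expect_equal(n1, n2[order(n2$layer, n2$partner_id, n2$sample_id), ],
               ignore_attr = TRUE)
})

test_that("display_select ranks by mean |rho| and applies the strong filter", {
  mk <- function(sid, pid, layer, rho) {
    data.frame(sample_id = sid, focal_id = "f", partner_id = pid,
               layer = layer, rho = rho, tie = FALSE, n_spots = 50,
               retained = TRUE, stringsAsFactors = FALSE)
  }
  sids <- paste0("s", 1:6)
  assoc <- rbind(
    do.call(rbind, lapply(sids, function(s) mk(s, "always", "TF", 0.9))),
    do.call(rbind, lapply(seq_along(sids), function(i)
      mk(sids[i], "rarely", "TF", c(0.95, 0.95, 0.95, 0.95, 0.2, 0.2)[i]))),
    do.call(rbind, lapply(sids, function(s) mk(s, "weak", "TF", 0.1))))
  out <- display_select(assoc, top_n = 20, strong_rho = 0.5,
                        strong_min_samples = 5)
  expect_true("always" %in% out$partner_id)
  # top mean |rho| but strong in only 4 of 6 samples -> excluded
  expect_false("rarely" %in% out$partner_id)
  expect_false("weak" %in% out$partner_id)
  # single sample with strong_min_samples = 1 reduces to a plain threshold
  one <- assoc[assoc$sample_id == "s1", ]
  out1 <- display_select(one, strong_min_samples = 1)
  expect_setequal(out1$partner_id, c("always", "rarely"))
  # pathway layer gets its own (smaller) cut
  passoc <- do.call(rbind, lapply(1:12, function(i) mk("s1", paste0("p", i), "P",
                                                       0.5 + i / 100)))
  outp <- display_select(passoc, top_n = 20, top_n_pathways = 8,
                         strong_rho = 0.5, strong_min_samples = 1)
  expect_equal(nrow(outp), 8)
  expect_true(all(outp$partner_id %in% paste0("p", 5:12)))
})
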