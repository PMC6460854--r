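test_that("ct_to_quantity rescales to (0, 1] with per-gene efficiency", {
  ct <- matrix(c(20, 21, 23, 25, 25, 25), 2, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  q <- ct_to_quantity(ct_matrix(ct))$q
  expect_equal(unname(q["g1", ]), c(1, 0.5, 0.125))
  expect_equal(unname(q["g2", ]), c(1, 1, 1))

  ct2 <- matrix(c(20, 21), 1, 2, dimnames = list("g", c("a", "b")))
  q2 <- ct_to_quantity(ct_matrix(ct2, efficiencies = c(g = 1.05)))$q
  expect_equal(unname(q2[1, ]), c(1, 1 / 2.05), tolerance = 1e-12)
  expect_true(all(q <= 1 & q > 0))
})

test_that("amplification efficiency comes off the standard-curve slope", {
  inputs <- 100 / 2^(0:7)
  expect_equal(min(inputs), 0.78125)  # the 0.78-100 ng series
  # slope exactly -1 per two-fold step: perfect doubling
  fit <- amplification_efficiency(inputs, 35 - 1 * log2(inputs))
  expect_equal(fit$efficiency, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # shallower slope -0.93 -> E = 2^(1/0.93) - 1
  fit2 <- amplification_efficiency(inputs, 30 - 0.93 * log2(inputs))
  expect_equal(fit2$efficiency, 2^(1 / 0.93) - 1, tolerance = 1e-9)
  expect_error(amplification_efficiency(inputs[1:2], c(20, 21)), ">= 3")
  expect_error(amplification_efficiency(c(100, 60, 30), c(20, 21, 22)),
               "factor of 2")
})

test_that("genorm_M matches hand values and the brute-force oracle", {
  # proportional genes: constant log-ratio, M = 0
  q <- rbind(g1 = c(1, 0.5, 0.25, 0.125), g2 = c(0.8, 0.4, 0.2, 0.1))
  colnames(q) <- paste0("s", 1:4)
  expect_equal(unname(genorm_M(q)), c(0, 0))

  # log2-ratio pattern (0,1,0,1): sd = 0.5774
  q2 <- rbind(a = 2^c(0, 1, 0, 1) / 2, b = rep(0.5, 4))
  colnames(q2) <- paste0("s", 1:4)
  expect_equal(unname(genorm_M(q2)), rep(sd(c(0, 1, 0, 1)), 2),
               tolerance = 1e-12)

  for (seed in 1:10) {
    set.seed(seed)
    q3 <- matrix(2^rnorm(40), 5, 8,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
    q3 <- q3 / apply(q3, 1, max)
    expect_equal(genorm_M(q3), oracle_genorm_M(q3), tolerance = 1e-9)
  }
})

test_that("genorm_M is invariant to gene rescaling and sample permutation", {
  set.seed(99)
  q <- matrix(2^rnorm(48), 6, 8,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  m0 <- genorm_M(q)
  expect_equal(genorm_M(q * runif(6, 0.1, 3)), m0, tolerance = 1e-9)
  expect_equal(genorm_M(q[, sample(8)]), m0, tolerance = 1e-9)
})

test_that("genorm_rank excludes stepwise and emits the V series", {
  # two proportional genes + one noisy: noisy removed first, pair tied
  set.seed(5)
  base <- 2^rnorm(6, 0, 0.3)
  q <- rbind(gp1 = base, gp2 = 0.7 * base, noisy = 2^rnorm(6, 0, 2))
  colnames(q) <- paste0("s", 1:6)
  r <- genorm_rank(q)
  expect_identical(r$exclusion_order, "noisy")
  expect_equal(unname(r$ranks[c("gp1", "gp2", "noisy")]), c(1.5, 1.5, 3))

  # all pairwise proportional -> V series identically 0
  qp <- outer(c(1, 0.5, 0.25, 0.8), 2^rnorm(5))
  dimnames(qp) <- list(paste0("g", 1:4), paste0("s", 1:5))
  expect_equal(unname(genorm_rank(qp)$pairwise_variation), rep(0, 2),
               tolerance = 1e-12)
  expect_length(genorm_rank(qp)$pairwise_variation, 4 - 2)

  for (seed in 1:10) {
    set.seed(seed * 7)
    q6 <- matrix(2^rnorm(60, 0, 1), 6, 10,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
    expect_identical(genorm_rank(q6)$exclusion_order,
                     oracle_genorm_exclusion(q6))
  }
  expect_error(genorm_rank(q[1:2, ]), ">= 3")
})

test_that("normfinder reproduces the interaction example exactly", {
  # 4 genes, 2 balanced groups of 3, no within-group noise, gene1 offset
  # +1 cycle in group 1 and -1 in group 2: |d| = (k-1)/k = 0.75
  k <- 4
  b <- c(0, 0.5, 1, 0.2, 0.7, 1.2)   # per-sample shifts
  a <- c(25, 27, 24, 26)             # per-gene baselines
  ct <- outer(a, b, "+")
  ct[1, 1:3] <- ct[1, 1:3] - 1       # y = -Ct: +1 on y scale in group 1
  ct[1, 4:6] <- ct[1, 4:6] + 1
  dimnames(ct) <- list(paste0("g", 1:4), paste0("s", 1:6))
  groups <- setNames(rep(c("grp1", "grp2"), each = 3), colnames(ct))
  stab <- normfinder_stability(ct_matrix(ct, groups = groups))
  expect_equal(unname(stab["g1"]), (k - 1) / k, tolerance = 1e-12)
  expect_equal(unname(stab[c("g2", "g3", "g4")]), rep(1 / k, 3),
               tolerance = 1e-12)
  expect_gt(stab["g1"], max(stab[-1]))

  # identical patterns up to per-gene constants: stability 0 in both modes
  flat <- outer(a, b, "+")
  dimnames(flat) <- dimnames(ct)
  cm <- ct_matrix(flat, groups = groups)
  expect_equal(unname(normfinder_stability(cm)), rep(0, 4),
               tolerance = 1e-12)
  expect_equal(unname(normfinder_stability(cm, grouped = FALSE)),
               rep(0, 4), tolerance = 1e-12)

  # singleton group: instructive error
  bad_groups <- setNames(c("a", "a", "a", "a", "a", "b"), colnames(ct))
  expect_error(normfinder_stability(ct_matrix(ct, groups = bad_groups)),
               "grouped = FALSE")
})

test_that("normfinder matches the brute-force oracle in both modes", {
  for (seed in 1:10) {
    cm <- random_ct(5, 8, seed)
    expect_equal(normfinder_stability(cm, grouped = FALSE),
                 oracle_normfinder_ungrouped(cm$ct), tolerance = 1e-9)
    groups <- setNames(rep(c("g1", "g2"), each = 4), colnames(cm$ct))
    cmg <- ct_matrix(cm$ct, groups = groups)
    expect_equal(normfinder_stability(cmg),
                 oracle_normfinder_grouped(cmg$ct, groups[colnames(cmg$ct)]),
                 tolerance = 1e-9)
  }
})

test_that("deltact matches its oracle and the geNorm identity at E = 1", {
  # constant offset: both stabilities 0
  ct <- rbind(g1 = c(20, 22, 21, 23), g2 = c(25, 27, 26, 28))
  colnames(ct) <- paste0("s", 1:4)
  expect_equal(unname(deltact_stability(ct_matrix(ct))), c(0, 0))

  for (seed in 1:10) {
    cm <- random_ct(4, 6, seed + 100)
    expect_equal(deltact_stability(cm), oracle_deltact(cm$ct),
                 tolerance = 1e-9)
    # log2 quantity ratio at E = 1 is -deltaCt, so the two measures agree
    expect_equal(deltact_stability(cm), genorm_M(ct_to_quantity(cm)),
                 tolerance = 1e-9)
  }
})

test_that("comprehensive_rank combines ranks by geometric mean", {
  gm <- c(a = 0.2, b = 0.5, c = 0.9, d = 1.4)
  nf <- c(a = 0.1, b = 0.3, c = 0.2, d = 0.9)   # ranks a1 c2 b3 d4
  dc <- c(a = 0.4, b = 0.6, c = 1.0, d = 1.1)
  out <- comprehensive_rank(gm, nf, dc)
  expect_identical(out$gene_id[1], "a")
  expect_equal(out$comprehensive_score[out$gene_id == "a"], 1)
  # gene with ranks (1, 2, 4) scores exactly 2
  expect_equal(unname((1 * 2 * 4)^(1 / 3)), 2)
  b_row <- out[out$gene_id == "b", ]
  expect_equal(b_row$comprehensive_score,
               (2 * 3 * 2)^(1 / 3), tolerance = 1e-12)

  # ties share average ranks
  gm_tie <- c(a = 0.2, b = 0.2, c = 0.9)
  out2 <- comprehensive_rank(gm_tie, nf[1:3], dc[1:3])
  expect_equal(out2$genorm_rank[match(c("a", "b"), out2$gene_id)],
               c(1.5, 1.5))

  # invariant under monotone transforms of any one method's scores
  out3 <- comprehensive_rank(exp(gm), nf, dc)
  expect_identical(out3$gene_id, out$gene_id)
  expect_equal(out3$comprehensive_score, out$comprehensive_score)

  expect_error(comprehensive_rank(gm, nf[1:3], dc), "different gene sets")
  nf_na <- nf; nf_na["c"] <- NA
  expect_error(comprehensive_rank(gm, nf_na, dc), "NormFinder.*gene c")
})

test_that("all three methods flag a 10x-noise gene as least stable", {
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    n_s <- 12
    base <- rnorm(n_s, 25, 0.5)
    ct <- rbind(t(replicate(7, base + rnorm(n_s, 0, 0.2))),
                spike = base + rnorm(n_s, 0, 2))
    rownames(ct) <- c(paste0("g", 1:7), "spike")
    colnames(ct) <- paste0("s", 1:n_s)
    cm <- ct_matrix(pmin(pmax(ct, 5), 40))
    worst <- c(names(which.max(genorm_M(ct_to_quantity(cm)))),
               names(which.max(normfinder_stability(cm, grouped = FALSE))),
               names(which.max(deltact_stability(cm))))
    if (all(worst == "spike")) hits <- hits + 1
  }
  expect_gte(hits, 49)
})

test_that("stability_report averages technical replicates first", {
  set.seed(8)
  ct <- matrix(rnorm(3 * 6, 25, 1), 3, 6,
               dimnames = list(paste0("g", 1:3), paste0("w", 1:6)))
  cm <- ct_matrix(ct)
  map <- setNames(rep(c("s1", "s2", "s3"), each = 2), colnames(ct))
  rep1 <- stability_report(cm, replicate_map = map)
  avg <- t(apply(ct, 1, function(r) tapply(r, map, mean)))
  rep2 <- stability_report(ct_matrix(avg[, c("s1", "s2", "s3")]))
  expect_equal(rep1$comprehensive_score, rep2$comprehensive_score,
               tolerance = 1e-9)
  expect_identical(rep1$gene_id, rep2$gene_id)
})
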