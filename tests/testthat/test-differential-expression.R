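test_that("conditional tag probability matches its closed form", {
  # x=0, y=0, equal libraries: p = 1/2 (k=0 term of a geometric(1/2))
  expect_equal(ac_probability(0, 0, 1e6, 1e6), 0.5)
  # with equal library sizes the conditional is symmetric in (x, y);
  # with unequal sizes the exchange carries an exact N1/N2 factor
  for (cse in list(c(3, 7), c(0, 4), c(12, 2))) {
    expect_equal(ac_probability(cse[2], cse[1], 5e5, 5e5),
                 ac_probability(cse[1], cse[2], 5e5, 5e5),
                 tolerance = 1e-12)
  }
  expect_equal(ac_probability(7, 3, 1e5, 2e5),
               (1e5 / 2e5) * ac_probability(3, 7, 2e5, 1e5),
               tolerance = 1e-12)
  expect_error(ac_probability(-1, 0, 1, 1))
})

test_that("conditional distribution sums to one over y", {
  # oracle: summation to where the tail is < 1e-12
  for (x in c(0, 1, 5, 20, 50)) {
    for (r in c(0.5, 1, 2)) {
      n1 <- 1e6
      n2 <- r * n1
      y_hi <- ceiling((x + 1) * r + 20 * sqrt((x + 1) * r + 10) + 60)
      total <- sum(ac_probability(0:y_hi, x, n1, n2))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("two-sided p behaves at the anchors and decreases with distance", {
  expect_equal(ac_two_sided_p(0, 0, 1e6, 1e6), 1)
  # x=0, y=20, equal libraries: p ~ 2 * (1/2)^21 magnitude
  p <- ac_two_sided_p(0, 20, 1e6, 1e6)
  expect_lt(p, 1e-4)
  expect_equal(p, 2 * sum(ac_probability(20:200, 0, 1e6, 1e6)),
               tolerance = 1e-10)
  expect_gt(ac_two_sided_p(100, 100, 1e6, 1e6), 0.5)
  # decreasing in |y - x * N2/N1| for fixed x
  x <- 50
  ps <- vapply(c(50, 70, 90, 120, 160), function(y) {
    ac_two_sided_p(x, y, 1e6, 1e6)
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("two-sided p agrees with the negative-binomial oracle", {
  # spot grid here; the full x,y <= 50 sweep runs in the acceptance suite
  set.seed(4)
  for (i in 1:50) {
    x <- sample(0:60, 1)
    y <- sample(0:60, 1)
    r <- sample(c(0.5, 1, 2), 1)
    n1 <- 1e6
    expect_equal(ac_two_sided_p(x, y, n1, r * n1),
                 ac_two_sided_oracle(x, y, n1, r * n1),
                 tolerance = 1e-10)
  }
  # the minlike alternative is a valid p-value and at most the doubled tail
  p_min <- ac_two_sided_p(5, 20, 1e6, 1e6, method = "minlike")
  expect_lte(p_min, ac_two_sided_p(5, 20, 1e6, 1e6) + 1e-12)
  expect_gt(p_min, 0)
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.9)), c(0.03, 0.06, 0.9))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 1.2)))
  set.seed(8)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_equal(q, bh_by_hand(p), tolerance = 1e-12)
  expect_true(all(q >= p))
})

test_that("DEG calling applies both thresholds on raw counts and TPM ratio", {
  # build two libraries over one gene universe
  genes <- sprintf("g%02d", 1:6)
  n1 <- n2 <- 1e5
  x <- c(200L, 1000L, 50L, 0L, 3L, 0L)
  y <- c(50L, 1010L, 400L, 40L, 5L, 0L)
  e1 <- expr_from_counts(setNames(x, genes), n1)
  e2 <- expr_from_counts(setNames(y, genes), n2)
  degs <- call_degs(e1, e2)

  # x=200 -> y=50 at equal totals: log2 ratio = -2, tiny p -> down
  g1 <- degs[degs$gene_id == "g01", ]
  expect_equal(g1$log2_ratio, -2)
  expect_lt(g1$fdr, 0.001)
  expect_equal(g1$status, "down")

  # equal counts -> not significant
  expect_equal(degs$status[degs$gene_id == "g02"], "not_significant")

  # zero in one library uses the pseudo-TPM floor, stays finite
  g4 <- degs[degs$gene_id == "g04", ]
  expect_true(is.finite(g4$log2_ratio))
  expect_gt(g4$log2_ratio, 1)

  # genes absent from both libraries are excluded before FDR
  expect_false("g06" %in% degs$gene_id)
  expect_equal(attr(degs, "n_excluded"), 1L)
  expect_true(all(degs$fdr >= degs$p_value - 1e-12))

  # threshold logic: significant FDR but small ratio, and vice versa
  st <- function(fdr, l2r) {
    if (fdr <= 0.001 && l2r >= 1) "up"
    else if (fdr <= 0.001 && l2r <= -1) "down" else "not_significant"
  }
  expect_equal(st(0.01, 3), "not_significant")
  expect_equal(st(1e-6, 0.5), "not_significant")
  for (i in seq_len(nrow(degs))) {
    expect_equal(degs$status[i], st(degs$fdr[i], degs$log2_ratio[i]))
  }

  expect_error(call_degs(e1, expr_from_counts(setNames(x, rev(genes)), n2)),
               "universe")
})

test_that("swapping libraries flips signs and up/down calls", {
  set.seed(10)
  genes <- sprintf("g%03d", 1:100)
  x <- rpois(100, 60)
  y <- rpois(100, 60)
  y[1:10] <- y[1:10] * 5L
  e1 <- expr_from_counts(setNames(x, genes), 1e5)
  e2 <- expr_from_counts(setNames(y, genes), 1.3e5)
  fwd <- call_degs(e1, e2)
  rev_ <- call_degs(e2, e1)
  expect_equal(fwd$log2_ratio, -rev_$log2_ratio)
  expect_equal(sum(fwd$status == "up"), sum(rev_$status == "down"))
  expect_equal(sum(fwd$status == "down"), sum(rev_$status == "up"))
  # two-sided p-values of a discrete doubled-tail test are exchange-stable
  # only up to which tail the observed point falls in: agreement within a
  # factor of 2 and near-perfect rank agreement
  ratio <- fwd$p_value / rev_$p_value
  expect_true(all(ratio <= 2 + 1e-9 & ratio >= 0.5 - 1e-9))
  expect_gt(cor(log(fwd$p_value), log(rev_$p_value),
                method = "spearman"), 0.999)
})

test_that("fold-change bins use an inclusive boundary and sum to 100%", {
  # boundary 4 keeps the edge cases exact in floating point (2^2, 2^-2)
  rec <- data.frame(log2_ratio = c(1.9, 2, 0, -2, -1.5, 2.5))
  d <- fold_change_distribution(rec, boundary = 4)
  expect_equal(d$count[d$bin == "<4-fold"], 3)        # 2^1.9, 2^0, 2^-1.5
  expect_equal(d$count[d$bin == ">=4-fold up"], 2)    # 4 (inclusive), 2^2.5
  expect_equal(d$count[d$bin == ">=4-fold down"], 1)  # 0.25 (inclusive)
  expect_equal(sum(d$pct), 100)
  # a 4.9-fold change sits below a boundary of 5
  d5 <- fold_change_distribution(data.frame(log2_ratio = log2(4.9)), 5)
  expect_equal(d5$count, c(1, 0, 0))
  expect_error(fold_change_distribution(rec, boundary = 1), "boundary")
})

test_that("DEG set overlap partitions correctly", {
  ov <- compare_deg_sets(c("1", "2", "3"), c("3", "4"))
  expect_equal(ov[c("a_only", "b_only", "overlap")],
               list(a_only = 2L, b_only = 1L, overlap = 1L))
  expect_equal(compare_deg_sets(c("a"), c("b"))$overlap, 0)
  same <- compare_deg_sets(c("a", "b"), c("b", "a"))
  expect_equal(same$a_only + same$b_only, 0)
})

test_that("null data yields almost no calls; spiked genes are recovered", {
  # small-scale operating check (the full-scale one runs in acceptance):
  # Poisson null, then a 4-fold spike
  set.seed(12)
  n_genes <- 500
  depth <- 5e4
  genes <- sprintf("g%03d", seq_len(n_genes))
  mu <- 10^runif(n_genes, 0, 2)
  pr <- mu / sum(mu)
  x <- as.integer(rmultinom(1, depth, pr))
  y <- as.integer(rmultinom(1, depth, pr))
  e1 <- expr_from_counts(setNames(x, genes), depth)
  e2 <- expr_from_counts(setNames(y, genes), depth)
  null_calls <- sum(call_degs(e1, e2)$status != "not_significant")
  expect_lte(null_calls, 2)

  pr2 <- mu
  spiked <- which(rank(-mu) <= 30)  # strongest genes, baseline count >> 10
  pr2[spiked] <- pr2[spiked] * 4
  y2 <- as.integer(rmultinom(1, depth, pr2 / sum(pr2)))
  e2b <- expr_from_counts(setNames(y2, genes), depth)
  degs <- call_degs(e1, e2b)
  hit <- degs$gene_id[degs$status == "up"]
  big <- genes[spiked][x[spiked] >= 100]
  expect_gte(mean(big %in% hit), 0.9)
})

test_that("volcano table carries log10 TPMs with the pseudo floor", {
  e1 <- expr_from_counts(c(a = 10L, b = 0L), 1e4)
  e2 <- expr_from_counts(c(a = 10L, b = 50L), 1e4)
  v <- volcano_table(call_degs(e1, e2))
  expect_equal(v$log10_tpm1[v$gene_id == "b"], log10(0.001))
  expect_equal(v$log10_tpm2[v$gene_id == "a"], log10(1e6 * 10 / 1e4))
})
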