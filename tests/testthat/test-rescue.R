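# straight-line reimplementation of the five rules, used as oracle
brute_force_rules <- function(ctl, dis, drg, fpm_min = 3, lfc_min = 1,
                              level = 0.95) {
  ci <- function(v) {
    z <- log2(v + 1)
    tq <- qt(1 - (1 - level) / 2, length(v) - 1)
    m <- mean(z); se <- sd(z) / sqrt(length(v))
    c(max(2^(m - tq * se) - 1, 0), 2^(m + tq * se) - 1)
  }
  ov <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  lfc <- log2((mean(dis) + 1) / (mean(ctl) + 1))
  cc <- ci(ctl); cd <- ci(dis); ce <- ci(drg)
  r <- c(r1 = max(mean(ctl), mean(dis), mean(drg)) > fpm_min,
         r2 = abs(lfc) > lfc_min,
         r3 = !ov(cc, cd), r4 = !ov(cd, ce), r5 = ov(cc, ce))
  c(r, sensitive = all(r))
}

test_that("group confidence intervals match a t-interval oracle", {
  expect_equal(group_ci(c(10, 10, 10, 10))[, c("lower", "upper")],
               tibble::tibble(lower = 10, upper = 10))
  v <- c(10, 11, 9, 10)
  ci <- group_ci(v, 0.95, "log2p1")
  z <- log2(v + 1)
  tq <- qt(0.975, 3)
  expect_equal(ci$lower, 2^(mean(z) - tq * sd(z) / 2) - 1, tolerance = 1e-9)
  expect_equal(ci$upper, 2^(mean(z) + tq * sd(z) / 2) - 1, tolerance = 1e-9)
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  # linear scale is the plain t interval
  lin <- group_ci(v, 0.95, "linear")
  expect_equal(lin$estimate, 10)
  expect_equal(lin$upper, mean(v) + tq * sd(v) / 2, tolerance = 1e-9)
  expect_error(group_ci(10), "n < 2")
})

test_that("interval overlap uses the closed-interval convention", {
  mk <- function(lo, hi) tibble::tibble(lower = lo, upper = hi, scale = "log2p1")
  expect_true(intervals_overlap(mk(0, 1), mk(0, 1)))
  expect_true(intervals_overlap(mk(0, 1), mk(1, 2)))   # touching counts
  expect_false(intervals_overlap(mk(0, 1), mk(1.1, 2)))
  b <- mk(0, 1); b$scale <- "linear"
  expect_error(intervals_overlap(mk(0, 1), b), "different scales")
})

test_that("the five-rule classifier reproduces the worked example", {
  call <- classify_strategy_b(control = c(10, 11, 9, 10),
                              disease = c(40, 44, 38, 42, 41),
                              disease_drug = c(11, 10, 12, 9, 10))
  expect_true(all(unlist(call[, c("r1", "r2", "r3", "r4", "r5")])))
  expect_true(call$strategy_b)
  expect_identical(call$direction, "up")
  expect_equal(call$lfc_cd, log2(42 / 11), tolerance = 1e-9)

  # identical groups: identical CIs overlap, rule 3 fails
  flat <- classify_strategy_b(c(10, 10, 10, 10), c(10, 10, 10, 10),
                              c(10, 10, 10, 10))
  expect_false(flat$r3)
  expect_false(flat$strategy_b)

  # low abundance gates everything regardless of fold change
  dim_gene <- classify_strategy_b(c(0.2, 0.25, 0.2), c(2, 2.2, 2.1),
                                  c(0.2, 0.22, 0.21))
  expect_false(dim_gene$r1)
  expect_false(dim_gene$strategy_b)
})

test_that("the classifier agrees with a brute-force rule evaluator", {
  set.seed(13)
  for (i in 1:300) {
    base <- rlnorm(1, log(8), 1.5)
    ctl <- base * rlnorm(4, 0, 0.3)
    dis <- base * 2^runif(1, -3, 3) * rlnorm(5, 0, 0.3)
    drg <- base * 2^runif(1, -3, 3) * rlnorm(5, 0, 0.3)
    got <- classify_strategy_b(ctl, dis, drg)
    want <- brute_force_rules(ctl, dis, drg)
    expect_identical(unlist(got[, c("r1", "r2", "r3", "r4", "r5")],
                            use.names = FALSE),
                     unname(want[1:5]))
    expect_identical(got$strategy_b, unname(want[6]))
  }
})

test_that("widening the confidence level only relaxes rule 5 and tightens 3 and 4", {
  set.seed(17)
  for (i in 1:100) {
    ctl <- rlnorm(4, log(20), 0.5)
    dis <- rlnorm(5, log(20) + runif(1, -2, 2), 0.5)
    drg <- rlnorm(5, log(20) + runif(1, -2, 2), 0.5)
    narrow <- classify_strategy_b(ctl, dis, drg, ci_level = 0.90)
    wide <- classify_strategy_b(ctl, dis, drg, ci_level = 0.99)
    expect_true(!wide$r3 | narrow$r3)  # wide pass implies narrow pass
    expect_true(!wide$r4 | narrow$r4)
    expect_true(!narrow$r5 | wide$r5)  # narrow pass implies wide pass
  }
})

test_that("strategy A matches its boolean definition on random DE tables", {
  set.seed(19)
  g <- sprintf("g%03d", 1:200)
  mk_de <- function() {
    tibble::tibble(gene_id = g, log2fc = runif(200, -3, 3),
                   consensus = runif(200) < 0.4)
  }
  de_cd <- mk_de(); de_ce <- mk_de()
  got <- classify_strategy_a(de_cd, de_ce)
  want <- de_cd$consensus & abs(de_cd$log2fc) >= 1 &
    !de_ce$consensus & abs(de_ce$log2fc) <= 1
  expect_identical(got$strategy_a, want)

  # textbook rescue and a non-normalized counterexample
  one <- function(fc_cd, c_cd, fc_ce, c_ce) {
    classify_strategy_a(
      tibble::tibble(gene_id = "g", log2fc = fc_cd, consensus = c_cd),
      tibble::tibble(gene_id = "g", log2fc = fc_ce, consensus = c_ce))$strategy_a
  }
  expect_true(one(2.0, TRUE, 0.3, FALSE))
  expect_false(one(2.0, TRUE, 1.8, TRUE))
})

test_that("every gene gets exactly one direction label", {
  set.seed(23)
  sim <- simulate_counts(simulation_config(n_genes = 400), seed = 23)
  calls <- classify_rescue(normalize_fpm(sim$study))
  expect_true(all(calls$direction %in% c("up", "down", "none")))
  expect_identical(nrow(calls), 400L)
  # sensitivity flags are FALSE wherever direction is none
  none <- calls$direction == "none"
  expect_false(any(calls$strategy_b[none]))
})

test_that("strategy summary bookkeeping is internally consistent", {
  set.seed(29)
  sim <- simulate_counts(simulation_config(n_genes = 800, effect_lfc = 2),
                         seed = 29)
  cs <- sim$study
  de_cd <- de_consensus(cs, c("control", "disease"))
  de_ce <- de_consensus(cs, c("control", "disease_drug"))
  calls <- classify_rescue(normalize_fpm(cs), de_cd, de_ce)
  s <- summarize_strategies(calls)
  expect_equal(s$overall$n_up + s$overall$n_down, s$overall$n_regulated)
  for (strat in c("a", "b")) {
    cell <- dplyr::filter(s$cells, strategy == strat)
    expect_equal(sum(cell$n), s$overall$n_regulated)
  }
  expect_true(all(s$cells$pct_of_direction >= 0 & s$cells$pct_of_direction <= 100))
  expect_true(s$overall$overlap_jaccard >= 0 && s$overall$overlap_jaccard <= 1)

  # empty sensitive set: percentages and overlaps are zero
  empty <- tibble::tibble(gene_id = c("a", "b"), direction = c("up", "down"),
                          lfc_cd = c(2, -2), lfc_ce = c(1.5, -1.5),
                          strategy_a = FALSE, strategy_b = FALSE)
  s0 <- summarize_strategies(empty)
  expect_equal(s0$overall$n_sensitive_a, 0L)
  expect_equal(s0$overall$overlap_jaccard, 0)
  expect_equal(dplyr::filter(s0$cells, sensitive)$pct_of_direction, rep(0, 4))
})
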