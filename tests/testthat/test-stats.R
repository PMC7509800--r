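test_that("spearman_cor reproduces hand-computed and degenerate cases", {
  # 1 - 6*4/(5*24) = 0.8
  r <- spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)
  expect_equal(r$df, 3)
  expect_equal(spearman_cor(1:10, 1:10)$rho, 1)
  expect_equal(spearman_cor(1:10, 1:10)$p, 0)
  # n = 63 -> df = 61, the r(61) reporting convention
  expect_equal(spearman_cor(rnorm(63), rnorm(63))$df, 61)
  expect_warning(rc <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(rc$rho))
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
  expect_error(spearman_cor(1:5, 1:4), "equal length")
  expect_error(spearman_cor(c(1, NA, 3), 1:3), "missing")
})

test_that("spearman_cor agrees with the rank-then-Pearson oracle on ties", {
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- sample(1:8, n, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    expect_lt(abs(spearman_cor(x, y)$rho - oracle_spearman(x, y)), 1e-12)
  }
})

test_that("spearman_cor is invariant under strictly increasing transforms", {
  set.seed(21)
  for (i in 1:50) {
    x <- rnorm(30); y <- rnorm(30)
    r0 <- spearman_cor(x, y)$rho
    expect_equal(spearman_cor(exp(x), y^3 + 5 * y)$rho, r0)
    expect_equal(spearman_cor(rank(x), atan(y))$rho, r0)
  }
})

test_that("t-approximation p-values match the permutation option", {
  set.seed(31)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  pt_ <- spearman_cor(x, y)$p
  pp <- spearman_cor(x, y, method = "permutation", n_perm = 4000,
                     perm_seed = 1)$p
  expect_lt(abs(pt_ - pp), 0.02)
})

make_cohort_tables <- function(n = 63, rho = 0, seed = 1) {
  # direct construction of network signals + scores for the inference layer
  set.seed(seed)
  z <- rnorm(n)
  mfi_total <- pmin(100, pmax(20, round(55 + 15 * z)))
  dmn <- 0.5 * rho * z + rnorm(n)  # crude coupling control for table tests
  signals <- data.frame(subject_id = sprintf("s%02d", 1:n),
                        cen_psc = rnorm(n), dmn_psc = dmn)
  items <- t(vapply(mfi_total, function(tt) decompose_mfi_total(tt, seed = tt),
                    integer(20)))
  scores <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject_id = signals$subject_id[i],
               as.data.frame(score_mfi(items[i, ])))
  }))
  list(signals = signals, scores = scores)
}

test_that("conditional correction logic covers all four main-test outcomes", {
  # drive the logic with constructed data hitting each outcome combination
  tb <- make_cohort_tables(n = 40, seed = 5)
  rep0 <- run_main_hypotheses(tb$signals, tb$scores, alpha = 0.05)
  for (nw in c("CEN", "DMN")) {
    expect_equal(rep0$main[[nw]]$alpha_effective, 0.025)
  }
  check_family <- function(rep, nw) {
    fam <- rep$results[rep$results$network == nw & rep$results$role != "main", ]
    parent <- rep$main[[nw]]
    if (!is.na(parent$p) && parent$p < 0.025) {
      expect_true(all(fam$role == "followup"))
      expect_true(all(fam$alpha_effective == rep$alpha))
    } else {
      expect_true(all(fam$role == "posthoc"))
      expect_true(all(fam$alpha_effective == rep$alpha / nrow(fam)))
    }
  }
  # hit all 4 combinations by forcing strong/absent coupling per network
  combos <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (cb in combos) {
    n <- 63
    set.seed(17)
    z <- rnorm(n)
    mfi_total <- pmin(100, pmax(20, round(55 + 15 * z)))
    sig <- data.frame(
      subject_id = sprintf("s%02d", 1:n),
      cen_psc = if (cb[1] == 1) z + 0.1 * rnorm(n) else rnorm(n),
      dmn_psc = if (cb[2] == 1) z + 0.1 * rnorm(n) else rnorm(n))
    scores <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(subject_id = sig$subject_id[i],
                 as.data.frame(score_mfi(decompose_mfi_total(mfi_total[i],
                                                             seed = i))))
    }))
    rep <- run_main_hypotheses(sig, scores, alpha = 0.05)
    sig_cen <- rep$main$CEN$p < 0.025
    sig_dmn <- rep$main$DMN$p < 0.025
    expect_equal(sig_cen, cb[1] == 1)
    expect_equal(sig_dmn, cb[2] == 1)
    check_family(rep, "CEN")
    check_family(rep, "DMN")
  }
})

test_that("run_main_hypotheses validates alignment and alpha", {
  tb <- make_cohort_tables(n = 10, seed = 2)
  expect_error(run_main_hypotheses(tb$signals, tb$scores, alpha = 0),
               "alpha")
  bad <- tb$scores
  bad$subject_id[1] <- "nope"
  expect_error(run_main_hypotheses(tb$signals, bad), "mismatch")
})

test_that("subgroup follow-ups use each subgroup's own n for df", {
  tb <- make_cohort_tables(n = 63, seed = 9)
  groups <- rep(c("MG", "LGG", "HGG"), c(23, 21, 19))
  rep <- run_main_hypotheses(tb$signals, tb$scores,
                             groups = stats::setNames(groups,
                                                      tb$signals$subject_id))
  sub <- rep$results[grepl("^subgroup_", rep$results$test) &
                       rep$results$network == "DMN", ]
  expect_setequal(sub$df, c(21, 19, 17))
})

test_that("per-ROI correlations sort by strength and flag Bonferroni significance", {
  set.seed(13)
  n <- 63
  mfi <- sample(20:100, n, replace = TRUE)
  per_roi <- cbind(strong = scale(rank(mfi)) + 0.3 * rnorm(n),
                   weak = rnorm(n))
  colnames(per_roi) <- c("5", "9")
  nw <- c(`5` = "DMN", `9` = "CEN")
  res <- per_roi_correlations(per_roi, mfi, nw)
  expect_equal(res$roi_id[1], 5)      # strongest first
  expect_true(res$significant[res$roi_id == 5])
  expect_false(res$significant[res$roi_id == 9])
  expect_equal(res$network[res$roi_id == 5], "DMN")
  # single-ROI network: its per-ROI rho equals the network-mean rho
  net_dmn <- vapply(seq_len(n), function(i) {
    v <- stats::setNames(unname(per_roi[i, "5"]), "5")
    suppressWarnings(network_mean(v, nw["5"])$dmn_psc)
  }, numeric(1))
  expect_equal(res$rho[res$roi_id == 5], spearman_cor(mfi, net_dmn)$rho)
})

test_that("build_report writes the full bundle and fails on empty selections", {
  geom <- tiny_geometry(c(10, 10, 5))
  grid <- seeded_grid(geom)
  dmx <- design_matrix(mc_design())
  spec <- cohort_spec(n_subjects = 6, seed = 4)
  co <- synthesize_cohort(spec, dmx, geom, grid)
  res <- analyze_cohort(co, dmx, grid, select = FALSE)
  out <- withr::local_tempdir()
  paths <- build_report(res$report, res$group, set_networks(grid, res$network_of),
                        res$signals, res$scores, out, selected = res$selected)
  expect_true(all(file.exists(paths)))
  tab <- utils::read.csv(file.path(out, "roi_summary.csv"))
  expect_equal(nrow(tab), length(res$selected))
  expect_true(all(c("mean_psc", "sem", "t", "p", "network") %in% names(tab)))
  # determinism: rerun with the same seed gives byte-identical tables
  co2 <- synthesize_cohort(spec, dmx, geom, grid)
  res2 <- analyze_cohort(co2, dmx, grid, select = FALSE)
  out2 <- withr::local_tempdir()
  build_report(res2$report, res2$group, set_networks(grid, res2$network_of),
               res2$signals, res2$scores, out2, selected = res2$selected)
  for (f in c("roi_summary.csv", "hypothesis_tests.csv", "network_scatter.csv")) {
    expect_identical(readLines(file.path(out, f)),
                     readLines(file.path(out2, f)))
  }
  # empty selection: explicit stanza + error
  empty_grid <- build_roi_grid(geom)
  expect_error(build_report(res$report, res$group, empty_grid, res$signals,
                            res$scores, withr::local_tempdir()),
               "no ROIs selected")
})
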