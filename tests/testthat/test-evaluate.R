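test_that("ROC handles separation, anti-separation, and tied scores", {
    r <- rocCurve(c(.9, .8, .4, .2), c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(r$auc, 1)
    expect_equal(rocCurve(c(.9, .8, .4, .2),
                          c(FALSE, FALSE, TRUE, TRUE))$auc, 0)
    # frozen from pair counting: 2 concordant of 4 pairs
    expect_equal(rocCurve(c(.9, .4, .8, .2), c(1, 0, 0, 1))$auc, 0.5)
    expect_error(rocCurve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("trapezoid ROC AUC equals the rank-sum oracle on random instances", {
    set.seed(91)
    for (i in 1:60) {
        n <- sample(4:100, 1L)
        s <- if (i %% 2L) stats::rnorm(n) else sample(seq(0, 1, 0.2), n, TRUE)
        y <- stats::runif(n) < 0.4
        if (all(y) || !any(y)) y[1:2] <- c(TRUE, FALSE)
        expect_equal(rocCurve(s, y)$auc, rocAucOracle(s, y),
                     tolerance = 1e-12)
    }
})

test_that("ROC AUC agrees with an established implementation", {
    skip_if_not_installed("pROC")
    set.seed(92)
    s <- stats::rnorm(60)
    y <- stats::runif(60) < 0.3
    expect_equal(rocCurve(s, y)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
})

test_that("PR curve follows the declared anchoring conventions", {
    expect_equal(prCurve(c(.9, .8, .4, .2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
    # all scores tied: one point at full recall with precision = prevalence
    flat <- prCurve(rep(0.5, 8L), rep(c(TRUE, FALSE), c(3L, 5L)))
    expect_identical(nrow(flat$points), 1L)
    expect_equal(flat$points$recall, 1)
    expect_equal(flat$points$precision, 3 / 8)
    expect_equal(flat$auc, 3 / 8)
    expect_error(prCurve(1:3, c(FALSE, FALSE, FALSE)), "positive")
})

test_that("PR AUC equals the threshold-enumeration oracle", {
    # a 6-sample mixed hand case plus random instances
    s6 <- c(.9, .7, .6, .5, .3, .1)
    y6 <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
    expect_equal(prCurve(s6, y6)$auc, prAucOracle(s6, y6), tolerance = 1e-12)
    set.seed(93)
    for (i in 1:40) {
        n <- sample(4:60, 1L)
        s <- if (i %% 2L) stats::rnorm(n) else sample(seq(0, 1, 0.25), n, TRUE)
        y <- stats::runif(n) < 0.5
        if (!any(y)) y[1L] <- TRUE
        expect_equal(prCurve(s, y)$auc, prAucOracle(s, y), tolerance = 1e-12)
    }
})

test_that("assignment tables count top-1 and top-2 hits per city", {
    sc <- matrix(c(0.9, 0.1, 0.2,   # s1: true A ranked 1
                   0.4, 0.6, 0.1,   # s2: true A ranked 2
                   0.2, 0.5, 0.8,   # s3: true A ranked 3 (C, B, A)
                   0.9, 0.2, 0.3),  # s4: true A ranked 1
                 nrow = 4L, byrow = TRUE,
                 dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
    tab <- assignmentTable(assignCities(sc), rep("A", 4L))
    all <- tab[tab$city == "All", ]
    expect_equal(all$top1_pct, 50)
    expect_equal(all$top2_pct, 75)
    expect_identical(all$top1_true + all$top1_false, all$n)

    # a sample whose true city ranks 2nd is false at top-1, true at top-2
    tab2 <- assignmentTable(assignCities(sc[2L, , drop = FALSE]), "A")
    expect_identical(tab2$top1_true[1L], 0L)
    expect_identical(tab2$top2_true[1L], 1L)

    perfect <- assignmentTable(assignCities(sc[c(1L, 4L), ]), c("A", "A"))
    expect_equal(perfect[perfect$city == "All", "top1_pct"], 100)
    expect_error(assignmentTable(assignCities(sc), rep("Z", 4L)),
                 "not among ranked")
})

test_that("top-2 hits always dominate top-1 hits", {
    set.seed(94)
    for (i in 1:15) {
        sc <- matrix(stats::runif(30), 6L, 5L,
                     dimnames = list(paste0("s", 1:6), LETTERS[1:5]))
        truth <- sample(LETTERS[1:5], 6L, replace = TRUE)
        tab <- assignmentTable(assignCities(sc), truth)
        expect_true(all(tab$top2_true >= tab$top1_true))
    }
})

test_that("per-city AUCs flag prevalence-driven PR degradation", {
    aucs <- cityAUCs(hardCV())
    minority <- aucs[aucs$city == "city01", ]
    majority <- aucs[aucs$n_pos == max(aucs$n_pos), ][1L, ]
    # ROC stays high for the minority city while PR suffers
    expect_gt(minority$roc_auc, 0.9)
    expect_lt(minority$pr_auc, minority$roc_auc - 0.05)
    expect_lt(minority$pr_auc, majority$pr_auc)
})

test_that("signature t-tests report direction and raw p-values", {
    se <- smallKnown()
    # planted depleted EC detected with the planted direction
    sig <- plantedSignatures(se)[["city02"]]
    tt <- signatureTTests(se, "city02", sig$ec)
    expect_identical(tt$direction, sig$direction)
    expect_true(all(tt$pValue[sig$direction == "depleted"] < 0.01))
    # swapping groups flips t and direction but not p
    labs <- cityLabels(se)
    a <- abundanceMatrix(se)
    flip <- ECProfileSet(a, city = ifelse(labs == "city02", "rest", "city02"),
                         totalReads = totalReads(se))
    tf <- signatureTTests(flip, "city02", sig$ec)
    expect_equal(tf$tStat, -tt$tStat, tolerance = 1e-10)
    expect_equal(tf$pValue, tt$pValue, tolerance = 1e-10)
    expect_identical(tf$direction == "enriched", tt$direction == "depleted")
    # optional multiplicity adjustment is off by default
    expect_null(tt$pAdjusted)
    expect_true(all(signatureTTests(se, "city02", sig$ec,
                                    adjust = "BH")$pAdjusted >= tt$pValue))
    expect_error(signatureTTests(se[, 1:9], "city02"), ">= 2 samples")
})

test_that("null t-tests behave like a uniform p-value draw", {
    cfg <- syntheticConfig(nCities = 2L, samplesPerCity = c(25L, 25L),
                           nEcs = 100L, nSignatureEcsPerCity = 5L,
                           effectSize = 1, sparsity = 0, seed = 37L)
    se <- simulateKnownSet(cfg)
    tt <- signatureTTests(se, "city01")
    expect_lt(mean(tt$pValue < 0.05), 0.15)
    expect_gt(mean(tt$pValue), 0.35)
    expect_identical(tt$direction,
                     ifelse(tt$meanInCity >= tt$meanElsewhere,
                            "enriched", "depleted"))
})
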