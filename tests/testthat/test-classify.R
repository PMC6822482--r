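.toyMatrix <- function(seed = 31) {
    set.seed(seed)
    m <- rbind(matrix(stats::rnorm(20, 0, 0.2), 10, 2),
               matrix(stats::rnorm(20, 3, 0.2), 10, 2))
    dimnames(m) <- list(sprintf("s%02d", 1:20), c("1.1.1.1", "2.2.2.2"))
    m
}

test_that("a separable toy problem separates in training scores", {
    m <- .toyMatrix()
    pos <- rep(c(TRUE, FALSE), each = 10L)
    mod <- trainCityModel(m, "toy", positives = pos)
    s <- rawScores(mod, m)
    expect_gt(min(s[pos]), max(s[!pos]))
    expect_identical(unname(trainScoreRange(mod)), unname(range(s)))
    # identical training data gives identical scores
    mod2 <- trainCityModel(m, "toy", positives = pos)
    expect_identical(rawScores(mod2, m), s)
    expect_error(trainCityModel(m, "toy", positives = rep(TRUE, 20L)),
                 "both classes")
})

test_that("score standardization maps the training range onto [0, 1]", {
    m <- .toyMatrix()
    mod <- trainCityModel(m, "toy", positives = rep(c(TRUE, FALSE), each = 10L))
    r <- trainScoreRange(mod)
    expect_equal(standardizeScores(r[2L], mod), 1)
    expect_equal(standardizeScores(r[1L], mod), 0)
    expect_equal(standardizeScores(mean(r), mod), 0.5)
    # not clamped: out-of-range raw scores land outside [0, 1]
    expect_gt(standardizeScores(r[2L] + 1, mod), 1)
    expect_lt(standardizeScores(r[1L] - 1, mod), 0)
    # strictly monotone: ordering preserved
    raw <- sort(stats::rnorm(20))
    expect_identical(order(standardizeScores(raw, mod)), order(raw))
    # degenerate range maps everything to 0.5
    degenerate <- mod
    degenerate@scoreRange <- c(0.2, 0.2)
    expect_equal(standardizeScores(c(-5, 0, 5), degenerate), rep(0.5, 3L))
})

test_that("city assignment ranks by score with lexicographic ties", {
    a <- assignCities(c(A = 0.9, B = 0.2))
    expect_identical(unname(topCity(a)), "A")
    expect_identical(unname(cityRanking(a)[1L, ]), c("A", "B"))
    expect_equal(unname(topHitScores(a)), 0.9)

    tied <- assignCities(c(B = 0.5, A = 0.5))
    expect_identical(unname(cityRanking(tied)[1L, ]), c("A", "B"))
    expect_error(assignCities(numeric(0)), "non-empty")

    df <- as.data.frame(assignCities(
        matrix(c(0.9, 0.2, 0.1, 0.8), 2L,
               dimnames = list(c("s1", "s2"), c("A", "B")))))
    expect_identical(df$top_city, c("A", "B"))
    expect_identical(df$second_city, c("B", "A"))
})

test_that("two-stage balancing yields the prescribed class sizes", {
    labels <- rep(c("a", "b", "c"), c(1L, 4L, 10L))
    b <- balanceResample(labels, "b", perCity = 150L, perClass = 5000L,
                         seed = 3L)
    expect_length(b$idx, 10000L)
    expect_identical(sum(b$positive), 5000L)
    expect_true(all(lengths(b$stage1) == 150L))
    # a single-sample city becomes 150 copies of that sample
    expect_identical(unique(b$stage1[["a"]]), 1L)
    # balancing re-weights but never invents samples
    expect_true(all(b$idx %in% seq_along(labels)))
    expect_true(all(labels[b$idx[b$positive]] == "b"))
    expect_true(all(labels[b$idx[!b$positive]] != "b"))
    expect_error(balanceResample(labels, "nope"), "absent")
    expect_error(balanceResample(rep("a", 5L), "a"), "two cities")
})

test_that("leave-one-out runs one leakage-free iteration per sample", {
    known <- smallKnown()
    cv <- smallCV()
    expect_identical(nrow(standardizedScores(assignments(cv))),
                     ncol(known))
    expect_identical(rownames(cv@rawScores), colnames(known))

    # recompute two iterations from scratch without the held-out sample and
    # reproduce the stored selection and held-out scores
    m <- abundanceMatrix(known, samplesAsRows = TRUE)
    labels <- as.character(cityLabels(known))
    for (i in c(1L, 15L)) {
        for (cc in sort(unique(labels))) {
            rk <- selectTopFeatures(m[-i, ], labels[-i] == cc, k = 10L,
                                    city = cc)
            stored <- iterationRankings(cv, cc)[[i]]
            expect_identical(selectedECs(stored), selectedECs(rk))
            mod <- trainCityModel(m[-i, ], cc, positives = labels[-i] == cc,
                                  selected = selectedECs(rk))
            expect_equal(unname(rawScores(mod, m[i, , drop = FALSE])),
                         unname(cv@rawScores[i, cc]), tolerance = 1e-10)
        }
    }
    expect_error(looCrossval(known, "nonsense"), "arg")
})

test_that("standardization preserves score order under one model", {
    suite <- smallSuite()
    known <- smallKnown()
    std <- standardizedScores(predictSuite(suite, known))
    for (cc in trainingCities(suite)) {
        raw <- rawScores(cityModel(suite, cc), known)
        expect_identical(order(std[, cc]), order(raw))
    }
})

test_that("cities with a lone sample are rejected for leave-one-out", {
    known <- smallKnown()[, -(1:7)]  # city01 keeps a single sample
    expect_error(looCrossval(known, "raw-full"), ">= 2 samples")
})

test_that("random-label accuracy sits at the chance level of the priors", {
    cv <- smallCV()
    acc <- randomLabelBaseline(cv, nReplicates = 30L, seed = 77L)
    expect_length(acc, 30L)
    perm <- randomLabelBaseline(cv, nReplicates = 500L, seed = 78L)
    ci <- stats::quantile(perm, c(0.025, 0.975))
    expect_gte(mean(acc), ci[[1L]])
    expect_lte(mean(acc), ci[[2L]])
    # chance from priors: sum_c P(assign c) P(true c)
    pr <- prop.table(table(cv@trueCity))
    qr <- prop.table(table(factor(topCity(assignments(cv)),
                                  levels = names(pr))))
    expect_equal(mean(perm), sum(pr * qr), tolerance = 0.05)
})

test_that("the final suite fits one standardizable model per city", {
    suite <- smallSuite()
    known <- smallKnown()
    expect_identical(trainingCities(suite),
                     sort(unique(as.character(cityLabels(known)))))
    expect_s4_class(cityModel(suite, "city01"), "CityModel")
    expect_error(cityModel(suite, "atlantis"), "no model")
    # refitting with the same seed reproduces the suite exactly
    suite2 <- fitFinalSuite(known, "final",
                            params = list(kFeatures = 10L, perCity = 20L,
                                          perClass = 60L), seed = 5L)
    expect_identical(suiteManifest(suite2), suiteManifest(suite))
    a1 <- standardizedScores(predictSuite(suite, known))
    a2 <- standardizedScores(predictSuite(suite2, known))
    expect_identical(a1, a2)
    # every city model scores its own training positives high
    for (cc in trainingCities(suite)) {
        own <- a1[cityLabels(known) == cc, cc]
        rest <- a1[cityLabels(known) != cc, cc]
        expect_gt(mean(own), mean(rest))
    }
})
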