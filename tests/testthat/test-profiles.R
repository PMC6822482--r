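test_that("profile files parse, with comments and blank lines skipped", {
    f <- writeProfileFile(c("# EC\tcount", "", "1.1.1.1\t50", "2.7.7.7\t10"))
    p <- readProfile(f, sampleID = "s1")
    expect_s4_class(p, "FunctionalProfile")
    expect_identical(readCounts(p), c("1.1.1.1" = 50L, "2.7.7.7" = 10L))
    expect_false(isNormalized(p))

    empty <- readProfile(writeProfileFile(c("# nothing", "# here")))
    expect_length(readCounts(empty), 0L)
})

test_that("malformed profile rows are rejected with the offending line", {
    dup <- writeProfileFile(c("1.1.1.1\t50", "1.1.1.1\t7"))
    expect_error(readProfile(dup), "duplicate EC '1\\.1\\.1\\.1'.*lines 1, 2")
    expect_error(readProfile(writeProfileFile("1.1.1\t5")),
                 "line 1.*malformed EC")
    expect_error(readProfile(writeProfileFile("1.1.1.1\tfifty")),
                 "line 1.*not a non-negative integer")
    expect_error(readProfile(writeProfileFile("1.1.1.1\t2.5")),
                 "not a non-negative integer")
    expect_error(readProfile(writeProfileFile("1.1.1.1 50")),
                 "expected 2 tab-separated fields")
    expect_error(readProfile(tempfile()), "not found")
})

test_that("normalization divides counts by the supplied total read count", {
    p <- FunctionalProfile("s", c("1.1.1.1" = 50L))
    expect_equal(abundances(normalizeProfile(p, 1000)),
                 c("1.1.1.1" = 0.05))
    q <- normalizeProfile(
        FunctionalProfile("t", c("1.1.1.1" = 30L, "2.2.2.2" = 70L)), 200)
    expect_equal(abundances(q), c("1.1.1.1" = 0.15, "2.2.2.2" = 0.35))
    expect_identical(readCounts(q), c("1.1.1.1" = 30L, "2.2.2.2" = 70L))
    # annotated reads can never exceed the sample's total reads
    expect_error(normalizeProfile(
        FunctionalProfile("u", c("1.1.1.1" = 300L)), 200),
        "exceed totalReads")
    expect_error(normalizeProfile(p, 0), "positive")
    expect_error(abundances(p), "not been normalized")
})

test_that("feature matrix is the zero-filled union in lexicographic order", {
    p1 <- normalizeProfile(FunctionalProfile("s1", c("1.1.1.1" = 10L,
                                                     "2.2.2.2" = 5L)), 100)
    p2 <- normalizeProfile(FunctionalProfile("s2", c("2.2.2.2" = 4L,
                                                     "3.3.3.3" = 6L)), 100)
    se <- buildFeatureMatrix(list(p1, p2))
    expect_s4_class(se, "ECProfileSet")
    expect_identical(ecUniverse(se), c("1.1.1.1", "2.2.2.2", "3.3.3.3"))
    a <- abundanceMatrix(se, samplesAsRows = TRUE)
    expect_identical(a["s1", "3.3.3.3"], 0)
    expect_identical(a["s2", "1.1.1.1"], 0)
    expect_equal(a["s2", "2.2.2.2"], 0.04)

    # unnormalized input is an error
    expect_error(buildFeatureMatrix(list(p1, FunctionalProfile("s3",
                 c("1.1.1.1" = 1L)))), "unnormalized profile")

    # identical profiles give identical rows
    p2b <- normalizeProfile(FunctionalProfile("s2b", readCounts(p1)), 100)
    se2 <- buildFeatureMatrix(list(p1, p2b))
    m <- abundanceMatrix(se2, samplesAsRows = TRUE)
    expect_identical(unname(m["s1", ]), unname(m["s2b", ]))
})

test_that("row sums and column counts match independently computed values", {
    set.seed(41)
    profiles <- lapply(1:6, function(i) {
        ecs <- sprintf("%d.%d.%d.%d", sample(1:6, 8, TRUE), sample(1:9, 8, TRUE),
                       sample(1:9, 8, TRUE), sample(1:50, 8, TRUE))
        ecs <- unique(ecs)
        normalizeProfile(
            FunctionalProfile(paste0("s", i),
                              stats::setNames(sample(1:40, length(ecs)), ecs)),
            1000)
    })
    se <- buildFeatureMatrix(profiles)
    # independent union cardinality
    expect_identical(nrow(se),
                     length(Reduce(union, lapply(profiles, function(p)
                         names(readCounts(p))))))
    # per-sample row sum equals the profile's own abundance sum
    a <- abundanceMatrix(se, samplesAsRows = TRUE)
    for (p in profiles)
        expect_equal(unname(sum(a[p@sampleID, ])),
                     unname(sum(abundances(p))))
})

test_that("feature matrix construction is permutation-safe", {
    set.seed(5)
    profiles <- lapply(1:5, function(i) {
        n <- sample(3:8, 1)
        ecs <- sprintf("%d.%d.%d.%d", 1:n, 2, 3, i)
        normalizeProfile(FunctionalProfile(paste0("s", i),
                         stats::setNames(sample(10:90, n), ecs)), 500)
    })
    se1 <- buildFeatureMatrix(profiles)
    se2 <- buildFeatureMatrix(rev(profiles))
    expect_identical(ecUniverse(se1), ecUniverse(se2))
    m1 <- abundanceMatrix(se1, samplesAsRows = TRUE)
    m2 <- abundanceMatrix(se2, samplesAsRows = TRUE)
    expect_identical(m1, m2[rownames(m1), ])
})

test_that("a written feature matrix re-reads bit-exactly", {
    se <- smallKnown()[, 1:10]
    f <- tempfile(fileext = ".tsv")
    writeFeatureMatrix(se, f)
    back <- readFeatureMatrix(f)
    expect_identical(abundanceMatrix(back), abundanceMatrix(se))
    expect_identical(ecUniverse(back), ecUniverse(se))
})

test_that("samples project onto a training universe by drop-and-zero-fill", {
    m <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2,
                dimnames = list(c("a", "b"), c("1.1.1.1", "9.9.9.9")))
    pr <- projectProfiles(m, c("1.1.1.1", "2.2.2.2"))
    expect_identical(colnames(pr), c("1.1.1.1", "2.2.2.2"))
    expect_equal(pr[, "1.1.1.1"], c(a = 0.1, b = 0.2))
    expect_equal(unname(pr[, "2.2.2.2"]), c(0, 0))  # unseen in training
})

test_that("a sample-set directory round-trips through the exchange formats", {
    dir <- tempfile("synthset")
    writeSyntheticSet(smallKnown(), dir)
    se <- readSampleSet(file.path(dir, "profiles"),
                        file.path(dir, "metadata.csv"))
    expect_identical(sort(colnames(se)), sort(colnames(smallKnown())))
    expect_identical(as.character(cityLabels(se)[colnames(smallKnown())]),
                     as.character(cityLabels(smallKnown())))
    # abundances agree on the shared EC universe (all-zero ECs are not
    # written to per-sample files, so the re-read union can be smaller)
    a0 <- abundanceMatrix(smallKnown())[ecUniverse(se), colnames(se)]
    expect_equal(abundanceMatrix(se), a0)
    truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
    expect_named(truth$signatures, names(plantedSignatures(smallKnown())))
})

test_that("container validity rejects malformed inputs", {
    a <- matrix(0.1, 2, 2, dimnames = list(c("2.2.2.2", "1.1.1.1"),
                                           c("s1", "s2")))
    # constructor sorts rows lexicographically
    se <- ECProfileSet(a)
    expect_identical(ecUniverse(se), c("1.1.1.1", "2.2.2.2"))
    expect_error(ECProfileSet(matrix(0.1, 1, 1,
        dimnames = list("not-an-ec", "s1"))), "malformed EC")
    expect_error(ECProfileSet(matrix(2, 1, 1,
        dimnames = list("1.1.1.1", "s1"))), "must not exceed 1")
})
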