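test_that("dibasic sites are found at every motif window", {
    s <- findCleavageSites("MAKRGS")
    expect_equal(s$cut_after, 4L)
    expect_equal(s$motif, "KR")
    expect_equal(s$kind, "dibasic")

    expect_equal(nrow(findCleavageSites("MAAAA")), 0L)

    # overlapping motifs each yield their own site
    s <- findCleavageSites("MKRRA")
    expect_equal(s$cut_after, c(3L, 4L))
    expect_equal(s$motif, c("KR", "RR"))

    # motif subset is honoured
    s <- findCleavageSites("MAKRGS", motifs = c("RR", "KK"))
    expect_equal(nrow(s), 0L)

    expect_error(findCleavageSites("MAKRGS", motifs = character(0)))
    expect_error(findCleavageSites("MAKRGS", motifs = "KRA"))
})

test_that("monobasic mode adds isolated K/R sites without touching dibasic ones", {
    # A R A K K A: KK is dibasic (cut after 5); R at 2 is isolated
    s <- findCleavageSites("ARAKKA", monobasic = TRUE)
    expect_equal(s$cut_after, c(2L, 5L))
    expect_equal(s$kind, c("monobasic", "dibasic"))

    # K/R inside a matched motif are covered, not monobasic
    s <- findCleavageSites("AKRA", monobasic = TRUE)
    expect_equal(s$cut_after, 3L)
    expect_equal(s$kind, "dibasic")
})

test_that("fragmentation applies the cut-after convention and drops empty tails", {
    s <- "SAKRTTKRGG"
    fr <- fragmentSequence(s, findCleavageSites(s))
    expect_equal(fr$sequence, c("SAKR", "TTKR", "GG"))
    expect_equal(fr$start, c(1L, 5L, 9L))
    expect_equal(fr$end, c(4L, 8L, 10L))
    expect_equal(fr$c_terminal_motif, c("KR", "KR", NA))

    # no sites: the whole sequence is one fragment
    fr <- fragmentSequence("MAAAA", findCleavageSites("MAAAA"))
    expect_equal(fr$sequence, "MAAAA")

    # trailing cut at the final residue: empty fragment dropped
    fr <- fragmentSequence("AAKR", findCleavageSites("AAKR"))
    expect_equal(fr$sequence, "AAKR")
    expect_equal(nrow(fr), 1L)

    expect_error(
        fragmentSequence("AAA", S4Vectors::DataFrame(cut_after = 5L)),
        "out of range")
})

test_that("site lists equal a brute-force dipeptide-window oracle on random sequences", {
    set.seed(101)
    for (rep in 1:300) {
        s <- randomSeq(sample(1:200, 1))
        expect_identical(findCleavageSites(s)$cut_after,
                         oracleCleavageSites(s))
        mono <- findCleavageSites(s, monobasic = TRUE)
        expect_identical(mono$cut_after,
                         oracleCleavageSites(s, monobasic = TRUE))
        expect_false(any(duplicated(mono$cut_after)))
    }
})

test_that("fragments concatenate to the precursor and monobasic mode is monotone", {
    set.seed(202)
    for (rep in 1:200) {
        s <- randomSeq(sample(2:150, 1))
        di <- findCleavageSites(s)
        mono <- findCleavageSites(s, monobasic = TRUE)
        frDi <- fragmentSequence(s, di)
        frMono <- fragmentSequence(s, mono)
        expect_identical(paste(frDi$sequence, collapse = ""), s)
        expect_identical(paste(frMono$sequence, collapse = ""), s)
        # enabling monobasic never removes a dibasic site
        expect_true(all(di$cut_after %in% mono$cut_after))
        expect_gte(nrow(frMono), nrow(frDi))
        # coordinates are 1-based inclusive and contiguous
        expect_true(all(frDi$start <= frDi$end))
        expect_identical(frDi$sequence,
                         substring(s, frDi$start, frDi$end))
    }
})
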