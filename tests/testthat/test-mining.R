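test_that("percentIdentity matches its stated examples", {
    expect_equal(percentIdentity("QYKAPSW", "QYKAPSW"), 100)
    # optimal local alignment spans all four columns under BLOSUM62
    expect_equal(percentIdentity("AAAA", "AATA"), 75)
    # all substitution scores negative: no positive-scoring alignment
    expect_equal(percentIdentity("GGGG", "WWWW"), 0)
    expect_error(percentIdentity("", "AAA"), "non-empty")
    expect_error(percentIdentity("AXA", "AAA"), "standard")
})

test_that("percentIdentity agrees with an exhaustive alignment enumeration on 4-mers", {
    expect_true(percentIdentity("AAAA", "AATA") %in%
                oracleIdentitySet("AAAA", "AATA"))
    expect_true(percentIdentity("GGGG", "WWWW") %in%
                oracleIdentitySet("GGGG", "WWWW"))
    set.seed(7)
    for (rep in 1:15) {
        a <- randomSeq(sample(2:4, 1))
        b <- randomSeq(sample(2:4, 1))
        expect_true(percentIdentity(a, b) %in% oracleIdentitySet(a, b),
                    info = paste(a, b))
    }
})

test_that("percentIdentity is symmetric and 100 on self", {
    set.seed(11)
    for (rep in 1:40) {
        a <- randomSeq(sample(3:30, 1))
        b <- randomSeq(sample(3:30, 1))
        expect_equal(percentIdentity(a, b), percentIdentity(b, a))
        expect_equal(percentIdentity(a, a), 100)
    }
})

test_that("tier rules follow their inclusive/exclusive boundaries", {
    cfg <- MiningConfig()
    # identity exactly 70 over 20 columns (14 matches): tier1, inclusive
    a20 <- strrep("A", 20)
    b70 <- "ATAATAATAATAATAATAAA"   # T at 2,5,8,11,14,17 -> 14/20 = 70%
    expect_equal(percentIdentity(a20, b70), 70)
    r <- isSimilar(a20, b70, cfg)
    expect_true(r$similar); expect_equal(r$tier, "tier1")
    # identity 65 (< 70), length 20 blocks tier2: not similar
    b65 <- "ATAATAATAATAATAATATA"   # 7 mismatches -> 13/20 = 65%
    expect_equal(percentIdentity(a20, b65), 65)
    r <- isSimilar(a20, b65, cfg)
    expect_false(r$similar)

    # tier1 length gate is exclusive at 30
    a <- strrep("L", 25)
    expect_true(isSimilar(a, paste0(a, strrep("G", 29)), cfg)$similar)
    expect_false(isSimilar(a, paste0(a, strrep("G", 30)), cfg)$similar)

    # spec example: lengths 10 and 50 at 100% identity fail both gates
    a10 <- strrep("W", 10)
    expect_false(isSimilar(a10, paste0(a10, strrep("G", 40)), cfg)$similar)

    # tier2: short fragments, identity exactly 40 (4/10), inclusive
    a10a <- strrep("A", 10)
    b40 <- "ATTATTATTA"              # matches at 1,4,7,10 -> 40%
    expect_equal(percentIdentity(a10a, b40), 40)
    r <- isSimilar(a10a, b40, cfg)
    expect_true(r$similar); expect_equal(r$tier, "tier2")
    # 30% misses the tier2 threshold
    b30 <- "ATTATTTTTA"              # matches at 1,4,10 -> 30%
    expect_false(isSimilar(a10a, b30, cfg)$similar)

    # tier2 length gate is exclusive at 20 residues
    a19 <- strrep("A", 19)
    b19 <- "ATTAATTAATTAATTAATA"    # 10/19 = 52.6%: tier2 only
    r <- isSimilar(a19, b19, cfg)
    expect_true(r$similar); expect_equal(r$tier, "tier2")
    a20b <- strrep("A", 20)
    b20 <- "ATTAATTAATTAATTAATAA"   # same identity class at length 20
    expect_false(isSimilar(a20b, b20, cfg)$similar)

    # tier2 length-difference gate is exclusive at 8
    a12 <- strrep("A", 12)
    b19id <- strrep("A", 19)         # diff 7, identity 100 -> tier1 anyway
    r <- isSimilar(a12, b19id, cfg)
    expect_true(r$similar); expect_equal(r$tier, "tier1")

    # a pair passing both tiers is labelled tier1
    a6 <- "MVHLTP"
    r <- isSimilar(a6, a6, cfg)
    expect_equal(r$tier, "tier1")
})

test_that("every emitted edge satisfies at least one full tier conjunction", {
    fix <- simulateProteome(seed = 3, nKeps = 4, nDecoysPerClass = 2)
    calls <- mineProteome(fix$precursors)
    cfg <- miningConfig(calls)
    for (id in names(similarityEdges(calls))) {
        ed <- similarityEdges(calls, id)
        if (nrow(ed) == 0) next
        fr <- fragments(calls, id)
        expect_true(all(ed$i < ed$j))   # self-pairs never evaluated
        expect_true(all(ed$identity >= 0 & ed$identity <= 100))
        for (k in seq_len(nrow(ed))) {
            r <- isSimilar(fr$sequence[ed$i[k]], fr$sequence[ed$j[k]], cfg)
            expect_true(r$similar)
            expect_equal(r$tier, ed$tier[k])
        }
    }
})

test_that("callKep applies the published filters with reasons", {
    kep <- paste0("M", strrep("L", 18), strrep("QYKAPSWKR", 3))
    ck <- callKep(kep, hasSignal = TRUE)
    expect_true(ck$accepted)
    # the middle repeat fragment has 2 similar partners at 100% identity
    expect_equal(ck$max_degree, 2L)
    expect_true(all(ck$edges$identity == 100))

    expect_equal(callKep(kep, hasSignal = FALSE)$reject_reason, "no_signal")

    long <- paste0(kep, strrep("G", 850 - nchar(kep)))
    ckLong <- callKep(long, hasSignal = TRUE)
    expect_equal(ckLong$reject_reason, "too_long")
    expect_false(ckLong$accepted)

    one <- paste0("M", strrep("L", 18), "AAAKRGGG")
    expect_equal(callKep(one, hasSignal = TRUE)$reject_reason,
                 "too_few_sites")

    expect_error(callKep(kep, hasSignal = NA), "signal")
})

test_that("mineProteome is deterministic, order-preserving and errors on missing annotations", {
    expect_equal(length(mineProteome(
        PrecursorSet(setNames(character(0), character(0))))), 0L)

    fix <- simulateProteome(seed = 5, nKeps = 3, nDecoysPerClass = 1)
    c1 <- mineProteome(fix$precursors)
    c2 <- mineProteome(fix$precursors)
    expect_identical(as.data.frame(kepCalls(c1)),
                     as.data.frame(kepCalls(c2)))
    expect_identical(kepCalls(c1)$protein_id, names(fix$precursors))

    noAnnot <- PrecursorSet(c(p1 = "MKRAKRA"))
    expect_error(mineProteome(noAnnot), "p1")
})

test_that("filters are monotone in their thresholds", {
    fix <- simulateProteome(seed = 9, nKeps = 5, nDecoysPerClass = 3)
    base <- acceptedIds(mineProteome(fix$precursors))
    # raising tier1 identity never adds a call
    strict <- acceptedIds(mineProteome(
        fix$precursors, MiningConfig(tier1MinIdentity = 100)))
    expect_true(all(strict %in% base))
    # raising the length cap never removes a call
    loose <- acceptedIds(mineProteome(
        fix$precursors, MiningConfig(maxProteinLength = 2000)))
    expect_true(all(base %in% loose))
})
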