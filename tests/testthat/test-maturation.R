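test_that("KEX1 trimming removes C-terminal basic residues stepwise", {
    v <- kex1Trim("QYKAPSWKR")
    expect_equal(v$sequence, c("QYKAPSWKR", "QYKAPSWK", "QYKAPSW"))
    expect_equal(v$canonical, c(FALSE, FALSE, TRUE))

    expect_equal(kex1Trim("GG")$sequence, "GG")

    # stops at the trim budget, not at the first non-basic residue
    expect_equal(kex1Trim("GKRK", maxTrim = 2)$sequence,
                 c("GKRK", "GKR", "GK"))
    # ... and at the first non-basic residue when the budget is larger
    expect_equal(kex1Trim("GAKR", maxTrim = 4)$sequence,
                 c("GAKR", "GAK", "GA"))

    # an all-basic fragment trims to the empty string
    expect_equal(kex1Trim("KR", maxTrim = 2)$sequence, c("KR", "K", ""))
    expect_error(kex1Trim(""))
})

test_that("STE13 trimming removes N-terminal XP/XA dipeptides iteratively", {
    v <- ste13Trim("EADAQMRPPSW")
    expect_equal(v$sequence, c("EADAQMRPPSW", "DAQMRPPSW", "QMRPPSW"))
    expect_equal(v$n_removed, 0:2)

    expect_equal(ste13Trim("W")$sequence, "W")
    expect_equal(ste13Trim("APAP")$sequence, c("APAP", "AP", ""))

    # only the terminal form without intermediates
    expect_equal(ste13Trim("EADAQMRPPSW", emitIntermediates = FALSE)$sequence,
                 "QMRPPSW")

    # configurable second-residue set
    expect_equal(ste13Trim("ESQW", secondResidues = "S")$sequence,
                 c("ESQW", "QW"))
})

test_that("pyroglutamate variants apply only to N-terminal glutamine", {
    v <- pyrogluVariants("QVPVDEPA")
    expect_equal(v$modifications, c("", "pyroGlu"))
    expect_equal(v$mass_delta[2], -ORACLE_NH3, tolerance = 1e-6)

    expect_equal(pyrogluVariants("AVPVDEPA")$modifications, "")
    expect_equal(nrow(pyrogluVariants("Q")), 2L)
    expect_equal(pyrogluVariants("QVP", enabled = FALSE)$modifications, "")
})

test_that("monoisotopic masses agree with an independent residue-mass summation", {
    for (s in c("GPPAPSW", "G", "QVPVDEPA", "QYKAPSW", "QMRPPSW",
                "DDDPEGPPAPSW", "SGTGEASAADW", "QIPAELPTKSINGNIEPYKV",
                "W", "ACDEFGHIKLMNPQRSTVWY"))
        expect_equal(monoisotopicMass(s), oracleMass(s), tolerance = 2e-6)

    # worked constant: GPPAPSW
    expect_equal(monoisotopicMass("GPPAPSW"), 710.338775, tolerance = 1e-4)
    expect_equal(monoisotopicMass("G"), 75.032028, tolerance = 1e-4)

    # pyro-Q is a pure mass delta
    expect_equal(monoisotopicMass("QVPVDEPA", "pyroGlu"),
                 monoisotopicMass("QVPVDEPA") - 17.026549,
                 tolerance = 1e-9)

    expect_error(monoisotopicMass("AXB"), "non-standard")
    expect_error(monoisotopicMass("AAA", "nosuchmod"), "unknown")
})

test_that("mass is additive over concatenation", {
    set.seed(33)
    for (rep in 1:50) {
        a <- randomSeq(sample(1:30, 1))
        b <- randomSeq(sample(1:30, 1))
        expect_equal(monoisotopicMass(paste0(a, b)),
                     monoisotopicMass(a) + monoisotopicMass(b) -
                         18.010565, tolerance = 1e-6)
    }
})

test_that("composed maturation reproduces the expected peptide forms", {
    prec <- paste0("M", strrep("L", 18),
                   "EADAQMRPPSWKR", "EAQYKAPSWRR", "EAQYKAPSWRR")
    ps <- PrecursorSet(c(kep1 = prec), hasSignal = TRUE,
                       signalCleavagePos = 19L)
    pep <- enumerateMaturePeptides(ps)

    expect_true(any(pep$sequence == "QMRPPSW" & pep$modifications == ""))
    expect_true(any(pep$sequence == "QMRPPSW" &
                    pep$modifications == "pyroGlu"))
    expect_true(any(pep$sequence == "QYKAPSW" & pep$modifications == ""))
    expect_true(any(pep$sequence == "QYKAPSW" &
                    pep$modifications == "pyroGlu"))

    # identical repeats collapse with multiplicity
    expect_equal(pep$multiplicity[pep$sequence == "QYKAPSW" &
                                  pep$modifications == ""], 2L)

    # pyro-Q mass relation
    m0 <- pep$monoisotopic_mass[pep$sequence == "QYKAPSW" &
                                pep$modifications == ""]
    m1 <- pep$monoisotopic_mass[pep$sequence == "QYKAPSW" &
                                pep$modifications == "pyroGlu"]
    expect_equal(m1, m0 - 17.026549, tolerance = 1e-6)
    expect_equal(m0, oracleMass("QYKAPSW"), tolerance = 2e-6)

    # every peptide is the precursor substring at its coordinates
    expect_identical(pep$sequence,
                     substring(prec, pep$start, pep$end))
})

test_that("recorded provenance replays to the emitted peptide", {
    prec <- paste0("M", strrep("L", 18),
                   "EADAQMRPPSWKR", "EAQYKAPSWRR", "EAQYKAPSWRR")
    ps <- PrecursorSet(c(kep1 = prec), hasSignal = TRUE,
                       signalCleavagePos = 19L)
    cfg <- MaturationConfig(maxCTruncation = 1)
    pep <- enumerateMaturePeptides(ps, cfg)
    for (k in seq_len(nrow(pep))) {
        fr <- parentFragment(prec, 19L, pep$start[k], cfg)
        expect_equal(nrow(fr), 1L)
        re <- replayProvenance(fr$sequence, pep$provenance[k])
        expect_identical(re$sequence, pep$sequence[k])
        expect_identical(paste(re$modifications, collapse = ","),
                         pep$modifications[k])
    }
})

test_that("enabling optional steps only adds peptides", {
    prec <- paste0("M", strrep("L", 18),
                   "EAQIPAELPTWKR", "GGSWRAAPSWKK", "EAQIPAELPTWKR")
    ps <- PrecursorSet(c(p = prec), hasSignal = TRUE,
                       signalCleavagePos = 19L)
    base <- enumerateMaturePeptides(ps)
    keys <- function(x) paste(x$sequence, x$modifications)
    for (cfg in list(MaturationConfig(maxCTruncation = 2),
                     MaturationConfig(monobasic = TRUE),
                     MaturationConfig(maxKex1Trim = 3))) {
        more <- enumerateMaturePeptides(ps, cfg)
        expect_true(all(keys(base) %in% keys(more)))
    }
})

test_that("degenerate inputs follow the stated conventions", {
    # no cleavage sites and all optional steps disabled: the mature
    # protein is the single peptide
    ps <- PrecursorSet(c(p = paste0("M", strrep("L", 18), "GAVSTNW")),
                       hasSignal = TRUE, signalCleavagePos = 19L)
    cfg <- MaturationConfig(maxKex1Trim = 0, ste13Enabled = FALSE,
                            pyrogluEnabled = FALSE)
    pep <- enumerateMaturePeptides(ps, cfg)
    expect_equal(nrow(pep), 1L)
    expect_equal(pep$sequence, "GAVSTNW")
    expect_equal(pep$start, 20L)

    # STE13 applies only to fragments whose N-terminus is a cut: without
    # a signal cleavage position the first fragment keeps its dipeptides
    ps2 <- PrecursorSet(c(p = "EAQWWWKREAQWWWKR"), hasSignal = NA)
    pep2 <- enumerateMaturePeptides(ps2)
    qw <- pep2[pep2$sequence == "QWWW", , drop = FALSE]
    expect_true(all(qw$start == 11L))

    # length filter drops sub-minimal peptides
    expect_true(all(nchar(pep2$sequence) >= 2))
})
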