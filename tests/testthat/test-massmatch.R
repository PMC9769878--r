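makePeptideTable <- function(seqs, mods = rep("", length(seqs))) {
    S4Vectors::DataFrame(
        precursor_id = "p", start = seq_along(seqs),
        end = seq_along(seqs) + nchar(seqs) - 1L,
        sequence = seqs, modifications = mods,
        provenance = "kex2_cut", multiplicity = 1L,
        monoisotopic_mass = monoisotopicMass(seqs, mods))
}

test_that("ppm matching honours the inclusive 10 ppm boundary", {
    pep <- makePeptideTable("GPPAPSW")
    theo <- pep$monoisotopic_mass

    hit <- matchMasses(theo, pep)
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$ppm_error, 0)

    # exactly +10 ppm and -10 ppm both match (inclusive, symmetric)
    for (sgn in c(1, -1)) {
        hit <- matchMasses(theo * (1 + sgn * 1e-5), pep)
        expect_equal(nrow(hit), 1L)
        expect_equal(hit$ppm_error, sgn * 10, tolerance = 1e-6)
    }
    # just outside
    expect_equal(nrow(matchMasses(theo * (1 + 1.1e-5), pep)), 0L)
    expect_equal(nrow(matchMasses(711.0, pep)), 0L)

    # ppm is signed and computed against the theoretical mass
    hit <- matchMasses(theo * (1 - 0.5e-5), pep)
    expect_lt(hit$ppm_error, 0)
})

test_that("matching equals a brute-force double loop and is monotone in tolerance", {
    set.seed(44)
    seqs <- vapply(1:40, function(i) randomSeq(sample(5:25, 1)), "")
    pep <- makePeptideTable(seqs)
    obs <- S4Vectors::DataFrame(
        sample_id = paste0("s", 1:30),
        observed_mass = sample(pep$monoisotopic_mass, 30, replace = TRUE) *
            (1 + runif(30, -2e-5, 2e-5)))

    hits <- matchMasses(obs, pep, ppmTol = 10)
    oracle <- oracleMatch(obs$observed_mass, pep$monoisotopic_mass, 10)
    expect_equal(nrow(hits), nrow(oracle))
    gotKeys <- sort(paste(match(hits$sample_id, obs$sample_id),
                          hits$sequence))
    expKeys <- sort(paste(oracle$i, pep$sequence[oracle$j]))
    expect_identical(gotKeys, expKeys)

    # widening the tolerance never removes a match
    wide <- matchMasses(obs, pep, ppmTol = 25)
    expect_true(all(paste(hits$sample_id, hits$sequence, hits$start) %in%
                    paste(wide$sample_id, wide$sequence, wide$start)))

    # |ppm| respects the tolerance and results are sorted within each mass
    expect_true(all(abs(hits$ppm_error) <= 10 + 1e-9))
    for (s in unique(hits$sample_id)) {
        e <- abs(hits$ppm_error[hits$sample_id == s])
        expect_true(!is.unsorted(e))
    }
})

test_that("variable modification deltas extend the search space", {
    pep <- makePeptideTable("SGTGEASAADW")
    ox <- modificationDeltas()["oxidation"]
    obs <- pep$monoisotopic_mass + ox
    expect_equal(nrow(matchMasses(obs, pep)), 0L)
    hit <- matchMasses(obs, pep, variableDeltas = ox)
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$modifications, "oxidation")
})

test_that("sequence matching is exact, canonicalized and modification-aware", {
    pep <- makePeptideTable(c("QYKAPSW", "QYKAPSW", "QYKAPS"),
                            mods = c("", "pyroGlu", ""))
    obs <- data.frame(sample_id = c("a", "b", "c"),
                      reported_sequence = c("QYKAPSW", "qykapsw", "QYKAP"))
    m <- matchSequences(obs, pep)
    # both modification states are reported for the matching sequence
    expect_equal(sum(m$sample_id == "a"), 2L)
    expect_setequal(m$modifications[m$sample_id == "a"], c("", "pyroGlu"))
    # lower case is canonicalized before matching
    expect_equal(sum(m$sample_id == "b"), 2L)
    # no substring logic
    expect_equal(sum(m$sample_id == "c"), 0L)
})

test_that("matcher rejects invalid inputs", {
    pep <- makePeptideTable("GPPAPSW")
    expect_error(matchMasses(-1, pep), "positive")
    expect_error(matchMasses(data.frame(x = 1), pep), "sample_id")
    expect_error(matchMasses(700, pep, ppmTol = 0))
})
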