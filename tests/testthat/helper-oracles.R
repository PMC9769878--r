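# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomSeq <- function(n, alphabet = AA20) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- cleavage-site oracle: test every dipeptide window independently -----
oracleCleavageSites <- function(seq, motifs = c("KR", "RR", "KK", "RK"),
                                monobasic = FALSE) {
    ch <- strsplit(seq, "")[[1]]
    cuts <- integer(0)
    if (length(ch) >= 2) {
        for (i in 2:length(ch)) {
            if (paste0(ch[i - 1], ch[i]) %in% motifs)
                cuts <- c(cuts, i)
        }
    }
    if (monobasic) {
        dib <- cuts
        for (i in seq_along(ch)) {
            if (!ch[i] %in% c("K", "R")) next
            partOfMotif <- (i %in% dib) || ((i + 1) %in% dib)
            if (!partOfMotif) cuts <- c(cuts, i)
        }
    }
    sort(unique(cuts))
}

# --- monoisotopic-mass oracle: frozen literal residue masses -------------
# (independent hand summation; values from a standard residue-mass table)
ORACLE_AA_MASS <- c(
    G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
    V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
    I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
    K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
    F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)
ORACLE_WATER <- 18.010565
ORACLE_NH3 <- 17.026549

oracleMass <- function(seq) {
    sum(ORACLE_AA_MASS[strsplit(seq, "")[[1]]]) + ORACLE_WATER
}

# --- ppm-matching oracle: brute-force double loop ------------------------
oracleMatch <- function(observedMasses, theoreticalMasses, tol) {
    hits <- list()
    for (i in seq_along(observedMasses)) {
        for (j in seq_along(theoreticalMasses)) {
            ppm <- 1e6 * (observedMasses[i] - theoreticalMasses[j]) /
                theoreticalMasses[j]
            if (abs(ppm) <= tol + 1e-9)
                hits[[length(hits) + 1]] <- c(i = i, j = j, ppm = ppm)
        }
    }
    if (length(hits) == 0)
        return(data.frame(i = integer(0), j = integer(0), ppm = numeric(0)))
    as.data.frame(do.call(rbind, hits))
}

# --- exhaustive local-alignment oracle (tiny sequences only) -------------
# Enumerates every canonical local alignment (starts and ends with an
# aligned column; gap runs between aligned columns) under affine gap
# penalties and returns all (score, matches, columns) triples.
oracleLocalAlignments <- function(a, b, gapOpen = 11, gapExt = 1) {
    B <- local({
        e <- new.env()
        utils::data(list = "BLOSUM62", package = "Biostrings", envir = e)
        get("BLOSUM62", envir = e)
    })
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    res <- list()
    extend <- function(i, j, score, matches, cols) {
        # alignment currently ends with aligned column (i, j): record it
        res[[length(res) + 1]] <<- c(score = score, matches = matches,
                                     cols = cols)
        # continue with a gap run in a (da) and/or b (db), then an aligned
        # column; runs in both sequences at once are dominated and omitted
        for (da in 0:(length(ca) - i)) {
            for (db in 0:(length(cb) - j)) {
                if (da > 0 && db > 0) next
                ni <- i + da + 1; nj <- j + db + 1
                if (ni > length(ca) || nj > length(cb)) next
                pen <- 0
                if (da > 0) pen <- pen + gapOpen + da * gapExt
                if (db > 0) pen <- pen + gapOpen + db * gapExt
                s <- B[ca[ni], cb[nj]]
                extend(ni, nj, score - pen + s,
                       matches + (ca[ni] == cb[nj]),
                       cols + da + db + 1)
            }
        }
    }
    for (i in seq_along(ca)) {
        for (j in seq_along(cb)) {
            extend(i, j, B[ca[i], cb[j]],
                   as.integer(ca[i] == cb[j]), 1)
        }
    }
    as.data.frame(do.call(rbind, res))
}

# identity values of all optimal alignments; 0 when no positive score
oracleIdentitySet <- function(a, b) {
    al <- oracleLocalAlignments(a, b)
    best <- max(al$score)
    if (best <= 0) return(0)
    opt <- al[al$score == best, , drop = FALSE]
    unique(100 * opt$matches / opt$cols)
}

# --- misc ----------------------------------------------------------------
# parent KEX2 fragment of a predicted peptide, for provenance replay
parentFragment <- function(precursorSeq, sigPos, pepStart, config) {
    matStart <- if (!is.na(sigPos)) sigPos + 1L else 1L
    mature <- substring(precursorSeq, matStart)
    fr <- fragmentSequence(
        mature, findCleavageSites(mature, motifs = config@motifs,
                                  monobasic = config@monobasic))
    fr$startPrec <- fr$start + matStart - 1L
    fr$endPrec <- fr$end + matStart - 1L
    hit <- which(fr$startPrec <= pepStart & fr$endPrec >= pepStart)
    fr[hit, , drop = FALSE]
}
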