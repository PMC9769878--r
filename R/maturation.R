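# Peptide maturation model: KEX2 endoproteolysis composed with KEX1
# carboxypeptidase trimming, STE13 dipeptidyl-aminopeptidase trimming,
# N-terminal pyroglutamate formation and optional C-terminal truncation.

# Monoisotopic element masses (most abundant isotope).
.ELEMENT_MASS <- c(H = 1.00782503207, C = 12.0, N = 14.0030740048,
                   O = 15.9949146196, S = 31.97207100)

.formulaMass <- function(counts) {
    sum(.ELEMENT_MASS[names(counts)] * counts)
}

# Residue (i.e. dehydrated) elemental compositions of the 20 standard
# amino acids: c(C, H, N, O, S).
.RESIDUE_FORMULA <- list(
    G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0),
    A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0),
    S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0),
    P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0),
    V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0),
    T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0),
    C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
    L = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
    I = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
    N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0),
    D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0),
    Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0),
    K = c(C = 6,  H = 12, N = 2, O = 1, S = 0),
    E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0),
    M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
    H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0),
    F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0),
    R = c(C = 6,  H = 12, N = 4, O = 1, S = 0),
    Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0),
    W = c(C = 11, H = 10, N = 2, O = 1, S = 0))

.RESIDUE_MASS <- vapply(.RESIDUE_FORMULA, .formulaMass, numeric(1))
.WATER_MASS <- .formulaMass(c(H = 2, O = 1))
.NH3_MASS <- .formulaMass(c(N = 1, H = 3))

# Mass deltas of supported modifications, in Da. pyroGlu is the only
# modification the maturation model enumerates; the remaining entries are
# available to the mass matcher as optional variable modifications.
.MOD_DELTA <- c(
    pyroGlu = -.formulaMass(c(N = 1, H = 3)),               # Gln - NH3
    amidation = .formulaMass(c(N = 1, H = 3)) -
        .formulaMass(c(O = 1, H = 2)),                      # -OH +NH2
    oxidation = .formulaMass(c(O = 1)),
    hydroxylation = .formulaMass(c(O = 1)),
    methylation = .formulaMass(c(C = 1, H = 2)))

#' Mass deltas of the supported peptide modifications
#'
#' @return Named numeric vector of monoisotopic mass deltas in Da
#'   (`pyroGlu` = -17.026549; plus `amidation`, `oxidation`,
#'   `hydroxylation`, `methylation` for use as variable modifications in
#'   mass matching).
#' @examples
#' modificationDeltas()["pyroGlu"]
#' @export
modificationDeltas <- function() .MOD_DELTA

#' Monoisotopic mass of a peptide
#'
#' Sum of the standard monoisotopic residue masses plus one water
#' (18.010565 Da), plus the deltas of any modifications.
#'
#' @param sequence Character vector of peptide sequences (standard
#'   residues only).
#' @param modifications `NULL`, a character vector of comma-joined
#'   modification names per peptide (`""` for none), or a list of character
#'   vectors. Names must be among `names(modificationDeltas())`.
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' monoisotopicMass("GPPAPSW")                   # 710.338775
#' monoisotopicMass("QVPVDEPA", "pyroGlu")
#' @export
monoisotopicMass <- function(sequence, modifications = NULL) {
    sequence <- as.character(sequence)
    if (any(!nzchar(sequence)))
        stop("sequences must be non-empty")
    if (any(!.isStandardSeq(sequence)))
        stop("non-standard residue in: ",
             paste(sequence[!.isStandardSeq(sequence)], collapse = ", "))
    base <- vapply(strsplit(sequence, ""), function(ch)
        sum(.RESIDUE_MASS[ch]), numeric(1)) + .WATER_MASS
    if (is.null(modifications)) return(base)
    if (is.character(modifications))
        modifications <- strsplit(modifications, ",", fixed = TRUE)
    modifications <- rep_len(modifications, length(sequence))
    delta <- vapply(modifications, function(m) {
        m <- m[nzchar(m)]
        if (length(m) == 0) return(0)
        unknown <- setdiff(m, names(.MOD_DELTA))
        if (length(unknown) > 0)
            stop("unknown modification(s): ", paste(unknown, collapse = ", "))
        sum(.MOD_DELTA[m])
    }, numeric(1))
    base + delta
}

#' KEX1 carboxypeptidase trim variants
#'
#' Removes up to `maxTrim` C-terminal basic residues (K/R) one at a time,
#' stopping at the first non-basic residue. All intermediate variants are
#' returned, ordered by trim count; the fully trimmed form is flagged as
#' the canonical KEX1 product.
#'
#' @param sequence A single non-empty peptide sequence.
#' @param maxTrim Maximum number of residues removed (default 2, the size
#'   of a dibasic motif).
#' @return A `DataFrame` with columns `sequence`, `n_trimmed` and
#'   `canonical`. A fragment consisting solely of K/R trims to the empty
#'   string, which downstream length filters discard.
#' @examples
#' kex1Trim("QYKAPSWKR")   # QYKAPSWKR, QYKAPSWK, QYKAPSW (canonical)
#' @export
kex1Trim <- function(sequence, maxTrim = 2) {
    stopifnot(is.character(sequence), length(sequence) == 1L,
              nzchar(sequence))
    ch <- strsplit(sequence, "")[[1L]]
    run <- 0L
    for (k in rev(seq_along(ch))) {
        if (ch[k] %in% c("K", "R")) run <- run + 1L else break
    }
    tmax <- min(run, as.integer(maxTrim))
    n <- nchar(sequence)
    trims <- 0:tmax
    S4Vectors::DataFrame(
        sequence = substring(sequence, 1L, n - trims),
        n_trimmed = trims,
        canonical = trims == tmax)
}

#' STE13 dipeptidyl-aminopeptidase trim variants
#'
#' Iteratively removes N-terminal dipeptides whose second residue is in
#' `secondResidues` (the XP/XA recognition motif; X is often D or E),
#' two residues at a time, until the rule no longer applies.
#'
#' @param sequence A single non-empty peptide sequence.
#' @param secondResidues Residues allowed at the second dipeptide position
#'   (default A and P).
#' @param emitIntermediates Return every intermediate (default) or only the
#'   terminal form.
#' @return A `DataFrame` with columns `sequence` and `n_removed` (number of
#'   dipeptides removed). The terminal variant may be the empty string,
#'   which downstream length filters discard.
#' @examples
#' ste13Trim("EADAQMRPPSW")   # EADAQMRPPSW, DAQMRPPSW, QMRPPSW
#' @export
ste13Trim <- function(sequence, secondResidues = c("A", "P"),
                      emitIntermediates = TRUE) {
    stopifnot(is.character(sequence), length(sequence) == 1L,
              nzchar(sequence))
    seqs <- sequence
    cur <- sequence
    while (nchar(cur) >= 2 && substr(cur, 2L, 2L) %in% secondResidues) {
        cur <- substring(cur, 3L)
        seqs <- c(seqs, cur)
    }
    out <- S4Vectors::DataFrame(sequence = seqs,
                                n_removed = seq_along(seqs) - 1L)
    if (!emitIntermediates)
        out <- out[nrow(out), , drop = FALSE]
    out
}

#' Pyroglutamate variants of a peptide
#'
#' When the sequence begins with glutamine (Q) and pyroglutamate formation
#' is enabled, two variants are returned: unmodified and pyro-Q (loss of
#' NH3, -17.026549 Da). Otherwise only the unmodified form. N-terminal
#' glutamate cyclization is not modelled.
#'
#' @param sequence A single peptide sequence.
#' @param enabled Model the modification (default `TRUE`).
#' @return A `DataFrame` with columns `modifications` (`""` or
#'   `"pyroGlu"`) and `mass_delta`.
#' @examples
#' pyrogluVariants("QVPVDEPA")
#' @export
pyrogluVariants <- function(sequence, enabled = TRUE) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (enabled && startsWith(sequence, "Q"))
        S4Vectors::DataFrame(modifications = c("", "pyroGlu"),
                             mass_delta = c(0, unname(.MOD_DELTA["pyroGlu"])))
    else
        S4Vectors::DataFrame(modifications = "", mass_delta = 0)
}

#' Replay a recorded maturation provenance
#'
#' Applies an ordered step list (as found in the `provenance` column of
#' [enumerateMaturePeptides()] output) to a parent KEX2 fragment and
#' returns the resulting sequence and modification set. Used to verify
#' that recorded provenance reproduces each peptide exactly.
#'
#' @param fragment The parent fragment sequence.
#' @param steps Character vector of steps (`kex2_cut`, `kex1_trim`,
#'   `ste13_trim`, `c_trunc`, `pyroglu`), or a single comma-joined string.
#' @param ste13SecondResidues Residues accepted at the second dipeptide
#'   position during `ste13_trim` steps.
#' @return A list with `sequence` and `modifications`.
#' @examples
#' replayProvenance("QYKAPSWKR", c("kex2_cut", "kex1_trim", "kex1_trim"))
#' @export
replayProvenance <- function(fragment, steps,
                             ste13SecondResidues = c("A", "P")) {
    if (length(steps) == 1L && grepl(",", steps))
        steps <- strsplit(steps, ",", fixed = TRUE)[[1L]]
    cur <- fragment
    mods <- character(0)
    for (s in steps) {
        switch(s,
            kex2_cut = NULL,
            kex1_trim = {
                last <- substr(cur, nchar(cur), nchar(cur))
                if (!last %in% c("K", "R"))
                    stop("kex1_trim on non-basic C-terminus: ", cur)
                cur <- substring(cur, 1L, nchar(cur) - 1L)
            },
            ste13_trim = {
                if (nchar(cur) < 2 ||
                    !substr(cur, 2L, 2L) %in% ste13SecondResidues)
                    stop("ste13_trim does not apply to: ", cur)
                cur <- substring(cur, 3L)
            },
            c_trunc = cur <- substring(cur, 1L, nchar(cur) - 1L),
            pyroglu = {
                if (!startsWith(cur, "Q"))
                    stop("pyroglu on a sequence not starting with Q: ", cur)
                mods <- c(mods, "pyroGlu")
            },
            stop("unknown provenance step: ", s))
    }
    list(sequence = cur, modifications = mods)
}

#' Enumerate predicted mature peptides of a precursor set
#'
#' For each precursor the signal region is excised when its cleavage
#' position is known (the mature N-terminus then corresponds to the
#' signal-peptidase cut), the remainder is cleaved at KEX2 sites (dibasic;
#' with `monobasic` enabled, cleavage after isolated K/R is modelled as
#' partial, so fragments of both the dibasic-only and the full cleavage
#' pattern are considered), and each fragment is expanded through KEX1
#' trim variants, STE13 trim variants (only for fragments whose N-terminus
#' is a KEX2 or signal-peptidase cut), optional C-terminal truncations and
#' pyroglutamate variants, then filtered on length.
#'
#' Exact duplicates on (start, end, modifications) arising from alternative
#' step paths are dropped (the shortest provenance is kept); identical
#' (sequence, modifications) entries from different repeat copies collapse
#' to one row whose `multiplicity` records the number of distinct loci.
#'
#' @param precursors A [PrecursorSet] (signal annotations may be `NA`; no
#'   excision is then performed).
#' @param config A [MaturationConfig].
#' @return A `DataFrame` with columns `precursor_id`, `start`, `end`
#'   (1-based inclusive precursor coordinates of the retained residues),
#'   `sequence`, `modifications` (comma-joined, `""` for none),
#'   `provenance` (comma-joined ordered step list), `multiplicity` and
#'   `monoisotopic_mass`; ordered by precursor, start, end, modifications.
#' @examples
#' ps <- PrecursorSet(
#'     c(kep = paste0("M", strrep("L", 18), strrep("EAQYKAPSWRR", 3))),
#'     hasSignal = TRUE, signalCleavagePos = 19L)
#' pep <- enumerateMaturePeptides(ps)
#' pep[pep$sequence == "QYKAPSW", ]
#' @export
enumerateMaturePeptides <- function(precursors,
                                    config = MaturationConfig()) {
    stopifnot(is(precursors, "PrecursorSet"))
    res <- lapply(seq_along(precursors), function(k)
        .maturePeptidesOne(names(precursors)[k],
                           as.character(precursors[[k]]),
                           S4Vectors::mcols(precursors)$signal_cleavage_pos[k],
                           config))
    do.call(rbind, res)
}

.maturePeptidesOne <- function(id, seq, sigPos, config) {
    matStart <- if (!is.na(sigPos)) as.integer(sigPos) + 1L else 1L
    mature <- substring(seq, matStart)
    sites <- findCleavageSites(mature, motifs = config@motifs,
                               monobasic = FALSE)
    frags <- fragmentSequence(mature, sites)
    if (config@monobasic) {
        # monobasic cleavage is partial in vivo: products of both the
        # dibasic-only and the full cleavage pattern coexist
        all <- fragmentSequence(mature,
            findCleavageSites(mature, motifs = config@motifs,
                              monobasic = TRUE))
        new <- !(paste(all$start, all$end) %in%
                 paste(frags$start, frags$end))
        frags <- rbind(frags, all[new, , drop = FALSE])
    }
    rows <- list()
    for (f in seq_len(nrow(frags))) {
        fragSeq <- frags$sequence[f]
        if (!.isStandardSeq(fragSeq)) next   # ambiguity codes: not matured
        fragStart <- frags$start[f] + matStart - 1L
        # N-terminus is a processing cut unless this is the first fragment
        # of a precursor whose signal cleavage position is unknown
        nTermIsCut <- frags$start[f] > 1L || matStart > 1L
        k1 <- kex1Trim(fragSeq, maxTrim = config@maxKex1Trim)
        for (a in seq_len(nrow(k1))) {
            t <- k1$n_trimmed[a]
            s1 <- k1$sequence[a]
            if (!nzchar(s1)) next
            st13 <- if (config@ste13Enabled && nTermIsCut)
                ste13Trim(s1, secondResidues = config@ste13SecondResidues,
                          emitIntermediates = config@ste13EmitIntermediates)
            else S4Vectors::DataFrame(sequence = s1, n_removed = 0L)
            for (b in seq_len(nrow(st13))) {
                s2 <- st13$sequence[b]
                nd <- st13$n_removed[b]
                if (!nzchar(s2)) next
                for (ct in 0:min(config@maxCTruncation, nchar(s2) - 1L)) {
                    s3 <- substring(s2, 1L, nchar(s2) - ct)
                    L <- nchar(s3)
                    if (L < config@minPeptideLength ||
                        L > config@maxPeptideLength) next
                    pg <- pyrogluVariants(s3, enabled = config@pyrogluEnabled)
                    for (v in seq_len(nrow(pg))) {
                        mods <- pg$modifications[v]
                        steps <- c("kex2_cut",
                                   rep("kex1_trim", t),
                                   rep("ste13_trim", nd),
                                   rep("c_trunc", ct),
                                   if (nzchar(mods)) "pyroglu")
                        rows[[length(rows) + 1L]] <- list(
                            start = fragStart + 2L * nd,
                            end = fragStart + nchar(fragSeq) - 1L - t - ct,
                            sequence = s3, modifications = mods,
                            provenance = paste(steps, collapse = ","),
                            mass = monoisotopicMass(s3) + pg$mass_delta[v])
                    }
                }
            }
        }
    }
    if (length(rows) == 0)
        return(S4Vectors::DataFrame(
            precursor_id = character(0), start = integer(0),
            end = integer(0), sequence = character(0),
            modifications = character(0), provenance = character(0),
            multiplicity = integer(0), monoisotopic_mass = numeric(0)))
    tab <- S4Vectors::DataFrame(
        precursor_id = id,
        start = vapply(rows, function(r) as.integer(r$start), 0L),
        end = vapply(rows, function(r) as.integer(r$end), 0L),
        sequence = vapply(rows, `[[`, "", "sequence"),
        modifications = vapply(rows, `[[`, "", "modifications"),
        provenance = vapply(rows, `[[`, "", "provenance"),
        monoisotopic_mass = vapply(rows, `[[`, 0, "mass"))
    # exact duplicates from alternative step paths (same locus, same mods)
    keyLocus <- paste(tab$start, tab$end, tab$modifications, sep = "|")
    tab <- tab[!duplicated(keyLocus), , drop = FALSE]
    # identical peptides from repeated cores: collapse across loci
    keySeq <- paste(tab$sequence, tab$modifications, sep = "|")
    mult <- as.integer(table(factor(keySeq, levels = unique(keySeq))))
    tab <- tab[!duplicated(keySeq), , drop = FALSE]
    tab$multiplicity <- mult
    tab <- tab[order(tab$start, tab$end, tab$modifications), , drop = FALSE]
    tab[, c("precursor_id", "start", "end", "sequence", "modifications",
            "provenance", "multiplicity", "monoisotopic_mass")]
}
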