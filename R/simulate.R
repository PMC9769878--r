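# Deterministic generator of synthetic proteomes with ground-truth
# implanted KEPs and decoy classes, so mining, maturation and matching are
# testable without external data.

.HYDROPHOBIC <- c("A", "L", "V", "I", "F", "M", "W", "S", "T", "G")
.NONBASIC <- setdiff(.AA_STANDARD, c("K", "R"))

.randSeq <- function(n, alphabet) {
    if (n == 0) return("")
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.shuffleSeq <- function(s) {
    ch <- strsplit(s, "")[[1L]]
    paste(sample(ch), collapse = "")
}

#' Generate a synthetic proteome with implanted KEPs and decoys
#'
#' Each implanted KEP is built as Met + a hydrophobic-biased signal region
#' + an optional short leader + k identical copies of (optional XP/XA
#' STE13 prefix + core + dibasic motif) + an optional tail. Core, leader
#' and tail are drawn from the non-basic alphabet so the cleavage-site
#' layout is exactly as designed. Decoy classes each violate one KEP
#' criterion:
#' \describe{
#'   \item{no_signal}{KEP architecture, but annotated without a signal
#'     peptide (the annotation table is authoritative).}
#'   \item{one_site}{a secreted protein with exactly one cut position.}
#'   \item{too_long}{KEP architecture padded beyond the length filter.}
#'   \item{shuffled_repeats}{KEP architecture in which every KEX2 fragment
#'     of the repeat region, including its dibasic motif residues, is
#'     independently residue-shuffled (destroying both repeat similarity
#'     and, usually, part of the cleavage-site layout).}
#'   \item{random_protein}{a secreted protein with two or more cut sites
#'     separating unrelated random segments.}
#' }
#'
#' The same seed yields byte-identical output; the caller's RNG state is
#' left untouched.
#'
#' @param seed Integer seed.
#' @param nKeps Number of implanted KEPs (default 10).
#' @param nDecoysPerClass Decoys per class (default 8).
#' @param repeatCountRange Range of repeat copy numbers (default 3-7).
#' @param coreLengthRange Range of core peptide lengths (default 6-15).
#' @param signalLengthRange Range of signal-region lengths, excluding the
#'   initiator Met (default 16-24).
#' @param leaderLengthRange Range of leader lengths between signal and
#'   first repeat (default 0-4, keeping the first-repeat fragment within
#'   the tier-1 length window of the repeat fragments).
#' @param tailLengthRange Range of C-terminal tail lengths (default 0-8).
#' @param motifs Dibasic motifs sampled for repeat junctions.
#' @param motifProbs Sampling weights over `motifs`.
#' @param ste13PrefixProb Probability that a KEP's cores carry an XP/XA
#'   STE13 prefix (X drawn from D/E; one or two dipeptides; default 0.5).
#' @param decoyClasses Which decoy classes to generate.
#' @return A list with `precursors` (a [PrecursorSet] with signal
#'   annotations attached) and `truth` (a `DataFrame` with columns `id`,
#'   `class`, `is_kep`, `n_repeats`, `repeat_coords` (semicolon-joined
#'   `start-end`, 1-based inclusive unit coordinates) and
#'   `canonical_peptide`, the expected core peptide after KEX1 + STE13).
#' @examples
#' fix <- simulateProteome(seed = 1, nKeps = 3, nDecoysPerClass = 1)
#' fix$truth[fix$truth$is_kep, c("id", "canonical_peptide")]
#' @export
simulateProteome <- function(seed, nKeps = 10, nDecoysPerClass = 8,
                             repeatCountRange = c(3, 7),
                             coreLengthRange = c(6, 15),
                             signalLengthRange = c(16, 24),
                             leaderLengthRange = c(0, 4),
                             tailLengthRange = c(0, 8),
                             motifs = c("KR", "RR", "KK", "RK"),
                             motifProbs = rep(0.25, 4),
                             ste13PrefixProb = 0.5,
                             decoyClasses = c("no_signal", "one_site",
                                              "too_long",
                                              "shuffled_repeats",
                                              "random_protein")) {
    stopifnot(length(seed) == 1L, is.finite(seed))
    if (min(coreLengthRange) < 2)
        stop("infeasible spec: cores must be at least 2 residues")
    decoyClasses <- match.arg(decoyClasses, several.ok = TRUE)
    .withSeed(as.integer(seed), {
        ids <- character(0); seqs <- character(0)
        hasSig <- logical(0); sigPos <- integer(0)
        truth <- list()

        rint <- function(rng) sample(rng[1]:rng[2], 1L)

        makeKepParts <- function() {
            sig <- .randSeq(rint(signalLengthRange), .HYDROPHOBIC)
            lead <- .randSeq(rint(leaderLengthRange), .NONBASIC)
            k <- rint(repeatCountRange)
            core <- .randSeq(rint(coreLengthRange), .NONBASIC)
            prefix <- if (stats::runif(1) < ste13PrefixProb)
                paste(vapply(seq_len(sample(1:2, 1L)), function(i)
                    paste0(sample(c("D", "E"), 1L),
                           sample(c("A", "P"), 1L)), ""), collapse = "")
            else ""
            motif <- sample(motifs, 1L, prob = motifProbs)
            list(sig = sig, lead = lead, k = k, core = core,
                 prefix = prefix, motif = motif,
                 unit = paste0(prefix, core, motif),
                 tail = .randSeq(rint(tailLengthRange), .NONBASIC))
        }

        assemble <- function(p, units = NULL) {
            if (is.null(units)) units <- rep(p$unit, p$k)
            paste0("M", p$sig, p$lead, paste(units, collapse = ""), p$tail)
        }

        addRecord <- function(id, seq, sig, pos, class, isKep,
                              nRep = NA_integer_, coords = "",
                              canonical = NA_character_) {
            ids <<- c(ids, id); seqs <<- c(seqs, seq)
            hasSig <<- c(hasSig, sig); sigPos <<- c(sigPos, pos)
            truth[[length(truth) + 1L]] <<- list(
                id = id, class = class, is_kep = isKep,
                n_repeats = nRep, repeat_coords = coords,
                canonical_peptide = canonical)
        }

        unitCoords <- function(p) {
            u <- nchar(p$unit)
            base <- 1L + nchar(p$sig) + nchar(p$lead)
            st <- base + (seq_len(p$k) - 1L) * u + 1L
            paste(sprintf("%d-%d", st, st + u - 1L), collapse = ";")
        }

        for (i in seq_len(nKeps)) {
            p <- makeKepParts()
            addRecord(sprintf("kep%03d", i), assemble(p), TRUE,
                      1L + nchar(p$sig), "kep", TRUE, p$k,
                      unitCoords(p), p$core)
        }
        for (cls in decoyClasses) for (i in seq_len(nDecoysPerClass)) {
            id <- sprintf("%s%03d", cls, i)
            p <- makeKepParts()
            switch(cls,
                no_signal = addRecord(id, assemble(p), FALSE, NA_integer_,
                                      cls, FALSE),
                one_site = {
                    s <- paste0("M", p$sig, .randSeq(30, .NONBASIC),
                                p$motif, .randSeq(30, .NONBASIC))
                    addRecord(id, s, TRUE, 1L + nchar(p$sig), cls, FALSE)
                },
                too_long = {
                    s <- assemble(p)
                    pad <- .randSeq(810L - nchar(s) + rint(c(0, 60)),
                                    .NONBASIC)
                    addRecord(id, paste0(s, pad), TRUE, 1L + nchar(p$sig),
                              cls, FALSE)
                },
                shuffled_repeats = {
                    units <- vapply(seq_len(p$k),
                                    function(j) .shuffleSeq(p$unit), "")
                    addRecord(id, assemble(p, units), TRUE,
                              1L + nchar(p$sig), cls, FALSE)
                },
                random_protein = {
                    nSeg <- sample(3:6, 1L)
                    segs <- vapply(seq_len(nSeg), function(j)
                        .randSeq(rint(c(10, 50)), .NONBASIC), "")
                    ms <- sample(motifs, nSeg - 1L, replace = TRUE,
                                 prob = motifProbs)
                    body <- paste0(paste0(segs[-nSeg], ms, collapse = ""),
                                   segs[nSeg])
                    addRecord(id, paste0("M", p$sig, body), TRUE,
                              1L + nchar(p$sig), cls, FALSE)
                })
        }
        ps <- PrecursorSet(setNames(seqs, ids), hasSignal = hasSig,
                           signalCleavagePos = sigPos)
        truthTab <- S4Vectors::DataFrame(
            id = vapply(truth, `[[`, "", "id"),
            class = vapply(truth, `[[`, "", "class"),
            is_kep = vapply(truth, `[[`, NA, "is_kep"),
            n_repeats = vapply(truth, `[[`, NA_integer_, "n_repeats"),
            repeat_coords = vapply(truth, `[[`, "", "repeat_coords"),
            canonical_peptide = vapply(truth, `[[`, NA_character_,
                                       "canonical_peptide"))
        list(precursors = ps, truth = truthTab)
    })
}

#' Write a simulated fixture to a directory
#'
#' Writes `proteome.fasta`, `signal.tsv` (columns `id`, `has_signal`,
#' `cleavage_pos`) and `truth.tsv`.
#'
#' @param fixture A list as returned by [simulateProteome()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ps <- fixture$precursors
    fa <- file.path(dir, "proteome.fasta")
    Biostrings::writeXStringSet(ps, fa)
    sig <- data.frame(
        id = names(ps),
        has_signal = ifelse(S4Vectors::mcols(ps)$has_signal, "yes", "no"),
        cleavage_pos = ifelse(
            is.na(S4Vectors::mcols(ps)$signal_cleavage_pos), "",
            as.character(S4Vectors::mcols(ps)$signal_cleavage_pos)))
    sigPath <- file.path(dir, "signal.tsv")
    utils::write.table(sig, sigPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truthPath <- file.path(dir, "truth.tsv")
    utils::write.table(as.data.frame(fixture$truth), truthPath, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    invisible(c(proteome = fa, signal = sigPath, truth = truthPath))
}
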