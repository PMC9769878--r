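# The KEP caller: pairwise fragment identity under the two-tier thresholds,
# a per-protein similarity graph, and the published precursor filters.

.subMatCache <- new.env(parent = emptyenv())

.getSubMatrix <- function(name) {
    if (is.null(.subMatCache[[name]])) {
        e <- new.env()
        utils::data(list = name, package = "Biostrings", envir = e)
        .subMatCache[[name]] <- get(name, envir = e)
    }
    .subMatCache[[name]]
}

# Vectorized identity of many patterns against one fixed subject.
# identity = 100 * identical columns / alignment length (including gaps) of
# the optimal alignment; 0 when no positive-scoring local alignment exists
# or when the alignment spans less than minCoverage of the shorter sequence.
.alignIdentity <- function(patterns, subject, alignType = "local",
                           minCoverage = 0, gapOpening = 11,
                           gapExtension = 1,
                           substitutionMatrix = "BLOSUM62") {
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(patterns), subject,
        type = alignType, substitutionMatrix = .getSubMatrix(substitutionMatrix),
        gapOpening = gapOpening, gapExtension = gapExtension)
    ni <- Biostrings::nindel(aln)
    nm <- Biostrings::nmatch(aln)
    # alignment length including gap columns
    len <- nm + Biostrings::nmismatch(aln) +
        Biostrings::insertion(ni)[, "WidthSum"] +
        Biostrings::deletion(ni)[, "WidthSum"]
    id <- ifelse(len > 0, 100 * nm / len, 0)
    if (alignType == "local")
        id[BiocGenerics::score(aln) <= 0] <- 0
    if (minCoverage > 0) {
        pl <- nchar(patterns)
        sl <- nchar(subject)
        spanP <- BiocGenerics::end(Biostrings::pattern(aln)) -
            BiocGenerics::start(Biostrings::pattern(aln)) + 1L
        spanS <- BiocGenerics::end(Biostrings::subject(aln)) -
            BiocGenerics::start(Biostrings::subject(aln)) + 1L
        span <- ifelse(pl <= sl, spanP, spanS)
        id[len == 0 | span < minCoverage * pmin(pl, sl)] <- 0
    }
    id
}

# Pairwise identities for parallel sequence vectors a, b. Each pair is
# oriented canonically (lexicographically smaller sequence as pattern)
# before alignment so that score ties between co-optimal alignments cannot
# make the result orientation-dependent: identity is symmetric by
# construction. Pairs are grouped by subject for vectorized alignment.
.identityPairs <- function(a, b, alignType = "local", minCoverage = 0,
                           gapOpening = 11, gapExtension = 1,
                           substitutionMatrix = "BLOSUM62") {
    out <- numeric(length(a))
    same <- a == b
    out[same] <- 100
    todo <- which(!same)
    if (length(todo) == 0) return(out)
    pa <- a[todo]; pb <- b[todo]
    swap <- pa > pb
    tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
    for (s in unique(pb)) {
        idx <- pb == s
        out[todo[idx]] <- .alignIdentity(
            pa[idx], s, alignType = alignType, minCoverage = minCoverage,
            gapOpening = gapOpening, gapExtension = gapExtension,
            substitutionMatrix = substitutionMatrix)
    }
    out
}

.identityPairsCfg <- function(a, b, config) {
    .identityPairs(a, b, alignType = config@alignType,
                   minCoverage = config@minAlignmentCoverage,
                   gapOpening = config@gapOpening,
                   gapExtension = config@gapExtension,
                   substitutionMatrix = config@substitutionMatrix)
}

#' Percent identity of two fragment sequences
#'
#' Identity is defined as 100 x (identical aligned positions) / (alignment
#' length including gaps) of the optimal alignment under the configured
#' substitution matrix and affine gap penalties. For local (Smith-Waterman)
#' alignments, 0 is returned when no positive-scoring alignment exists.
#' A `minCoverage` gate (off by default here; the mining screen uses 0.5)
#' additionally returns 0 when the alignment spans less than that fraction
#' of the shorter sequence, standing in for the significance filtering a
#' database-search tool would apply to very short matches.
#'
#' @param a,b Character vectors of fragment sequences (recycled to a common
#'   length); standard amino-acid alphabet only.
#' @param alignType `"local"` (default) or `"overlap"` (global,
#'   end-gap free).
#' @param minCoverage Minimum fraction of the shorter sequence the alignment
#'   must span (default 0).
#' @param gapOpening,gapExtension Affine gap penalties (default 11/1).
#' @param substitutionMatrix Substitution matrix name (default
#'   `"BLOSUM62"`).
#' @return Numeric vector of identities in `[0, 100]`.
#' @examples
#' percentIdentity("QYKAPSW", "QYKAPSW")   # 100
#' percentIdentity("AAAA", "AATA")         # 75
#' percentIdentity("GGGG", "WWWW")         # 0
#' @export
percentIdentity <- function(a, b, alignType = c("local", "overlap"),
                            minCoverage = 0, gapOpening = 11,
                            gapExtension = 1,
                            substitutionMatrix = "BLOSUM62") {
    alignType <- match.arg(alignType)
    n <- max(length(a), length(b))
    a <- rep_len(as.character(a), n)
    b <- rep_len(as.character(b), n)
    if (any(!nzchar(a)) || any(!nzchar(b)))
        stop("sequences must be non-empty")
    if (any(!.isStandardSeq(a)) || any(!.isStandardSeq(b)))
        stop("sequences must use the standard 20-letter alphabet")
    .identityPairs(a, b, alignType = alignType, minCoverage = minCoverage,
                   gapOpening = gapOpening, gapExtension = gapExtension,
                   substitutionMatrix = substitutionMatrix)
}

#' Two-tier similarity rule for a fragment pair
#'
#' Tier 1: length difference fewer than `tier1MaxLenDiff` residues and
#' identity at least `tier1MinIdentity` percent. Tier 2 (short fragments):
#' both fragments shorter than `tier2MaxLen` residues, length difference
#' fewer than `tier2MaxLenDiff`, identity at least `tier2MinIdentity`.
#' A pair is similar when either tier's full conjunction holds. Length
#' bounds are exclusive, identity bounds inclusive.
#'
#' @param a,b Fragment sequences (single strings).
#' @param config A [MiningConfig].
#' @return A list with elements `similar` (logical), `tier` (`"tier1"`,
#'   `"tier2"` or `NA`; tier 1 wins when both hold) and `identity`
#'   (numeric, `NA` when no length gate passed and no alignment was run).
#' @examples
#' isSimilar("QYKAPSW", "QYKAPSW")
#' @export
isSimilar <- function(a, b, config = MiningConfig()) {
    la <- nchar(a); lb <- nchar(b)
    t1gate <- abs(la - lb) < config@tier1MaxLenDiff
    t2gate <- la < config@tier2MaxLen && lb < config@tier2MaxLen &&
        abs(la - lb) < config@tier2MaxLenDiff
    if (!t1gate && !t2gate)
        return(list(similar = FALSE, tier = NA_character_,
                    identity = NA_real_))
    id <- .identityPairsCfg(a, b, config)
    tier1 <- t1gate && id >= config@tier1MinIdentity
    tier2 <- t2gate && id >= config@tier2MinIdentity
    list(similar = tier1 || tier2,
         tier = if (tier1) "tier1" else if (tier2) "tier2" else NA_character_,
         identity = id)
}

# Build the all-pairs similarity graph over eligible fragments.
# Returns list(edges = DataFrame(i, j, identity, tier), maxDegree).
.similarityGraph <- function(fragSeqs, config) {
    scoreSeqs <- fragSeqs
    if (config@stripBasicForMining)
        scoreSeqs <- sub("[KR]+$", "", scoreSeqs)
    eligible <- which(nchar(scoreSeqs) >= config@minFragmentLength &
                      .isStandardSeq(scoreSeqs) & nzchar(scoreSeqs))
    edges <- S4Vectors::DataFrame(i = integer(0), j = integer(0),
                                  identity = numeric(0),
                                  tier = character(0))
    m <- length(eligible)
    if (m >= 2) {
        len <- nchar(scoreSeqs)
        pairs <- utils::combn(eligible, 2L)
        pi <- pairs[1L, ]; pj <- pairs[2L, ]
        diff <- abs(len[pi] - len[pj])
        t1gate <- diff < config@tier1MaxLenDiff
        t2gate <- len[pi] < config@tier2MaxLen &
            len[pj] < config@tier2MaxLen & diff < config@tier2MaxLenDiff
        keep <- t1gate | t2gate
        pi <- pi[keep]; pj <- pj[keep]
        t1gate <- t1gate[keep]; t2gate <- t2gate[keep]
        if (length(pi) > 0) {
            id <- .identityPairsCfg(scoreSeqs[pi], scoreSeqs[pj], config)
            t1 <- t1gate & id >= config@tier1MinIdentity
            t2 <- t2gate & id >= config@tier2MinIdentity
            sim <- t1 | t2
            edges <- S4Vectors::DataFrame(
                i = pi[sim], j = pj[sim], identity = id[sim],
                tier = ifelse(t1[sim], "tier1", "tier2"))
        }
    }
    deg <- integer(length(fragSeqs))
    if (nrow(edges) > 0) {
        # distinct partners per fragment; identical repeat copies count as
        # distinct partners (degree counts fragment instances)
        cnt <- table(factor(c(edges$i, edges$j),
                            levels = seq_along(fragSeqs)))
        deg <- as.integer(cnt)
    }
    list(edges = edges, maxDegree = if (length(deg)) max(deg) else 0L)
}

#' Screen one precursor for KEP architecture
#'
#' Applies the precursor-level filters (signal peptide present, at least
#' `minCleavageSites` distinct cut positions, length at most
#' `maxProteinLength` residues) and, when all pass, builds the all-pairs
#' fragment similarity graph and accepts the precursor when some fragment
#' has at least `minSimilarPartners` distinct similar partners.
#'
#' @param sequence A single canonicalized amino-acid sequence.
#' @param hasSignal Logical signal-peptide presence call; `NA` is an error
#'   (a missing annotation is a contract violation, not a silent rejection).
#' @param config A [MiningConfig].
#' @param id Precursor identifier used in the result.
#' @return A list with elements `protein_id`, `length`,
#'   `n_cleavage_sites`, `n_fragments`, `fragments` (a `DataFrame`),
#'   `edges` (`DataFrame`, pre-filter rejects have zero rows),
#'   `max_degree` (`NA` when the graph was not built), the per-filter
#'   booleans `pass_signal`, `pass_sites`, `pass_length`, `pass_repeat`,
#'   `accepted` and `reject_reason` (`NA` when accepted).
#' @examples
#' kep <- paste0("M", strrep("L", 18), strrep("QYKAPSWKR", 3))
#' callKep(kep, hasSignal = TRUE)$accepted
#' @export
callKep <- function(sequence, hasSignal, config = MiningConfig(),
                    id = "protein") {
    if (length(hasSignal) != 1L || is.na(hasSignal))
        stop("missing signal-peptide annotation for '", id, "'")
    sites <- findCleavageSites(sequence, motifs = config@motifs,
                               monobasic = FALSE)
    frags <- fragmentSequence(sequence, sites)
    len <- nchar(sequence)
    passSignal <- isTRUE(hasSignal)
    passSites <- nrow(sites) >= config@minCleavageSites
    passLength <- len <= config@maxProteinLength
    edges <- S4Vectors::DataFrame(i = integer(0), j = integer(0),
                                  identity = numeric(0), tier = character(0))
    maxDegree <- NA_integer_
    passRepeat <- NA
    if (passSignal && passSites && passLength) {
        g <- .similarityGraph(frags$sequence, config)
        edges <- g$edges
        maxDegree <- as.integer(g$maxDegree)
        passRepeat <- maxDegree >= config@minSimilarPartners
    }
    accepted <- isTRUE(passRepeat)
    reason <- if (accepted) NA_character_
        else if (!passSignal) "no_signal"
        else if (!passSites) "too_few_sites"
        else if (!passLength) "too_long"
        else "no_repeat"
    list(protein_id = id, length = len,
         n_cleavage_sites = nrow(sites), n_fragments = nrow(frags),
         fragments = frags, edges = edges, max_degree = maxDegree,
         pass_signal = passSignal, pass_sites = passSites,
         pass_length = passLength, pass_repeat = passRepeat,
         accepted = accepted, reject_reason = reason)
}

#' Mine a proteome for KEX2-processed repeat proteins
#'
#' Runs [callKep()] on every precursor. Results are deterministic and
#' per-protein independent; output order follows input order.
#'
#' @param precursors A [PrecursorSet] with signal annotations attached to
#'   all records (see [attachSignalAnnotations()]).
#' @param config A [MiningConfig].
#' @return A [KepCallSet].
#' @examples
#' fix <- simulateProteome(seed = 1, nKeps = 2, nDecoysPerClass = 1)
#' calls <- mineProteome(fix$precursors)
#' acceptedIds(calls)
#' @export
mineProteome <- function(precursors, config = MiningConfig()) {
    stopifnot(is(precursors, "PrecursorSet"))
    hs <- S4Vectors::mcols(precursors)$has_signal
    if (any(is.na(hs)))
        stop("missing signal-peptide annotation for: ",
             paste(names(precursors)[is.na(hs)], collapse = ", "))
    seqs <- as.character(precursors)
    ids <- names(precursors)
    res <- lapply(seq_along(seqs), function(k)
        callKep(seqs[k], hs[k], config = config, id = ids[k]))
    calls <- S4Vectors::DataFrame(
        protein_id = vapply(res, `[[`, "", "protein_id"),
        length = vapply(res, `[[`, 0L, "length"),
        n_cleavage_sites = vapply(res, `[[`, 0L, "n_cleavage_sites"),
        n_fragments = vapply(res, `[[`, 0L, "n_fragments"),
        max_degree = vapply(res, `[[`, NA_integer_, "max_degree"),
        pass_signal = vapply(res, `[[`, NA, "pass_signal"),
        pass_sites = vapply(res, `[[`, NA, "pass_sites"),
        pass_length = vapply(res, `[[`, NA, "pass_length"),
        pass_repeat = vapply(res, `[[`, NA, "pass_repeat"),
        accepted = vapply(res, `[[`, NA, "accepted"),
        reject_reason = vapply(res, `[[`, NA_character_, "reject_reason"))
    new("KepCallSet", calls = calls,
        fragments = setNames(lapply(res, `[[`, "fragments"), ids),
        edges = setNames(lapply(res, `[[`, "edges"), ids),
        config = config)
}
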