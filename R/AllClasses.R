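#' @include AllGenerics.R utils.R
#' @importFrom Biostrings AAStringSet width
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
NULL

# ---------------------------------------------------------------------------
# PrecursorSet
# ---------------------------------------------------------------------------

#' PrecursorSet: a proteome with signal-peptide annotations
#'
#' An [Biostrings::AAStringSet] whose element metadata carries a
#' signal-peptide presence call (`has_signal`) and the optional 1-based
#' position of the last signal-peptide residue (`signal_cleavage_pos`), as
#' produced by an external predictor such as SignalP. Signal-peptide calls
#' are consumed, never computed, by this package.
#'
#' @slot .Data,elementMetadata,... inherited from `AAStringSet`.
#' @seealso [readProteome()], [attachSignalAnnotations()]
#' @export
setClass("PrecursorSet", contains = "AAStringSet")

setValidity("PrecursorSet", function(object) {
    ids <- names(object)
    if (length(object) > 0 && (is.null(ids) || any(!nzchar(ids))))
        return("all precursors must have non-empty identifiers")
    if (anyDuplicated(ids))
        return(paste0("duplicate precursor identifiers: ",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (any(width(object) == 0))
        return("precursor sequences must be non-empty")
    mc <- mcols(object)
    need <- c("has_signal", "signal_cleavage_pos")
    if (!all(need %in% colnames(mc)))
        return(paste0("element metadata must contain columns: ",
                      paste(need, collapse = ", ")))
    pos <- mc$signal_cleavage_pos
    ok <- is.na(pos) | (pos >= 1L & pos < width(object))
    if (!all(ok))
        return("signal_cleavage_pos must satisfy 1 <= pos < sequence length")
    TRUE
})

#' Construct a PrecursorSet
#'
#' @param sequences Named character vector or `AAStringSet` of amino-acid
#'   sequences. Sequences are canonicalized (upper case, terminal `*`
#'   stripped) via [canonicalizeSequence()].
#' @param hasSignal Logical vector (recycled): signal-peptide presence call
#'   per precursor; `NA` when not yet annotated.
#' @param signalCleavagePos Integer vector (recycled): 1-based position of
#'   the last signal-peptide residue, or `NA`.
#' @return A `PrecursorSet`.
#' @examples
#' ps <- PrecursorSet(c(p1 = "MKRAAA", p2 = "maa*"), hasSignal = TRUE,
#'                    signalCleavagePos = c(2L, NA))
#' @export
PrecursorSet <- function(sequences, hasSignal = NA,
                         signalCleavagePos = NA_integer_) {
    if (is(sequences, "XStringSet"))
        sequences <- setNames(as.character(sequences), names(sequences))
    seqs <- canonicalizeSequence(sequences)
    names(seqs) <- names(sequences)
    x <- AAStringSet(seqs)
    n <- length(x)
    mcols(x) <- DataFrame(
        has_signal = as.logical(rep_len(hasSignal, n)),
        signal_cleavage_pos = as.integer(rep_len(signalCleavagePos, n)))
    new("PrecursorSet", x)
}

#' @describeIn PrecursorSet precursor identifiers
#' @param x A `PrecursorSet`.
#' @export
setMethod("precursorIds", "PrecursorSet", function(x) names(x))

#' @describeIn PrecursorSet per-precursor signal-peptide presence call
#' @export
setMethod("hasSignalPeptide", "PrecursorSet",
    function(x) setNames(mcols(x)$has_signal, names(x)))

#' @describeIn PrecursorSet 1-based position of the last signal residue
#' @export
setMethod("signalCleavagePos", "PrecursorSet",
    function(x) setNames(mcols(x)$signal_cleavage_pos, names(x)))

setMethod("show", "PrecursorSet", function(object) {
    hs <- mcols(object)$has_signal
    cat(sprintf(
        "PrecursorSet with %d precursors (%d signal+, %d signal-, %d unannotated)\n",
        length(object), sum(hs %in% TRUE), sum(hs %in% FALSE), sum(is.na(hs))))
    if (length(object) > 0)
        callNextMethod()
})

# ---------------------------------------------------------------------------
# MiningConfig
# ---------------------------------------------------------------------------

#' Configuration of the KEP mining screen
#'
#' Holds the cleavage motifs, the two-tier similarity thresholds and the
#' precursor-level filters of the repeat-mining screen. Length-difference
#' bounds are exclusive ("fewer than"); identity bounds are inclusive
#' ("at least").
#'
#' @slot motifs character; dibasic motifs recognized by KEX2
#'   (default `KR, RR, KK, RK`).
#' @slot tier1MinIdentity numeric; minimum percent identity of tier 1
#'   (default 70, inclusive).
#' @slot tier1MaxLenDiff numeric; tier-1 fragment length difference bound in
#'   residues (default 30, exclusive).
#' @slot tier2MinIdentity numeric; minimum percent identity of tier 2 for
#'   short fragments (default 40, inclusive).
#' @slot tier2MaxLen numeric; both fragments must be shorter than this for
#'   tier 2 (default 20, exclusive).
#' @slot tier2MaxLenDiff numeric; tier-2 length difference bound
#'   (default 8, exclusive).
#' @slot minCleavageSites numeric; minimum number of distinct cut positions
#'   (default 2).
#' @slot maxProteinLength numeric; maximum precursor length in residues
#'   (default 800).
#' @slot minSimilarPartners numeric; a precursor is accepted when some
#'   fragment has at least this many distinct similar partners (default 2).
#' @slot minFragmentLength numeric; fragments shorter than this are excluded
#'   from similarity scoring (default 1, i.e. no gate).
#' @slot stripBasicForMining logical; strip trailing K/R before similarity
#'   scoring (default `FALSE`).
#' @slot alignType character; `"local"` (Smith-Waterman) or `"overlap"`
#'   (global, end-gap free).
#' @slot minAlignmentCoverage numeric; minimum fraction of the shorter
#'   fragment the alignment must span for an identity to be reported
#'   (default 0.5); stands in for BLAST's seeding/significance filtering.
#' @slot gapOpening,gapExtension numeric; affine gap penalties (default 11/1).
#' @slot substitutionMatrix character; name of the substitution matrix
#'   (default `"BLOSUM62"`).
#' @seealso [mineProteome()], [isSimilar()]
#' @export
setClass("MiningConfig", representation(
    motifs = "character",
    tier1MinIdentity = "numeric", tier1MaxLenDiff = "numeric",
    tier2MinIdentity = "numeric", tier2MaxLen = "numeric",
    tier2MaxLenDiff = "numeric",
    minCleavageSites = "numeric", maxProteinLength = "numeric",
    minSimilarPartners = "numeric", minFragmentLength = "numeric",
    stripBasicForMining = "logical", alignType = "character",
    minAlignmentCoverage = "numeric",
    gapOpening = "numeric", gapExtension = "numeric",
    substitutionMatrix = "character"))

setValidity("MiningConfig", function(object) {
    if (length(object@motifs) == 0)
        return("at least one cleavage motif is required")
    if (!all(grepl("^[KR]{2}$", object@motifs)))
        return("motifs must be length-2 strings over {K, R}")
    num <- c(object@tier1MinIdentity, object@tier1MaxLenDiff,
             object@tier2MinIdentity, object@tier2MaxLen,
             object@tier2MaxLenDiff, object@minCleavageSites,
             object@maxProteinLength, object@minSimilarPartners,
             object@minFragmentLength)
    if (any(!is.finite(num)) || any(num <= 0))
        return("all thresholds must be positive finite numbers")
    if (object@tier2MinIdentity > object@tier1MinIdentity)
        return("tier2MinIdentity must not exceed tier1MinIdentity")
    if (!object@alignType %in% c("local", "overlap"))
        return("alignType must be 'local' or 'overlap'")
    if (object@minAlignmentCoverage < 0 || object@minAlignmentCoverage > 1)
        return("minAlignmentCoverage must be in [0, 1]")
    TRUE
})

#' @rdname MiningConfig-class
#' @param motifs,tier1MinIdentity,tier1MaxLenDiff,tier2MinIdentity,tier2MaxLen,tier2MaxLenDiff,minCleavageSites,maxProteinLength,minSimilarPartners,minFragmentLength,stripBasicForMining,alignType,minAlignmentCoverage,gapOpening,gapExtension,substitutionMatrix see slot documentation.
#' @return `MiningConfig()` returns a validated configuration object.
#' @examples
#' cfg <- MiningConfig(tier1MinIdentity = 80)
#' @export
MiningConfig <- function(motifs = c("KR", "RR", "KK", "RK"),
                         tier1MinIdentity = 70, tier1MaxLenDiff = 30,
                         tier2MinIdentity = 40, tier2MaxLen = 20,
                         tier2MaxLenDiff = 8,
                         minCleavageSites = 2, maxProteinLength = 800,
                         minSimilarPartners = 2, minFragmentLength = 1,
                         stripBasicForMining = FALSE,
                         alignType = c("local", "overlap"),
                         minAlignmentCoverage = 0.5,
                         gapOpening = 11, gapExtension = 1,
                         substitutionMatrix = "BLOSUM62") {
    new("MiningConfig", motifs = toupper(motifs),
        tier1MinIdentity = tier1MinIdentity,
        tier1MaxLenDiff = tier1MaxLenDiff,
        tier2MinIdentity = tier2MinIdentity,
        tier2MaxLen = tier2MaxLen, tier2MaxLenDiff = tier2MaxLenDiff,
        minCleavageSites = minCleavageSites,
        maxProteinLength = maxProteinLength,
        minSimilarPartners = minSimilarPartners,
        minFragmentLength = minFragmentLength,
        stripBasicForMining = stripBasicForMining,
        alignType = match.arg(alignType),
        minAlignmentCoverage = minAlignmentCoverage,
        gapOpening = gapOpening, gapExtension = gapExtension,
        substitutionMatrix = substitutionMatrix)
}

setMethod("show", "MiningConfig", function(object) {
    cat("MiningConfig\n")
    cat("  motifs:", paste(object@motifs, collapse = ", "), "\n")
    cat(sprintf("  tier1: identity >= %g%%, length diff < %g\n",
                object@tier1MinIdentity, object@tier1MaxLenDiff))
    cat(sprintf("  tier2: identity >= %g%%, both lengths < %g, length diff < %g\n",
                object@tier2MinIdentity, object@tier2MaxLen,
                object@tier2MaxLenDiff))
    cat(sprintf("  filters: >= %g cleavage sites, length <= %g, >= %g similar partners\n",
                object@minCleavageSites, object@maxProteinLength,
                object@minSimilarPartners))
    cat(sprintf("  alignment: %s %s, gap %g/%g, min coverage %g\n",
                object@alignType, object@substitutionMatrix,
                object@gapOpening, object@gapExtension,
                object@minAlignmentCoverage))
})

# ---------------------------------------------------------------------------
# MaturationConfig
# ---------------------------------------------------------------------------

#' Configuration of the peptide maturation model
#'
#' Controls which processing steps are composed when enumerating predicted
#' mature peptides: KEX2 endoproteolysis (dibasic, optionally monobasic),
#' KEX1 C-terminal basic trimming, STE13 N-terminal XP/XA dipeptide removal,
#' N-terminal pyroglutamate formation and optional nonspecific C-terminal
#' truncation.
#'
#' @slot motifs character; dibasic KEX2 motifs.
#' @slot monobasic logical; also cut after isolated K/R (default `FALSE`).
#'   Monobasic cleavage is modelled as partial: enabling it adds the
#'   fragments of the finer cleavage pattern without removing the
#'   dibasic-only products.
#' @slot maxKex1Trim numeric; maximum C-terminal basic residues removed by
#'   KEX1 (default 2, the size of a dibasic motif).
#' @slot ste13Enabled logical; apply STE13 dipeptidyl-aminopeptidase trimming
#'   (default `TRUE`).
#' @slot ste13SecondResidues character; second residues of removable
#'   N-terminal dipeptides (default A and P).
#' @slot ste13EmitIntermediates logical; emit all partial STE13 trims, not
#'   only the terminal form (default `TRUE`).
#' @slot pyrogluEnabled logical; model N-terminal Gln to pyroglutamate
#'   cyclization (default `TRUE`).
#' @slot maxCTruncation numeric; number of single-residue C-terminal
#'   truncations modelled after KEX1 (default 0; heterologous-expression
#'   observations motivate values up to 5).
#' @slot minPeptideLength,maxPeptideLength numeric; length window of emitted
#'   peptides (defaults 2 and 60 residues).
#' @seealso [enumerateMaturePeptides()]
#' @export
setClass("MaturationConfig", representation(
    motifs = "character", monobasic = "logical",
    maxKex1Trim = "numeric", ste13Enabled = "logical",
    ste13SecondResidues = "character", ste13EmitIntermediates = "logical",
    pyrogluEnabled = "logical", maxCTruncation = "numeric",
    minPeptideLength = "numeric", maxPeptideLength = "numeric"))

setValidity("MaturationConfig", function(object) {
    if (!all(grepl("^[KR]{2}$", object@motifs)))
        return("motifs must be length-2 strings over {K, R}")
    cnt <- c(object@maxKex1Trim, object@maxCTruncation,
             object@minPeptideLength, object@maxPeptideLength)
    if (any(!is.finite(cnt)) || any(cnt < 0))
        return("all counts must be non-negative")
    if (object@minPeptideLength > object@maxPeptideLength)
        return("minPeptideLength must not exceed maxPeptideLength")
    if (!all(object@ste13SecondResidues %in% .AA_STANDARD))
        return("ste13SecondResidues must be standard amino acids")
    TRUE
})

#' @rdname MaturationConfig-class
#' @param motifs,monobasic,maxKex1Trim,ste13Enabled,ste13SecondResidues,ste13EmitIntermediates,pyrogluEnabled,maxCTruncation,minPeptideLength,maxPeptideLength see slot documentation.
#' @return `MaturationConfig()` returns a validated configuration object.
#' @examples
#' mcfg <- MaturationConfig(maxCTruncation = 2)
#' @export
MaturationConfig <- function(motifs = c("KR", "RR", "KK", "RK"),
                             monobasic = FALSE, maxKex1Trim = 2,
                             ste13Enabled = TRUE,
                             ste13SecondResidues = c("A", "P"),
                             ste13EmitIntermediates = TRUE,
                             pyrogluEnabled = TRUE, maxCTruncation = 0,
                             minPeptideLength = 2, maxPeptideLength = 60) {
    new("MaturationConfig", motifs = toupper(motifs), monobasic = monobasic,
        maxKex1Trim = maxKex1Trim, ste13Enabled = ste13Enabled,
        ste13SecondResidues = toupper(ste13SecondResidues),
        ste13EmitIntermediates = ste13EmitIntermediates,
        pyrogluEnabled = pyrogluEnabled, maxCTruncation = maxCTruncation,
        minPeptideLength = minPeptideLength,
        maxPeptideLength = maxPeptideLength)
}

setMethod("show", "MaturationConfig", function(object) {
    cat("MaturationConfig\n")
    cat("  KEX2 motifs:", paste(object@motifs, collapse = ", "),
        if (object@monobasic) "+ monobasic K/R" else "", "\n")
    cat(sprintf("  KEX1: trim up to %g C-terminal basic residues\n",
                object@maxKex1Trim))
    cat(sprintf("  STE13: %s (X[%s] dipeptides%s)\n",
                if (object@ste13Enabled) "on" else "off",
                paste(object@ste13SecondResidues, collapse = ""),
                if (object@ste13EmitIntermediates) ", intermediates emitted" else ""))
    cat(sprintf("  pyroglutamate: %s; C-terminal truncation up to %g\n",
                if (object@pyrogluEnabled) "on" else "off",
                object@maxCTruncation))
    cat(sprintf("  peptide length window: %g-%g residues\n",
                object@minPeptideLength, object@maxPeptideLength))
})

# ---------------------------------------------------------------------------
# KepCallSet
# ---------------------------------------------------------------------------

#' Result of a KEP mining screen
#'
#' One row per screened precursor recording cleavage-site and fragment
#' counts, the per-filter pass/fail booleans, the maximum similarity-graph
#' degree and the acceptance call, together with the per-precursor cleavage
#' fragments and similarity edges.
#'
#' @slot calls `DataFrame` with one row per precursor.
#' @slot fragments named list of per-precursor fragment `DataFrame`s
#'   (`start`, `end`, `sequence`, `c_terminal_motif`, 1-based inclusive).
#' @slot edges named list of per-precursor similarity-edge `DataFrame`s
#'   (`i`, `j`, `identity`, `tier`; `i`/`j` index into the fragment table).
#' @slot config the [MiningConfig] used.
#' @seealso [mineProteome()], [writeKepCalls()]
#' @export
setClass("KepCallSet", representation(
    calls = "DFrame", fragments = "list", edges = "list",
    config = "MiningConfig"))

setValidity("KepCallSet", function(object) {
    need <- c("protein_id", "length", "n_cleavage_sites", "n_fragments",
              "max_degree", "pass_signal", "pass_sites", "pass_length",
              "pass_repeat", "accepted", "reject_reason")
    if (!all(need %in% colnames(object@calls)))
        return(paste0("calls must contain columns: ",
                      paste(need, collapse = ", ")))
    acc <- object@calls$accepted
    deg <- object@calls$max_degree
    bad <- acc %in% TRUE &
        !(object@calls$pass_signal & object@calls$pass_sites &
          object@calls$pass_length & (deg >= object@config@minSimilarPartners))
    if (any(bad))
        return("accepted calls must pass all filters and the degree rule")
    TRUE
})

#' @describeIn KepCallSet the per-precursor call table
#' @param x A `KepCallSet`.
#' @export
setMethod("kepCalls", "KepCallSet", function(x) x@calls)

#' @describeIn KepCallSet identifiers of accepted KEPs, in input order
#' @export
setMethod("acceptedIds", "KepCallSet",
    function(x) x@calls$protein_id[x@calls$accepted %in% TRUE])

#' @describeIn KepCallSet cleavage fragments of one precursor (or all,
#'   as a named list, when `id` is `NULL`)
#' @param id Precursor identifier, or `NULL` for all.
#' @export
setMethod("fragments", "KepCallSet", function(x, id = NULL) {
    if (is.null(id)) return(x@fragments)
    if (!id %in% names(x@fragments)) stop("unknown precursor id: ", id)
    x@fragments[[id]]
})

#' @describeIn KepCallSet similarity edges of one precursor (or all)
#' @export
setMethod("similarityEdges", "KepCallSet", function(x, id = NULL) {
    if (is.null(id)) return(x@edges)
    if (!id %in% names(x@edges)) stop("unknown precursor id: ", id)
    x@edges[[id]]
})

#' @describeIn KepCallSet the mining configuration used
#' @export
setMethod("miningConfig", "KepCallSet", function(x) x@config)

#' @describeIn KepCallSet number of screened precursors
#' @export
setMethod("length", "KepCallSet", function(x) nrow(x@calls))

setMethod("show", "KepCallSet", function(object) {
    tab <- object@calls
    cat(sprintf("KepCallSet: %d precursors screened, %d accepted as KEPs\n",
                nrow(tab), sum(tab$accepted %in% TRUE)))
    rej <- table(tab$reject_reason[!is.na(tab$reject_reason)])
    if (length(rej) > 0)
        cat("  rejections:",
            paste(sprintf("%s=%d", names(rej), rej), collapse = ", "), "\n")
})
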