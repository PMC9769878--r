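# Matching observed neutral monoisotopic masses (or sequences) against
# predicted mature peptides at ppm tolerance.

#' Match observed masses against predicted peptides
#'
#' Reports every (observed mass, predicted peptide) pair whose signed
#' ppm error, `1e6 * (observed - theoretical) / theoretical`, is within
#' the tolerance (inclusive boundary, computed against the theoretical
#' mass). Matching is many-to-many. Observed masses are neutral
#' monoisotopic masses; charge-state deconvolution must be done upstream.
#'
#' @param observed A data frame or `DataFrame` with columns `sample_id`
#'   and `observed_mass` (Da, > 0), e.g. from [readObservedMasses()]; a
#'   bare numeric vector of masses is also accepted.
#' @param peptides Predicted peptides as returned by
#'   [enumerateMaturePeptides()] (needs columns `precursor_id`, `start`,
#'   `end`, `sequence`, `modifications`, `monoisotopic_mass`).
#' @param ppmTol Tolerance in ppm (default 10, inclusive).
#' @param variableDeltas Optional named numeric vector of additional
#'   variable-modification mass deltas (see [modificationDeltas()]); each
#'   peptide is then also considered with each single delta applied.
#' @return A `DataFrame` with columns `sample_id`, `observed_mass`,
#'   `precursor_id`, `start`, `end`, `sequence`, `modifications`,
#'   `theoretical_mass` and `ppm_error`, ordered by observed mass (input
#'   order) and then by `|ppm_error|`.
#' @examples
#' ps <- PrecursorSet(
#'     c(kep = paste0("M", strrep("L", 18), strrep("EAQYKAPSWRR", 3))),
#'     hasSignal = TRUE, signalCleavagePos = 19L)
#' pep <- enumerateMaturePeptides(ps)
#' matchMasses(monoisotopicMass("QYKAPSW"), pep)
#' @export
matchMasses <- function(observed, peptides, ppmTol = 10,
                        variableDeltas = NULL) {
    stopifnot(is.numeric(ppmTol), length(ppmTol) == 1L, ppmTol > 0)
    if (is.numeric(observed))
        observed <- S4Vectors::DataFrame(
            sample_id = paste0("obs", seq_along(observed)),
            observed_mass = observed)
    if (!all(c("sample_id", "observed_mass") %in% colnames(observed)))
        stop("observed must have columns sample_id and observed_mass")
    if (any(observed$observed_mass <= 0))
        stop("observed masses must be positive")
    pep <- peptides
    if (!is.null(variableDeltas) && length(variableDeltas) > 0) {
        if (is.null(names(variableDeltas)) || any(!nzchar(names(variableDeltas))))
            stop("variableDeltas must be named")
        extra <- lapply(names(variableDeltas), function(nm) {
            p <- peptides
            p$modifications <- ifelse(nzchar(p$modifications),
                                      paste0(p$modifications, ",", nm), nm)
            p$monoisotopic_mass <- p$monoisotopic_mass + variableDeltas[[nm]]
            p
        })
        pep <- do.call(rbind, c(list(peptides), extra))
    }
    out <- lapply(seq_len(nrow(observed)), function(k) {
        om <- observed$observed_mass[k]
        ppm <- 1e6 * (om - pep$monoisotopic_mass) / pep$monoisotopic_mass
        # tiny fuzz keeps the stated inclusive boundary inclusive in
        # floating point
        hit <- which(abs(ppm) <= ppmTol + 1e-9)
        if (length(hit) == 0) return(NULL)
        hit <- hit[order(abs(ppm[hit]))]
        S4Vectors::DataFrame(
            sample_id = observed$sample_id[k], observed_mass = om,
            precursor_id = pep$precursor_id[hit], start = pep$start[hit],
            end = pep$end[hit], sequence = pep$sequence[hit],
            modifications = pep$modifications[hit],
            theoretical_mass = pep$monoisotopic_mass[hit],
            ppm_error = ppm[hit])
    })
    out <- out[!vapply(out, is.null, NA)]
    if (length(out) == 0)
        return(S4Vectors::DataFrame(
            sample_id = character(0), observed_mass = numeric(0),
            precursor_id = character(0), start = integer(0),
            end = integer(0), sequence = character(0),
            modifications = character(0), theoretical_mass = numeric(0),
            ppm_error = numeric(0)))
    do.call(rbind, out)
}

#' Match reported peptide sequences against predictions
#'
#' Exact string equality on the (canonicalized) sequence, ignoring
#' modifications; modification agreement is reported separately. No
#' substring logic is applied.
#'
#' @param observed A data frame or `DataFrame` with columns `sample_id`
#'   and `reported_sequence`.
#' @param peptides Predicted peptides (as for [matchMasses()]).
#' @return A `DataFrame` with columns `sample_id`, `reported_sequence`,
#'   `precursor_id`, `start`, `end`, `modifications` and
#'   `theoretical_mass`, one row per matching prediction.
#' @examples
#' obs <- data.frame(sample_id = "s1", reported_sequence = "qykapsw")
#' ps <- PrecursorSet(
#'     c(kep = paste0("M", strrep("L", 18), strrep("EAQYKAPSWRR", 3))),
#'     hasSignal = TRUE, signalCleavagePos = 19L)
#' matchSequences(obs, enumerateMaturePeptides(ps))
#' @export
matchSequences <- function(observed, peptides) {
    if (!all(c("sample_id", "reported_sequence") %in% colnames(observed)))
        stop("observed must have columns sample_id and reported_sequence")
    rep_seq <- canonicalizeSequence(observed$reported_sequence)
    out <- lapply(seq_along(rep_seq), function(k) {
        hit <- which(peptides$sequence == rep_seq[k])
        if (length(hit) == 0) return(NULL)
        S4Vectors::DataFrame(
            sample_id = observed$sample_id[k],
            reported_sequence = rep_seq[k],
            precursor_id = peptides$precursor_id[hit],
            start = peptides$start[hit], end = peptides$end[hit],
            modifications = peptides$modifications[hit],
            theoretical_mass = peptides$monoisotopic_mass[hit])
    })
    out <- out[!vapply(out, is.null, NA)]
    if (length(out) == 0)
        return(S4Vectors::DataFrame(
            sample_id = character(0), reported_sequence = character(0),
            precursor_id = character(0), start = integer(0),
            end = integer(0), modifications = character(0),
            theoretical_mass = numeric(0)))
    do.call(rbind, out)
}
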