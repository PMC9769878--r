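# In-silico KEX2 endoproteolysis: site finding and fragmentation.
# The peptide bond is cut on the C-terminal side of the full dibasic motif,
# so the motif stays at the C-terminus of the upstream fragment.

#' Locate KEX2 cleavage sites in a precursor sequence
#'
#' Reports a site with `cut_after = i` for every position `i >= 2` such that
#' residues `(i - 1, i)` form one of the configured dibasic motifs.
#' Overlapping motifs (e.g. within `"KRR"`) each yield their own site. In
#' monobasic mode, additional sites are reported after every isolated K or R
#' that is not part of a matched dibasic motif.
#'
#' @param sequence A single canonicalized amino-acid sequence.
#' @param motifs Dibasic motifs, each of length 2 over `{K, R}`.
#' @param monobasic Also cut after isolated K/R residues (default `FALSE`;
#'   the mining screen uses dibasic motifs only, monobasic cleavage is a
#'   maturation option).
#' @return A `DataFrame` with columns `cut_after` (1-based residue index
#'   after which the bond is cut), `motif` (matched motif, or the single
#'   residue in monobasic mode) and `kind` (`"dibasic"` or `"monobasic"`),
#'   sorted by `cut_after` with no duplicates.
#' @examples
#' findCleavageSites("MAKRGS")            # one site, cut after 4
#' findCleavageSites("MKRRA")             # overlapping KR and RR
#' @export
findCleavageSites <- function(sequence, motifs = c("KR", "RR", "KK", "RK"),
                              monobasic = FALSE) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    motifs <- toupper(motifs)
    if (length(motifs) == 0 || !all(grepl("^[KR]{2}$", motifs)))
        stop("motifs must be non-empty, each of length 2 over {K, R}")
    ch <- strsplit(sequence, "")[[1L]]
    n <- length(ch)
    out <- S4Vectors::DataFrame(cut_after = integer(0), motif = character(0),
                                kind = character(0))
    if (n >= 2) {
        dip <- paste0(ch[-n], ch[-1L])
        hit <- which(dip %in% motifs)
        out <- S4Vectors::DataFrame(cut_after = hit + 1L, motif = dip[hit],
                                    kind = rep("dibasic", length(hit)))
    } else {
        hit <- integer(0)
    }
    if (monobasic) {
        covered <- unique(c(hit, hit + 1L))
        mono <- setdiff(which(ch %in% c("K", "R")), covered)
        if (length(mono) > 0)
            out <- rbind(out, S4Vectors::DataFrame(
                cut_after = as.integer(mono), motif = ch[mono],
                kind = rep("monobasic", length(mono))))
    }
    out[order(out$cut_after), , drop = FALSE]
}

#' Fragment a precursor at cleavage sites
#'
#' Applies cuts after each `cut_after` index; the matched motif remains at
#' the C-terminus of the upstream fragment. A zero-length trailing fragment
#' (cut at the final residue) is dropped. Fragments are non-overlapping,
#' ordered, and concatenate to the full input sequence.
#'
#' @param sequence A single amino-acid sequence.
#' @param sites A site table as returned by [findCleavageSites()] (or any
#'   data frame with a `cut_after` column; an optional `motif` column is
#'   carried into `c_terminal_motif`).
#' @return A `DataFrame` with columns `start`, `end` (1-based inclusive),
#'   `sequence` and `c_terminal_motif` (`NA` for the final fragment when it
#'   does not end at a cut).
#' @examples
#' s <- findCleavageSites("SAKRTTKRGG")
#' fragmentSequence("SAKRTTKRGG", s)   # SAKR | TTKR | GG
#' @export
fragmentSequence <- function(sequence, sites) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    n <- nchar(sequence)
    cuts <- sort(unique(as.integer(sites$cut_after)))
    if (length(cuts) > 0 && (min(cuts) < 1L || max(cuts) > n))
        stop("cleavage site out of range for a sequence of length ", n)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    keep <- starts <= ends
    starts <- starts[keep]; ends <- ends[keep]
    motif <- rep(NA_character_, length(starts))
    if (!is.null(sites$motif) && length(cuts) > 0) {
        m <- setNames(as.character(sites$motif), as.character(sites$cut_after))
        atCut <- match(as.character(ends), names(m))
        motif <- unname(m[atCut])
    }
    S4Vectors::DataFrame(start = starts, end = ends,
                         sequence = substring(sequence, starts, ends),
                         c_terminal_motif = motif)
}
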