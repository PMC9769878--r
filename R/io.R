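# Readers and writers for every external representation the pipeline
# touches: FASTA proteomes and peptide databases, TSV signal annotations,
# KEP call tables, peptide tables, observed-mass tables, GFF3 fragments.
# All coordinates in files are 1-based inclusive; all tables are TSV with
# a header row.

#' Read a proteome FASTA into a PrecursorSet
#'
#' One record per FASTA entry, order preserved. The identifier is the
#' first whitespace-delimited token of the header. Sequences are
#' canonicalized (upper case, terminal `*` stripped). Signal-peptide
#' fields are left unset (`NA`); attach them with
#' [attachSignalAnnotations()].
#'
#' @param path Path to a FASTA file.
#' @return A [PrecursorSet].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 desc", "MKR", ">p2", "AAA"), fa)
#' readProteome(fa)
#' @export
readProteome <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    content <- which(!grepl("^\\s*$", lines))
    if (length(content) == 0)
        return(PrecursorSet(setNames(character(0), character(0))))
    if (!startsWith(lines[content[1L]], ">"))
        stop("malformed FASTA at line ", content[1L],
             ": expected a '>' header")
    isHdr <- startsWith(lines, ">")
    bad <- content[!isHdr[content] &
        grepl(paste0("[^A-Za-z*]"), lines[content])]
    if (length(bad) > 0)
        stop("malformed FASTA at line ", bad[1L],
             ": invalid sequence character")
    x <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(x))
    dup <- unique(ids[duplicated(ids)])
    if (length(dup) > 0)
        stop("duplicate sequence identifiers: ",
             paste(dup, collapse = ", "))
    PrecursorSet(setNames(as.character(x), ids))
}

#' Read a signal-peptide annotation table
#'
#' A TSV with header columns `id`, `has_signal` and `cleavage_pos`
#' (`cleavage_pos` may be empty), e.g. parsed from SignalP output.
#' `has_signal` accepts `yes/no`, `true/false` and `1/0` (any case).
#'
#' @param path Path to the TSV file.
#' @return A `DataFrame` with columns `id` (character), `has_signal`
#'   (logical) and `cleavage_pos` (integer, `NA` when absent).
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("id\thas_signal\tcleavage_pos", "p1\tyes\t19",
#'              "p2\tno\t"), tsv)
#' readSignalAnnotations(tsv)
#' @export
readSignalAnnotations <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.delim(path, colClasses = "character")
    need <- c("id", "has_signal", "cleavage_pos")
    if (!all(need %in% colnames(tab)))
        stop("signal annotation table must have columns: ",
             paste(need, collapse = ", "))
    tok <- tolower(trimws(tab$has_signal))
    hs <- rep(NA, nrow(tab))
    hs[tok %in% c("yes", "true", "1")] <- TRUE
    hs[tok %in% c("no", "false", "0")] <- FALSE
    if (any(is.na(hs)))
        stop("unknown has_signal token(s): ",
             paste(unique(tab$has_signal[is.na(hs)]), collapse = ", "))
    pos <- suppressWarnings(as.integer(tab$cleavage_pos))
    S4Vectors::DataFrame(id = tab$id, has_signal = hs, cleavage_pos = pos)
}

#' @describeIn PrecursorSet attach signal-peptide annotations read with
#'   [readSignalAnnotations()]; annotation rows whose id is absent from
#'   the proteome produce a warning, precursors without a row keep `NA`
#' @param annotations A `DataFrame`/data frame with columns `id`,
#'   `has_signal`, `cleavage_pos`.
#' @export
setMethod("attachSignalAnnotations", "PrecursorSet",
    function(x, annotations) {
        stopifnot(all(c("id", "has_signal", "cleavage_pos") %in%
                      colnames(annotations)))
        unknown <- setdiff(annotations$id, names(x))
        if (length(unknown) > 0)
            warning("annotation ids absent from proteome: ",
                    paste(unknown, collapse = ", "))
        hit <- match(names(x), annotations$id)
        mc <- S4Vectors::mcols(x)
        upd <- !is.na(hit)
        mc$has_signal[upd] <- annotations$has_signal[hit[upd]]
        mc$signal_cleavage_pos[upd] <-
            as.integer(annotations$cleavage_pos[hit[upd]])
        S4Vectors::mcols(x) <- mc
        validObject(x)
        x
    })

#' Read an observed-mass table
#'
#' A TSV with header columns `sample_id`, `observed_mass` (neutral
#' monoisotopic mass in Da, > 0) and optionally `reported_sequence`.
#'
#' @param path Path to the TSV file.
#' @return A `DataFrame` with columns `sample_id`, `observed_mass` and
#'   `reported_sequence` (`NA` when the column is absent).
#' @export
readObservedMasses <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.delim(path, colClasses = "character")
    if (!all(c("sample_id", "observed_mass") %in% colnames(tab)))
        stop("observed-mass table must have columns sample_id, observed_mass")
    om <- as.numeric(tab$observed_mass)
    if (any(is.na(om)) || any(om <= 0))
        stop("observed_mass must be a positive number")
    S4Vectors::DataFrame(
        sample_id = tab$sample_id, observed_mass = om,
        reported_sequence = if ("reported_sequence" %in% colnames(tab))
            tab$reported_sequence else NA_character_)
}

#' Write (and read back) a KEP call table
#'
#' One row per screened precursor with the counts, the maximum
#' similarity-graph degree, the fragment cluster (semicolon-joined
#' `start-end:sequence` entries, 1-based inclusive, for fragments carrying
#' at least one similarity edge) and the per-filter pass/fail booleans.
#'
#' @param calls A [KepCallSet].
#' @param path Output TSV path.
#' @return `writeKepCalls()` returns `path` invisibly; `readKepCalls()`
#'   returns the table as a data frame with the same field values.
#' @examples
#' fix <- simulateProteome(seed = 1, nKeps = 2, nDecoysPerClass = 0)
#' tsv <- tempfile(fileext = ".tsv")
#' writeKepCalls(mineProteome(fix$precursors), tsv)
#' readKepCalls(tsv)[, 1:5]
#' @export
writeKepCalls <- function(calls, path) {
    stopifnot(is(calls, "KepCallSet"))
    tab <- calls@calls
    cluster <- vapply(tab$protein_id, function(id) {
        fr <- calls@fragments[[id]]
        ed <- calls@edges[[id]]
        inClust <- sort(unique(c(ed$i, ed$j)))
        if (length(inClust) == 0) return("")
        paste(sprintf("%d-%d:%s", fr$start[inClust], fr$end[inClust],
                      fr$sequence[inClust]), collapse = ";")
    }, "")
    out <- data.frame(
        protein_id = tab$protein_id, length = tab$length,
        n_cleavage_sites = tab$n_cleavage_sites,
        n_fragments = tab$n_fragments,
        max_similarity_degree = tab$max_degree,
        fragment_cluster = cluster,
        pass_signal = tab$pass_signal, pass_min_sites = tab$pass_sites,
        pass_max_length = tab$pass_length, pass_repeat = tab$pass_repeat,
        accepted = tab$accepted, reject_reason = tab$reject_reason,
        check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}

#' @rdname writeKepCalls
#' @export
readKepCalls <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.delim(path, colClasses = "character", na.strings = "")
    for (col in c("length", "n_cleavage_sites", "n_fragments",
                  "max_similarity_degree"))
        tab[[col]] <- as.integer(tab[[col]])
    for (col in c("pass_signal", "pass_min_sites", "pass_max_length",
                  "pass_repeat", "accepted"))
        tab[[col]] <- as.logical(tab[[col]])
    tab$fragment_cluster[is.na(tab$fragment_cluster)] <- ""
    tab
}

#' Write predicted peptides as TSV or FASTA
#'
#' The TSV has columns `precursor_id`, `start`, `end`, `sequence`,
#' `modifications` (comma-joined), `provenance` (ordered step list) and
#' `monoisotopic_mass` (6 decimal places). FASTA headers encode
#' `precursor_id|start-end|modifications` (with `-` for an empty
#' modification set), suitable as a search database for a peptide search
#' engine.
#'
#' @param peptides Peptides as returned by [enumerateMaturePeptides()].
#' @param path Output path.
#' @param format `"tsv"` (default) or `"fasta"`.
#' @return `path`, invisibly.
#' @export
writePeptides <- function(peptides, path, format = c("tsv", "fasta")) {
    format <- match.arg(format)
    if (format == "tsv") {
        out <- data.frame(
            precursor_id = peptides$precursor_id,
            start = peptides$start, end = peptides$end,
            sequence = peptides$sequence,
            modifications = peptides$modifications,
            provenance = peptides$provenance,
            monoisotopic_mass = sprintf("%.6f", peptides$monoisotopic_mass),
            check.names = FALSE)
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        hdr <- sprintf("%s|%d-%d|%s", peptides$precursor_id,
                       peptides$start, peptides$end,
                       ifelse(nzchar(peptides$modifications),
                              peptides$modifications, "-"))
        x <- Biostrings::AAStringSet(setNames(peptides$sequence, hdr))
        Biostrings::writeXStringSet(x, path)
    }
    invisible(path)
}

#' @rdname writePeptides
#' @export
readPeptides <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.delim(path, colClasses = "character")
    for (col in c("start", "end")) tab[[col]] <- as.integer(tab[[col]])
    tab$monoisotopic_mass <- as.numeric(tab$monoisotopic_mass)
    tab
}

#' Export called repeat fragments as GFF3
#'
#' Writes the fragments that carry at least one similarity edge in
#' accepted KEPs as `repeat_region` features (1-based inclusive, per
#' GFF3), with the precursor identifier as the sequence name.
#'
#' @param calls A [KepCallSet].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
exportFragmentsGFF3 <- function(calls, path) {
    stopifnot(is(calls, "KepCallSet"))
    ids <- acceptedIds(calls)
    rows <- lapply(ids, function(id) {
        fr <- calls@fragments[[id]]
        ed <- calls@edges[[id]]
        inClust <- sort(unique(c(ed$i, ed$j)))
        if (length(inClust) == 0) return(NULL)
        data.frame(id = id, start = fr$start[inClust],
                   end = fr$end[inClust], seq = fr$sequence[inClust])
    })
    rows <- do.call(rbind, rows[!vapply(rows, is.null, NA)])
    gr <- if (is.null(rows)) GenomicRanges::GRanges()
          else GenomicRanges::GRanges(
              seqnames = rows$id,
              ranges = IRanges::IRanges(start = rows$start, end = rows$end),
              strand = "*", type = "repeat_region", Name = rows$seq)
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}
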