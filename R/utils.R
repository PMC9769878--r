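# Alphabets and sequence canonicalization shared across the package.

.AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity / non-standard codes are retained in sequences but any fragment
# containing one is excluded from similarity scoring and maturation.
.AA_EXTENDED <- c(.AA_STANDARD, "B", "J", "O", "U", "X", "Z")

.isStandardSeq <- function(x) {
    !grepl(paste0("[^", paste(.AA_STANDARD, collapse = ""), "]"), x)
}

#' Canonicalize an amino-acid sequence
#'
#' Upper-cases the sequence, strips a single terminal stop character (`*`)
#' and validates that all remaining letters belong to the amino-acid
#' alphabet (20 standard residues plus the ambiguity codes B, J, O, U, X, Z,
#' which are retained but excluded from similarity scoring and maturation).
#'
#' @param x Character vector of amino-acid sequences.
#' @return Character vector of canonicalized sequences.
#' @examples
#' canonicalizeSequence("mkr")    # "MKR"
#' canonicalizeSequence("AAA*")   # "AAA"
#' @export
canonicalizeSequence <- function(x) {
    x <- toupper(as.character(x))
    x <- sub("\\*$", "", x)
    bad <- grepl("\\*", x)
    if (any(bad))
        stop("internal stop character '*' in sequence(s): ",
             paste(which(bad), collapse = ", "))
    pat <- paste0("[^", paste(.AA_EXTENDED, collapse = ""), "]")
    hit <- regexpr(pat, x)
    if (any(hit > 0)) {
        i <- which(hit > 0)[1L]
        stop(sprintf("invalid character '%s' in sequence %d",
                     substr(x[i], hit[i], hit[i]), i))
    }
    x
}

# Restore the caller's RNG state on exit; gives functions their own
# deterministic stream without touching global reproducibility.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}
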