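#' @include AllClasses.R
NULL

## Alphabet check shared by the sequence-facing entry points. Sequences are
## normalized to uppercase; anything outside ACGT is rejected with the
## position of the first offending character.
.checkDNA <- function(seq, what = "sequence") {
    stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
    seq <- toupper(seq)
    bad <- regexpr("[^ACGT]", seq)
    if (bad != -1L)
        stop(sprintf("non-ACGT character '%s' in %s at position %d",
                     substr(seq, bad, bad), what, bad), call. = FALSE)
    seq
}

#' Reverse complement of a DNA sequence
#'
#' Strict ACGT Watson-Crick reverse complement. Lowercase input is accepted
#' and normalized to uppercase; any other character is an error naming the
#' offending position. The empty string maps to itself.
#'
#' @param seq Character scalar over ACGT (case-insensitive).
#' @return Uppercase reverse-complemented character scalar.
#' @examples
#' revComp("TTTAGGG")  # "CCCTAAA"
#' @export
revComp <- function(seq) {
    seq <- .checkDNA(seq)
    if (!nzchar(seq)) return(seq)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Enumerate telomere-repeat template permutations
#'
#' A "permutation" of a repeat unit is a fixed-length window of the infinite
#' tandem repetition of the unit, indexed by the circular offset at which the
#' window starts. For each length in `[min_len, max_len]` and each of the
#' `period` offsets, one window is generated; with `both_strands = TRUE` the
#' same enumeration is repeated for the reverse-complemented unit. Identical
#' sequences are de-duplicated (first occurrence kept), so the result has at
#' most `2 * period * (max_len - min_len + 1)` elements, with equality when
#' the unit is primitive and the two strands share no window. For the plant
#' telomere repeat TTTAGGG and the 9-19 nt template-length range this yields
#' the canonical 154 permutations.
#'
#' @param unit Repeat unit (character scalar over ACGT), default the plant
#'   telomere repeat `"TTTAGGG"`.
#' @param min_len,max_len Window length range in nucleotides (defaults 9 and
#'   19, the template-domain screen range).
#' @param both_strands Include windows of the reverse-complemented unit
#'   (default `TRUE`).
#' @return A [TemplatePermutations-class] object.
#' @examples
#' length(enumeratePermutations())  # 154
#' @export
enumeratePermutations <- function(unit = "TTTAGGG", min_len = 9L,
                                  max_len = 19L, both_strands = TRUE) {
    unit <- .checkDNA(unit, "repeat unit")
    min_len <- as.integer(min_len)
    max_len <- as.integer(max_len)
    if (is.na(min_len) || is.na(max_len) || min_len < 1L || min_len > max_len)
        stop("need 1 <= min_len <= max_len", call. = FALSE)
    units <- if (both_strands) c("+" = unit, "-" = revComp(unit)) else
        c("+" = unit)
    seqs <- character()
    meta <- list(length = integer(), strand = character(), offset = integer())
    for (s in names(units)) {
        u <- units[[s]]
        p <- nchar(u)
        tandem <- strrep(u, ceiling((max_len + p) / p))
        for (L in min_len:max_len) {
            for (o in seq_len(p) - 1L) {
                seqs <- c(seqs, substr(tandem, o + 1L, o + L))
                meta$length <- c(meta$length, L)
                meta$strand <- c(meta$strand, s)
                meta$offset <- c(meta$offset, o)
            }
        }
    }
    keep <- !duplicated(seqs)
    out <- Biostrings::DNAStringSet(seqs[keep])
    names(out) <- sprintf("%s_o%d_l%d",
                          ifelse(meta$strand[keep] == "+", "fwd", "rev"),
                          meta$offset[keep], meta$length[keep])
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        length = meta$length[keep],
        strand = meta$strand[keep],
        offset = meta$offset[keep]
    )
    new("TemplatePermutations", out, unit = unit, min_len = min_len,
        max_len = max_len, both_strands = both_strands)
}

#' Classify an observed template domain against the canonical sequence
#'
#' Used to class repeat-template alleles across ecotypes or species: a
#' template is `intact` when it equals the canonical sequence, `mutated` when
#' it has the same length but at least one substitution (e.g. the
#' TCCCAAAT -> TCCCAAAA template mutation segregating among A. thaliana
#' ecotypes), and `absent` when it is empty or of different length.
#'
#' @param observed,canonical Character scalars (canonical non-empty).
#' @return One of `"intact"`, `"mutated"`, `"absent"`.
#' @examples
#' classifyTemplate("TCCCAAAA", "TCCCAAAT")  # "mutated"
#' @export
classifyTemplate <- function(observed, canonical) {
    stopifnot(is.character(observed), is.character(canonical),
              length(observed) == 1L, length(canonical) == 1L)
    if (!nzchar(canonical)) stop("canonical template must be non-empty",
                                 call. = FALSE)
    observed <- toupper(observed)
    canonical <- toupper(canonical)
    if (!nzchar(observed) || nchar(observed) != nchar(canonical))
        return("absent")
    if (observed == canonical) "intact" else "mutated"
}

#' Edit distance between repeat units
#'
#' Levenshtein distance between two repeat units, e.g. the single-nucleotide
#' difference between the plant telomere repeat TTTAGGG and the vertebrate
#' repeat TTAGGG. With `circular = TRUE` the minimum over all circular
#' rotations of `b` is returned, which compares the repeats as cyclic words.
#'
#' @param a,b Character scalars over ACGT.
#' @param circular Minimize over circular rotations of `b` (default FALSE).
#' @return Non-negative integer edit distance.
#' @examples
#' repeatUnitDistance("TTTAGGG", "TTAGGG")  # 1
#' @export
repeatUnitDistance <- function(a, b, circular = FALSE) {
    a <- .checkDNA(a, "unit a")
    b <- .checkDNA(b, "unit b")
    rots <- if (circular && nzchar(b)) {
        p <- nchar(b)
        bb <- paste0(b, b)
        vapply(seq_len(p) - 1L, function(o) substr(bb, o + 1L, o + p), "")
    } else b
    as.integer(min(utils::adist(a, rots)))
}
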