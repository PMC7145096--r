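#' @include permutations.R
NULL

.emptyMatches <- function(raw = FALSE) {
    d <- data.frame(seq_id = character(), start = integer(), end = integer(),
                    length = integer(), strand = character(),
                    matched_seq = character(), stringsAsFactors = FALSE)
    if (raw) d$permutation <- character()
    d
}

## Maximal runs of agreement between one sequence and the infinite tandem
## repetition of `u`, over all `period` phases. Returns 0-based starts and
## uncapped run lengths. Characters outside ACGT never match.
.phaseRunsOneStrand <- function(ch, u, min_len) {
    n <- length(ch)
    ui <- utf8ToInt(u)
    p <- length(ui)
    starts <- integer()
    lens <- integer()
    idx <- seq_len(n) - 1L
    for (shift in seq_len(p) - 1L) {
        ok <- ch == ui[((idx + shift) %% p) + 1L]
        r <- rle(ok)
        ends <- cumsum(r$lengths)
        sel <- which(r$values & r$lengths >= min_len)
        if (length(sel)) {
            starts <- c(starts, ends[sel] - r$lengths[sel])
            lens <- c(lens, r$lengths[sel])
        }
    }
    list(start = starts, len = lens)
}

## Drop runs whose interval is contained in a longer run (same strand);
## de-duplicate identical intervals.
.collapseContained <- function(start, len) {
    if (!length(start)) return(integer(0))
    end <- start + len
    o <- order(start, -len)
    dup <- duplicated(paste(start[o], end[o]))
    idx <- o[!dup]
    s <- start[idx]; e <- end[idx]; l <- len[idx]
    drop <- vapply(seq_along(idx), function(i) {
        any(s <= s[i] & e >= e[i] & l > l[i])
    }, logical(1))
    idx[!drop]
}

#' Scan sequences for telomere template domains
#'
#' Finds template-domain matches of an enumerated permutation set in one or
#' more DNA sequences, case-insensitively, on both strands of the permutation
#' set. In the default collapsed mode each reported match is a maximal run of
#' agreement with the infinite tandem repetition of the repeat unit (in some
#' circular phase, on one strand); runs contained within a longer run at the
#' same locus and strand are collapsed, and reported lengths are capped at
#' the enumeration's `max_len` (the match starts at the run start). With
#' `collapse = FALSE` every raw occurrence of every permutation is reported,
#' overlaps included.
#'
#' @param x Sequences to scan: a named character vector or a
#'   [Biostrings::DNAStringSet]. An empty sequence yields no matches.
#' @param permutations A [TemplatePermutations-class], by default the 154
#'   permutations of TTTAGGG at 9-19 nt.
#' @param collapse Collapse to maximal matches (default `TRUE`).
#' @return data.frame with columns `seq_id`, `start` (0-based), `end`
#'   (half-open), `length`, `strand` (`"+"` = forward unit, `"-"` = reverse
#'   complement), `matched_seq`, and in raw mode also `permutation`.
#' @examples
#' scanTemplates(c(tx = strrep("TTTAGGG", 3)))
#' @export
scanTemplates <- function(x, permutations = enumeratePermutations(),
                          collapse = TRUE) {
    stopifnot(is(permutations, "TemplatePermutations"),
              length(permutations) > 0L)
    if (is(x, "DNAStringSet") || is(x, "DNAString")) {
        x <- as.character(x)
    }
    stopifnot(is.character(x))
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x <- toupper(x)
    if (collapse) .scanCollapsed(x, permutations) else .scanRaw(x, permutations)
}

.scanCollapsed <- function(x, perms) {
    unit <- perms@unit
    strands <- if (perms@both_strands) c("+" = unit, "-" = revComp(unit)) else
        c("+" = unit)
    out <- vector("list", length(x))
    for (i in seq_along(x)) {
        s <- x[[i]]
        if (!nzchar(s)) next
        ch <- utf8ToInt(s)
        rows <- list()
        for (st in names(strands)) {
            runs <- .phaseRunsOneStrand(ch, strands[[st]], perms@min_len)
            keep <- .collapseContained(runs$start, runs$len)
            if (!length(keep)) next
            st0 <- runs$start[keep]
            ln <- pmin(runs$len[keep], perms@max_len)
            rows[[st]] <- data.frame(
                seq_id = names(x)[i], start = st0, end = st0 + ln,
                length = ln, strand = st,
                matched_seq = substring(s, st0 + 1L, st0 + ln),
                stringsAsFactors = FALSE)
        }
        if (length(rows)) out[[i]] <- do.call(rbind, rows)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out)) return(.emptyMatches())
    res <- do.call(rbind, out)
    res <- res[order(match(res$seq_id, names(x)), res$start, res$strand), ,
               drop = FALSE]
    rownames(res) <- NULL
    res
}

.scanRaw <- function(x, perms) {
    subj <- Biostrings::DNAStringSet(x)
    pat_strand <- S4Vectors::mcols(perms)$strand
    out <- list()
    for (j in seq_along(perms)) {
        hits <- Biostrings::vmatchPattern(perms[[j]], subj, fixed = TRUE)
        nh <- lengths(hits)
        if (!sum(nh)) next
        ir <- unlist(hits)
        out[[length(out) + 1L]] <- data.frame(
            seq_id = rep(names(x), nh),
            start = BiocGenerics::start(ir) - 1L,
            end = BiocGenerics::end(ir),
            length = BiocGenerics::width(ir),
            strand = pat_strand[j],
            matched_seq = as.character(perms[[j]]),
            permutation = names(perms)[j],
            stringsAsFactors = FALSE)
    }
    if (!length(out)) return(.emptyMatches(raw = TRUE))
    res <- do.call(rbind, out)
    res <- res[order(match(res$seq_id, names(x)), res$start, res$strand,
                     -res$length), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Longest template domain in a sequence
#'
#' Summary of [scanTemplates()] for the funnel's template screen: the single
#' maximal-length collapsed match, ties broken by smallest start and then by
#' forward strand.
#'
#' @inheritParams scanTemplates
#' @param seq A single sequence (character scalar or
#'   [Biostrings::DNAString]).
#' @return One-row match data.frame, or `NULL` when there is no match.
#' @export
longestTemplate <- function(seq, permutations = enumeratePermutations()) {
    if (is(seq, "DNAString")) seq <- as.character(seq)
    stopifnot(is.character(seq), length(seq) == 1L)
    m <- scanTemplates(c(query = seq), permutations, collapse = TRUE)
    .pickLongest(m)
}

.pickLongest <- function(m) {
    if (!nrow(m)) return(NULL)
    o <- order(-m$length, m$start, m$strand)
    m[o[1L], , drop = FALSE]
}

## Longest collapsed match per sequence for a whole set; returns a data.frame
## keyed by seq_id with length 0 rows for sequences without a match omitted.
.longestPerSequence <- function(x, permutations) {
    m <- scanTemplates(x, permutations, collapse = TRUE)
    if (!nrow(m)) return(.emptyMatches())
    parts <- split(m, m$seq_id)
    res <- do.call(rbind, lapply(parts, .pickLongest))
    rownames(res) <- NULL
    res
}
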