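#' @include scan.R AllGenerics.R
NULL

.HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
               "gapopen", "qstart", "qend", "sstart", "send",
               "evalue", "bitscore")

#' Read a 12-column tabular homology hit table
#'
#' Standard BLAST outfmt-6 layout (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), one hit per line, no
#' header. The subject species is parsed from the subject id using a prefix
#' convention, by default everything before the first `|`
#' (e.g. `Capsella_rubella|cand_0042`).
#'
#' @param path Path to the tab-separated hit table.
#' @param species_sep Separator between species prefix and locus id in
#'   subject ids (default `"|"`).
#' @return data.frame with the 12 standard columns plus `species`. An empty
#'   file yields zero rows.
#' @export
readHitTable <- function(path, species_sep = "|") {
    if (!file.exists(path)) stop("no such hit table: ", path, call. = FALSE)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
        d <- as.data.frame(stats::setNames(
            rep(list(character(0)), 12L), .HIT_COLS))
        d$species <- character(0)
        return(.coerceHits(d))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 12L))
        stop(sprintf("malformed hit table line %d: %d fields (expected 12)",
                     which(nf != 12L)[1L], nf[nf != 12L][1L]), call. = FALSE)
    d <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(d) <- .HIT_COLS
    d <- .coerceHits(d)
    bad <- which(!is.finite(d$evalue) | !is.finite(d$bitscore))
    if (length(bad))
        stop("malformed hit table line ", bad[1L],
             ": non-numeric evalue/bitscore", call. = FALSE)
    d$species <- vapply(strsplit(d$sseqid, species_sep, fixed = TRUE),
                        `[[`, "", 1L)
    d
}

.coerceHits <- function(d) {
    num <- c("pident", "evalue", "bitscore")
    int <- c("length", "mismatch", "gapopen", "qstart", "qend",
             "sstart", "send")
    for (cl in num) d[[cl]] <- suppressWarnings(as.numeric(d[[cl]]))
    for (cl in int) d[[cl]] <- suppressWarnings(as.integer(d[[cl]]))
    d
}

#' Write a hit table in the 12-column tabular layout
#'
#' Inverse of [readHitTable()] (the derived `species` column is dropped).
#'
#' @param hits data.frame with the 12 standard columns.
#' @param path Output path.
#' @export
writeHitTable <- function(hits, path) {
    stopifnot(all(.HIT_COLS %in% names(hits)))
    utils::write.table(format(hits[, .HIT_COLS], scientific = TRUE,
                              trim = TRUE),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
}

#' Build the ortholog presence matrix
#'
#' For each candidate and each panel species: `present` when at least one
#' hit passes the E-value cutoff; `present_with_template` when additionally
#' the best such hit (highest bit score) has a subject sequence carrying a
#' template domain of at least `min_template_len`. A passing hit whose
#' subject sequence is unavailable leaves the species `present` with a
#' warning (template status unknown).
#'
#' @param hits Hit data.frame from [readHitTable()] (a `species` column is
#'   derived from `sseqid` if absent).
#' @param ortholog_sequences Named [Biostrings::DNAStringSet] or character
#'   vector of subject sequences, names = subject ids.
#' @param permutations A [TemplatePermutations-class].
#' @param evalue_cutoff Maximum E-value counted as presence (default 1e-5).
#' @param min_template_len Minimum template length (default 9).
#' @param query_species Species name of the query transcripts.
#' @param species Panel species (default: query plus species seen in hits).
#' @param candidates Candidate ids forming the rows (default: ids seen in
#'   hits).
#' @param species_sep Subject-id species separator.
#' @return An [OrthologMatrix-class].
#' @export
buildOrthologMatrix <- function(hits, ortholog_sequences = NULL,
                                permutations = enumeratePermutations(),
                                evalue_cutoff = 1e-5,
                                min_template_len = 9L,
                                query_species = "Arabidopsis_thaliana",
                                species = NULL, candidates = NULL,
                                species_sep = "|") {
    if (is.null(hits$species))
        hits$species <- vapply(strsplit(hits$sseqid, species_sep,
                                        fixed = TRUE), `[[`, "", 1L)
    if (is.null(candidates)) candidates <- unique(hits$qseqid)
    if (is.null(species))
        species <- union(query_species, unique(hits$species))
    if (!is.null(ortholog_sequences) && is(ortholog_sequences, "DNAStringSet"))
        ortholog_sequences <- as.character(ortholog_sequences)
    m <- matrix("absent", nrow = length(candidates), ncol = length(species),
                dimnames = list(candidates, species))
    pass <- hits[is.finite(hits$evalue) & hits$evalue <= evalue_cutoff &
                 hits$qseqid %in% candidates &
                 hits$species %in% species, , drop = FALSE]
    if (nrow(pass)) {
        for (grp in split(pass, list(pass$qseqid, pass$species),
                          drop = TRUE)) {
            cand <- grp$qseqid[1L]
            sp <- grp$species[1L]
            best <- grp[which.max(grp$bitscore), ]
            status <- "present"
            subj <- ortholog_sequences[best$sseqid]
            if (is.null(ortholog_sequences) || is.na(subj)) {
                warning(sprintf(
                    "subject sequence %s missing; %s/%s marked present, template status unknown",
                    best$sseqid, cand, sp), call. = FALSE)
            } else {
                best_match <- longestTemplate(unname(subj), permutations)
                if (!is.null(best_match) &&
                    best_match$length >= min_template_len)
                    status <- "present_with_template"
            }
            m[cand, sp] <- status
        }
    }
    new("OrthologMatrix", matrix = m, query_species = query_species)
}

#' Conservation filter
#'
#' Keeps candidates with a template-bearing ortholog in at least
#' `min_relatives` species other than the query species.
#'
#' @param x An [OrthologMatrix-class].
#' @param min_relatives Minimum count of relatives (default 3).
#' @return Character vector of surviving candidate ids (row order kept).
#' @export
conservationFilter <- function(x, min_relatives = 3L) {
    stopifnot(is(x, "OrthologMatrix"))
    n <- relativeCounts(x)
    as.character(names(n)[n >= min_relatives])
}

#' Accessors for ortholog matrices
#'
#' @param x An [OrthologMatrix-class].
#' @param status Which status to count per candidate across relatives
#'   (query species excluded); default `"present_with_template"`.
#' @param ... Ignored.
#' @return `presenceMatrix()`: the candidate-by-species character matrix;
#'   `querySpecies()`: the query species; `relativeCounts()`: named integer
#'   vector of per-candidate relative counts.
#' @name orthologMatrix-accessors
NULL

#' @rdname orthologMatrix-accessors
#' @export
setMethod("presenceMatrix", "OrthologMatrix", function(x) x@matrix)

#' @rdname orthologMatrix-accessors
#' @export
setMethod("querySpecies", "OrthologMatrix", function(x) x@query_species)

#' @rdname orthologMatrix-accessors
#' @export
setMethod("relativeCounts", "OrthologMatrix",
    function(x, status = "present_with_template", ...) {
    rel <- setdiff(colnames(x@matrix), x@query_species)
    sub <- x@matrix[, rel, drop = FALSE]
    if (identical(status, "present"))
        hit <- sub %in% c("present", "present_with_template")
    else hit <- sub == status
    counts <- rowSums(matrix(hit, nrow = nrow(sub)))
    stats::setNames(as.integer(counts), rownames(sub))
})

setMethod("show", "OrthologMatrix", function(object) {
    m <- object@matrix
    cat(sprintf("OrthologMatrix: %d candidate(s) x %d species (query: %s)\n",
                nrow(m), ncol(m), object@query_species))
    n <- relativeCounts(object)
    for (id in utils::head(rownames(m), 8L))
        cat(sprintf("  %s: %d relative(s) with template\n", id, n[[id]]))
    if (nrow(m) > 8L) cat("  ...\n")
})

#' Branch-sites likelihood-ratio test helper
#'
#' Decision rule for branch-sites tests of positive selection: the statistic
#' is twice the log-likelihood improvement of the alternative model over the
#' null (clamped at zero), compared against a chi-squared distribution with
#' one degree of freedom. A log-likelihood improvement of at least
#' qchisq(0.95, 1)/2 = 1.9207 (printed as 1.92 at two decimals) is
#' significant at alpha = 0.05.
#'
#' @param lnl_alt,lnl_null Finite log-likelihoods of the alternative and
#'   null models.
#' @param alpha Significance level (default 0.05).
#' @return List with `lnl_alt`, `lnl_null`, `statistic` (`= max(0,
#'   2*(lnl_alt - lnl_null))`), `p_value` (upper chi-squared(1) tail; 1 when
#'   the statistic is 0) and `significant` (`p_value < alpha`).
#' @examples
#' branchSiteLRT(-1000, -1002)$significant  # TRUE (delta-lnL = 2)
#' @export
branchSiteLRT <- function(lnl_alt, lnl_null, alpha = 0.05) {
    if (!is.finite(lnl_alt) || !is.finite(lnl_null))
        stop("log-likelihoods must be finite", call. = FALSE)
    stat <- max(0, 2 * (lnl_alt - lnl_null))
    p <- if (stat == 0) 1 else stats::pchisq(stat, df = 1, lower.tail = FALSE)
    list(lnl_alt = lnl_alt, lnl_null = lnl_null, statistic = stat,
         p_value = p, significant = p < alpha)
}
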