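#' @include scan.R AllGenerics.R
NULL

#' Funnel configuration
#'
#' Parameters of the four-stage TER candidate funnel. Defaults reproduce the
#' published screen: mean TPM strictly above 1 across experiments, discard of
#' candidates overlapping known genes by at least 1 bp on either strand, a
#' template domain of at least 9 nt among the 9-19 nt permutations of
#' TTTAGGG (both strands), and template-bearing orthologs at E-value <= 1e-5
#' in at least 3 relatives.
#'
#' @param tpm_threshold Mean-TPM survival threshold (strict inequality).
#' @param min_template_len Minimum template-domain length in nt.
#' @param min_relatives Minimum number of relatives with a template-bearing
#'   ortholog.
#' @param evalue_cutoff Maximum homology-hit E-value counted as presence.
#' @param unit,min_len,max_len,both_strands Permutation enumeration
#'   parameters, see [enumeratePermutations()].
#' @param stranded_overlap Require same-strand overlap in the known-gene
#'   discard (default `FALSE`: any-strand overlap discards).
#' @param query_species Species of the query transcripts, excluded from
#'   relative counts.
#' @return Named list of validated parameters.
#' @export
funnelConfig <- function(tpm_threshold = 1, min_template_len = 9L,
                         min_relatives = 3L, evalue_cutoff = 1e-5,
                         unit = "TTTAGGG", min_len = 9L, max_len = 19L,
                         both_strands = TRUE, stranded_overlap = FALSE,
                         query_species = "Arabidopsis_thaliana") {
    cfg <- list(tpm_threshold = as.numeric(tpm_threshold),
                min_template_len = as.integer(min_template_len),
                min_relatives = as.integer(min_relatives),
                evalue_cutoff = as.numeric(evalue_cutoff),
                unit = unit, min_len = as.integer(min_len),
                max_len = as.integer(max_len),
                both_strands = isTRUE(both_strands),
                stranded_overlap = isTRUE(stranded_overlap),
                query_species = query_species)
    num <- c("tpm_threshold", "min_template_len", "min_relatives",
             "evalue_cutoff")
    if (any(vapply(cfg[num], function(v) !is.finite(v) || v <= 0, logical(1))))
        stop("funnel thresholds must be strictly positive", call. = FALSE)
    cfg
}

#' Convert a counts matrix to TPM
#'
#' Transcripts-per-million normalization, accounting for feature length and
#' sequencing depth: per experiment, each feature's count is divided by its
#' length in kilobases, and the resulting rates are rescaled to sum to one
#' million. A column with no counts stays all-zero.
#'
#' @param counts Feature-by-experiment matrix of non-negative counts with
#'   feature rownames.
#' @param lengths Feature lengths in nucleotides: either an unnamed vector
#'   aligned with the rows or a named vector covering all rownames.
#' @return Numeric matrix of TPM values with the same dimnames; every column
#'   with nonzero counts sums to 1e6.
#' @examples
#' computeTPM(matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "e1")),
#'            c(a = 1000, b = 2000))
#' @export
computeTPM <- function(counts, lengths) {
    counts <- as.matrix(counts)
    if (nrow(counts) > 0L && is.null(rownames(counts)))
        stop("counts must have feature rownames", call. = FALSE)
    if (any(counts < 0, na.rm = TRUE))
        stop("counts must be non-negative", call. = FALSE)
    if (!is.null(names(lengths))) {
        missing <- setdiff(rownames(counts), names(lengths))
        if (length(missing))
            stop("no length for feature(s): ",
                 paste(utils::head(missing, 5L), collapse = ", "),
                 call. = FALSE)
        lengths <- lengths[rownames(counts)]
    } else if (length(lengths) != nrow(counts)) {
        stop(sprintf("lengths (%d) do not match counts rows (%d)",
                     length(lengths), nrow(counts)), call. = FALSE)
    }
    lengths <- as.numeric(lengths)
    if (any(!is.finite(lengths) | lengths <= 0))
        stop("feature lengths must be strictly positive", call. = FALSE)
    rate <- counts / (lengths / 1000)
    denom <- colSums(rate)
    denom[denom == 0] <- 1  # all-zero column stays all-zero
    tpm <- sweep(rate, 2L, denom, "/") * 1e6
    dimnames(tpm) <- dimnames(counts)
    tpm
}

#' Mean-expression survival filter
#'
#' Keeps features whose arithmetic mean TPM across all experiments (zeros
#' included) is strictly greater than the threshold.
#'
#' @param tpm TPM matrix from [computeTPM()].
#' @param threshold Strict lower bound on the mean (default 1).
#' @return Character vector of surviving feature ids, in input order.
#' @export
meanExpressionFilter <- function(tpm, threshold = 1) {
    stopifnot(is.matrix(tpm), nrow(tpm) == 0L || !is.null(rownames(tpm)))
    if (nrow(tpm) == 0L) return(character(0))
    rownames(tpm)[rowMeans(tpm) > threshold]
}

#' Known-gene overlap filter
#'
#' Discards candidates with at least 1 bp of exonic overlap with any
#' annotated gene. Overlap is strand-agnostic by default; set
#' `stranded = TRUE` to only discard same-strand overlaps. Candidates on
#' chromosomes absent from the annotation cannot overlap and are retained
#' with a warning.
#'
#' @param candidates [GenomicRanges::GRanges] of candidate exons with a
#'   `transcript_id` metadata column (several exons may share an id), or a
#'   [GenomicRanges::GRangesList] named by transcript.
#' @param annotation [GenomicRanges::GRanges] of known genes.
#' @param stranded Require same-strand overlap (default `FALSE`).
#' @return Character vector of surviving transcript ids.
#' @export
overlapFilter <- function(candidates, annotation, stranded = FALSE) {
    if (is(candidates, "GRangesList"))
        candidates <- unlist(candidates, use.names = TRUE)
    ids <- .transcriptIds(candidates)
    unknown <- setdiff(as.character(GenomeInfoDb::seqnames(candidates)),
                       as.character(GenomeInfoDb::seqnames(annotation)))
    if (length(unknown))
        warning("candidate chromosome(s) not in annotation, retained: ",
                paste(unique(unknown), collapse = ", "), call. = FALSE)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
        candidates, annotation, minoverlap = 1L,
        ignore.strand = !stranded))
    discarded <- unique(ids[S4Vectors::queryHits(hits)])
    unique(ids)[!unique(ids) %in% discarded]
}

.transcriptIds <- function(gr) {
    if (!length(gr)) return(character(0))
    md <- S4Vectors::mcols(gr)
    if (!is.null(md$transcript_id)) as.character(md$transcript_id)
    else if (!is.null(names(gr))) names(gr)
    else stop("candidates need a transcript_id column or names",
              call. = FALSE)
}

#' Template-domain filter
#'
#' Keeps candidates whose longest template domain (either strand, collapsed
#' maximal matches) reaches the minimum length.
#'
#' @param sequences Named [Biostrings::DNAStringSet] or character vector of
#'   candidate sequences.
#' @param ids Candidate ids to screen (default: all sequences). A candidate
#'   without a sequence is an error naming it.
#' @param permutations A [TemplatePermutations-class].
#' @param min_template_len Minimum surviving template length (default 9).
#' @return List with `survivors` (character vector) and `matches` (data.frame
#'   of each screened candidate's longest match; candidates with no match at
#'   all are absent).
#' @export
templateFilter <- function(sequences, ids = NULL,
                           permutations = enumeratePermutations(),
                           min_template_len = 9L) {
    if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
    stopifnot(is.character(sequences), !is.null(names(sequences)))
    if (is.null(ids)) ids <- names(sequences)
    missing <- setdiff(ids, names(sequences))
    if (length(missing))
        stop("no sequence for candidate(s): ",
             paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    best <- .longestPerSequence(sequences[ids], permutations)
    surv <- best$seq_id[best$length >= min_template_len]
    list(survivors = ids[ids %in% surv], matches = best)
}

#' Rank candidates by mean expression
#'
#' Orders surviving candidates by descending mean TPM, ties broken
#' lexicographically by id.
#'
#' @param ids Candidate ids (must be rows of `tpm`).
#' @param tpm TPM matrix.
#' @return data.frame with columns `id` and `mean_tpm`, ranked.
#' @export
rankCandidates <- function(ids, tpm) {
    if (!length(ids))
        return(data.frame(id = character(), mean_tpm = numeric(),
                          stringsAsFactors = FALSE))
    stopifnot(all(ids %in% rownames(tpm)))
    means <- rowMeans(tpm[ids, , drop = FALSE])
    o <- order(-means, ids)
    data.frame(id = ids[o], mean_tpm = unname(means[o]),
               stringsAsFactors = FALSE)
}

.makeFunnelReport <- function(stage_names, survivor_list, n0, ranking, config) {
    n_out <- vapply(survivor_list, length, integer(1))
    stages <- data.frame(stage = stage_names,
                         n_in = c(n0, n_out[-length(n_out)]),
                         n_out = unname(n_out),
                         stringsAsFactors = FALSE)
    new("FunnelReport", stages = stages, survivors = survivor_list,
        ranking = ranking, config = config)
}

#' @describeIn runFunnel Funnel over explicit in-memory inputs. `transcripts`
#'   is a GRanges/GRangesList of candidate exons, `sequences` a named
#'   DNAStringSet (used both for feature lengths and the template screen),
#'   `annotation` a GRanges of known genes, `hits` a data.frame as returned
#'   by [readHitTable()], and `ortholog_sequences` a named DNAStringSet of
#'   subject loci.
#' @param transcripts Candidate exon coordinates.
#' @param sequences Candidate transcript sequences.
#' @param annotation Known-gene coordinates.
#' @param hits Homology hit table (12-column BLAST tabular data.frame).
#' @param ortholog_sequences Subject sequences for template status.
#' @param config A [funnelConfig()] list.
#' @export
setMethod("runFunnel", "matrix",
    function(x, transcripts, sequences, annotation, hits,
             ortholog_sequences, config = funnelConfig(), ...) {
    counts <- x
    if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
    stopifnot(nrow(counts) == 0L || !is.null(rownames(counts)),
              length(sequences) == 0L || !is.null(names(sequences)))
    feats <- if (is.null(rownames(counts))) character(0) else
        rownames(counts)
    perms <- enumeratePermutations(config$unit, config$min_len,
                                   config$max_len, config$both_strands)

    lens <- nchar(sequences)
    tpm <- computeTPM(counts, lens)
    s1 <- meanExpressionFilter(tpm, config$tpm_threshold)

    if (is(transcripts, "GRangesList"))
        transcripts <- unlist(transcripts, use.names = TRUE)
    tx_ids <- .transcriptIds(transcripts)
    s2 <- if (length(s1)) {
        overlapFilter(transcripts[tx_ids %in% s1], annotation,
                      stranded = config$stranded_overlap)
    } else character(0)
    s2 <- s1[s1 %in% s2]  # preserve order

    tf <- if (length(s2)) {
        templateFilter(sequences, s2, perms, config$min_template_len)
    } else list(survivors = character(0), matches = .emptyMatches())
    s3 <- tf$survivors

    omat <- buildOrthologMatrix(hits[hits$qseqid %in% s3, , drop = FALSE],
                                ortholog_sequences, perms,
                                evalue_cutoff = config$evalue_cutoff,
                                min_template_len = config$min_template_len,
                                query_species = config$query_species,
                                candidates = s3)
    s4 <- conservationFilter(omat, config$min_relatives)

    ranking <- rankCandidates(s4, tpm)
    tpl_len <- tf$matches$length[match(ranking$id, tf$matches$seq_id)]
    ranking$template_length <- as.integer(tpl_len)
    ranking$n_relatives <- as.integer(
        relativeCounts(omat)[ranking$id])

    .makeFunnelReport(
        c("mean_tpm", "overlap", "template", "conservation"),
        list(mean_tpm = s1, overlap = s2, template = s3, conservation = s4),
        length(feats), ranking, config)
})

#' @describeIn runFunnel Funnel over a [SyntheticDataset-class]: all inputs
#'   are taken from the dataset's slots.
#' @export
setMethod("runFunnel", "SyntheticDataset",
    function(x, config = funnelConfig(), ...) {
    runFunnel(x@counts, transcripts = x@transcripts,
              sequences = x@sequences, annotation = x@annotation,
              hits = x@hits, ortholog_sequences = x@ortholog_sequences,
              config = config)
})

#' Accessors for funnel reports
#'
#' @param x A [FunnelReport-class].
#' @param stage Stage name (one of `stageCounts(x)$stage`).
#' @return `stageCounts()`: the per-stage data.frame; `survivors()`: the
#'   surviving ids at a stage; `ranking()`: the final ranking data.frame.
#' @name stageCounts
#' @aliases survivors ranking
NULL

#' @rdname stageCounts
#' @export
setMethod("stageCounts", "FunnelReport", function(x) x@stages)

#' @rdname stageCounts
#' @export
setMethod("survivors", "FunnelReport", function(x, stage) {
    if (missing(stage)) return(x@survivors)
    if (!stage %in% names(x@survivors))
        stop("unknown stage: ", stage, call. = FALSE)
    x@survivors[[stage]]
})

#' @rdname stageCounts
#' @export
setMethod("ranking", "FunnelReport", function(x) x@ranking)

setMethod("show", "FunnelReport", function(object) {
    cat("TER candidate funnel report\n")
    st <- object@stages
    for (i in seq_len(nrow(st)))
        cat(sprintf("  %-12s %6d -> %d\n", st$stage[i], st$n_in[i],
                    st$n_out[i]))
    cat(sprintf("final candidates: %d\n", nrow(object@ranking)))
    if (nrow(object@ranking))
        print(utils::head(object@ranking, 5L), row.names = FALSE)
})
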