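#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Set of telomere-repeat template permutations
#'
#' A [Biostrings::DNAStringSet] of all distinct fixed-length windows of the
#' infinite tandem repetition of a telomere repeat unit (and, optionally, of
#' its reverse complement), together with the enumeration parameters.
#' Element metadata columns record for each window its length, the strand of
#' the generating unit (`"+"` forward, `"-"` reverse complement) and the
#' circular offset in `[0, period)` at which the window starts.
#'
#' @slot unit Character scalar; the repeat unit (e.g. `"TTTAGGG"`).
#' @slot min_len,max_len Integer window-length range in nucleotides.
#' @slot both_strands Logical; whether reverse-complement windows are included.
#'
#' @seealso [enumeratePermutations()], [scanTemplates()]
#' @export
setClass("TemplatePermutations",
    contains = "DNAStringSet",
    representation(
        unit = "character",
        min_len = "integer",
        max_len = "integer",
        both_strands = "logical"
    )
)

setValidity("TemplatePermutations", function(object) {
    msg <- character()
    if (length(object@unit) != 1L || !nzchar(object@unit))
        msg <- c(msg, "'unit' must be a non-empty character scalar")
    if (object@min_len < 1L || object@min_len > object@max_len)
        msg <- c(msg, "window length range must satisfy 1 <= min_len <= max_len")
    s <- as.character(object)
    if (anyDuplicated(s))
        msg <- c(msg, "permutation sequences must be pairwise distinct")
    w <- Biostrings::width(object)
    if (length(w) && (min(w) < object@min_len || max(w) > object@max_len))
        msg <- c(msg, "window widths outside [min_len, max_len]")
    if (length(msg)) msg else TRUE
})

#' Per-stage report of the TER candidate funnel
#'
#' Records, for each stage of the candidate funnel (mean-TPM expression
#' filter, known-gene overlap discard, template-domain screen, conservation
#' filter), the number of features entering and surviving, the surviving
#' feature identifiers, and the final ranking of candidates by mean TPM.
#'
#' @slot stages data.frame with columns `stage`, `n_in`, `n_out`.
#' @slot survivors Named list of character vectors, one per stage (same order
#'   as `stages$stage`).
#' @slot ranking data.frame with columns `id`, `mean_tpm`, `template_length`,
#'   `n_relatives`, ordered by decreasing mean TPM (ties by id).
#' @slot config List of funnel parameters used (see [funnelConfig()]).
#'
#' @seealso [runFunnel()], [writeReport()]
#' @export
setClass("FunnelReport",
    representation(
        stages = "data.frame",
        survivors = "list",
        ranking = "data.frame",
        config = "list"
    )
)

setValidity("FunnelReport", function(object) {
    msg <- character()
    st <- object@stages
    if (!all(c("stage", "n_in", "n_out") %in% names(st)))
        msg <- c(msg, "'stages' needs columns stage, n_in, n_out")
    if (nrow(st)) {
        if (any(st$n_out > st$n_in))
            msg <- c(msg, "stage output count exceeds input count")
        if (nrow(st) > 1L && any(st$n_in[-1L] != st$n_out[-nrow(st)]))
            msg <- c(msg, "stage inputs must chain from previous outputs")
        if (!identical(sort(names(object@survivors)), sort(st$stage)))
            msg <- c(msg, "'survivors' names must match stage names")
        nest <- vapply(seq_len(nrow(st))[-1L], function(k) {
            all(object@survivors[[st$stage[k]]] %in%
                object@survivors[[st$stage[k - 1L]]])
        }, logical(1))
        if (!all(nest))
            msg <- c(msg, "stage survivors must nest within the previous stage")
    }
    if (!all(c("id", "mean_tpm") %in% names(object@ranking)))
        msg <- c(msg, "'ranking' needs columns id and mean_tpm")
    if (length(msg)) msg else TRUE
})

#' Ortholog presence matrix for conservation screening
#'
#' Candidate-by-species matrix with values `"absent"`, `"present"` or
#' `"present_with_template"`. A species is `present` when it has at least one
#' homology hit at or below the E-value cutoff; `present_with_template` when
#' the best such hit's subject sequence additionally carries a telomere
#' template domain of at least the configured minimum length.
#'
#' @slot matrix Character matrix, rows = candidate ids, columns = species.
#' @slot query_species Character scalar; excluded from relative counts.
#'
#' @seealso [buildOrthologMatrix()], [conservationFilter()]
#' @export
setClass("OrthologMatrix",
    representation(
        matrix = "matrix",
        query_species = "character"
    )
)

.ORTHO_LEVELS <- c("absent", "present", "present_with_template")

setValidity("OrthologMatrix", function(object) {
    msg <- character()
    m <- object@matrix
    if (!is.character(m))
        msg <- c(msg, "matrix must be character")
    else if (!all(m %in% .ORTHO_LEVELS))
        msg <- c(msg, sprintf("values must be one of: %s",
                              paste(.ORTHO_LEVELS, collapse = ", ")))
    if ((nrow(m) > 0L && is.null(rownames(m))) ||
        (ncol(m) > 0L && is.null(colnames(m))))
        msg <- c(msg, "matrix must have candidate rownames and species colnames")
    if (length(object@query_species) != 1L)
        msg <- c(msg, "'query_species' must be a single species name")
    if (length(msg)) msg else TRUE
})

#' Substrate utilization profile
#'
#' Species-by-oligo matrix of observed telomerase product-length differences
#' relative to a baseline oligo, on the integer 0-6 quadrant scale used for
#' TRAP product ladders with a 7-nt telomere repeat. Missing observations are
#' `NA`; the baseline column is identically zero.
#'
#' @slot values Integer matrix, rows = species, columns = oligos; entries in
#'   0..6 or NA.
#' @slot baseline Character scalar; column name of the baseline oligo.
#'
#' @seealso [buildProfile()], [profileDistance()], [upgmaCluster()]
#' @export
setClass("UtilizationProfile",
    representation(
        values = "matrix",
        baseline = "character"
    )
)

setValidity("UtilizationProfile", function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v))
        msg <- c(msg, "profile values must be numeric")
    else {
        ok <- is.na(v) | (v == as.integer(v) & v >= 0 & v <= 6)
        if (!all(ok))
            msg <- c(msg, "profile values must be integers in 0..6 (or NA)")
    }
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "profile needs species rownames and oligo colnames")
    if (length(object@baseline) != 1L ||
        !(object@baseline %in% colnames(v)))
        msg <- c(msg, "'baseline' must name one profile column")
    else if (!all(v[, object@baseline] == 0, na.rm = FALSE))
        msg <- c(msg, "baseline column must be all zeros")
    if (length(msg)) msg else TRUE
})

#' Ground-truth-labelled synthetic RIP-seq dataset
#'
#' Container for a seeded synthetic dataset emulating the downstream products
#' of a telomerase RNA immunoprecipitation study: assembled candidate
#' transcripts (coordinates and sequences), a known-gene annotation, a
#' feature-by-experiment counts matrix, per-species ortholog sequences with a
#' BLAST-style homology hit table, and a truth table recording each
#' transcript's class and the funnel stage designed to remove it.
#'
#' @slot sequences [Biostrings::DNAStringSet] of candidate transcript
#'   sequences (strand-resolved, names = transcript ids).
#' @slot transcripts [GenomicRanges::GRanges] of candidate transcript exons
#'   with `transcript_id`/`gene_id` metadata.
#' @slot annotation [GenomicRanges::GRanges] of known genes.
#' @slot counts Integer matrix, features x experiments.
#' @slot hits data.frame in 12-column BLAST tabular layout.
#' @slot ortholog_sequences [Biostrings::DNAStringSet] of ortholog loci,
#'   names = `species|candidate` subject ids.
#' @slot genome [Biostrings::DNAStringSet] of the synthetic chromosome.
#' @slot truth data.frame with columns `id`, `class`, `designed_stage`.
#' @slot config List; the [syntheticConfig()] used, including the seed.
#'
#' @seealso [generateDataset()], [runFunnel()], [writeSyntheticDataset()]
#' @export
setClass("SyntheticDataset",
    representation(
        sequences = "DNAStringSet",
        transcripts = "GRanges",
        annotation = "GRanges",
        counts = "matrix",
        hits = "data.frame",
        ortholog_sequences = "DNAStringSet",
        genome = "DNAStringSet",
        truth = "data.frame",
        config = "list"
    )
)

setValidity("SyntheticDataset", function(object) {
    msg <- character()
    ids <- names(object@sequences)
    if (!identical(sort(ids), sort(rownames(object@counts))))
        msg <- c(msg, "counts rows must match sequence names")
    if (!all(object@truth$id %in% ids))
        msg <- c(msg, "truth ids must be candidate transcript ids")
    ok_stage <- c("survivor", "mean_tpm", "overlap", "template", "conservation")
    if (!all(object@truth$designed_stage %in% ok_stage))
        msg <- c(msg, "unknown designed_stage in truth table")
    if (length(msg)) msg else TRUE
})
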