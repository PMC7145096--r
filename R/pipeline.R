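#' @include synthetic.R
NULL

#' Read and write counts matrices
#'
#' Tab-separated counts: first column `feature_id`, header row of experiment
#' ids, integer counts.
#'
#' @param path File path.
#' @return `readCountsMatrix()`: integer matrix with feature rownames.
#' @export
readCountsMatrix <- function(path) {
    if (!file.exists(path))
        stop("no such counts file: ", path, call. = FALSE)
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(d) < 2L)
        stop("counts file needs a feature_id column plus experiments",
             call. = FALSE)
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d[[1L]]
    storage.mode(m) <- "integer"
    m
}

#' @rdname readCountsMatrix
#' @param counts Matrix with feature rownames.
#' @export
writeCountsMatrix <- function(counts, path) {
    d <- data.frame(feature_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read candidate transcripts or gene annotation from GTF
#'
#' GTF coordinates are 1-based inclusive on disk;
#' [GenomicRanges::GRanges] keeps that convention and all package logic uses
#' half-open arithmetic internally via IRanges. `readCandidateGtf()` returns
#' exon features named by `transcript_id`; `readAnnotationGtf()` returns
#' gene features (falling back to all features when no `type` column or no
#' gene rows are present).
#'
#' @param path GTF file path.
#' @return A [GenomicRanges::GRanges].
#' @export
readCandidateGtf <- function(path) {
    if (!file.exists(path)) stop("no such GTF: ", path, call. = FALSE)
    gr <- rtracklayer::import(path, format = "gtf")
    if (!is.null(gr$type) && any(gr$type == "exon"))
        gr <- gr[gr$type == "exon"]
    if (is.null(gr$transcript_id))
        stop("candidate GTF lacks transcript_id attributes", call. = FALSE)
    names(gr) <- gr$transcript_id
    gr
}

#' @rdname readCandidateGtf
#' @export
readAnnotationGtf <- function(path) {
    if (!file.exists(path)) stop("no such GTF: ", path, call. = FALSE)
    gr <- rtracklayer::import(path, format = "gtf")
    if (!is.null(gr$type) && any(gr$type == "gene"))
        gr <- gr[gr$type == "gene"]
    gr
}

#' Run the full discovery pipeline from files on disk
#'
#' Reads the counts matrix, candidate transcript coordinates and sequences,
#' known-gene annotation, homology hit table and ortholog sequences, runs
#' [runFunnel()], and (unless `dry_run`) writes the report and per-candidate
#' template annotations into `out_dir`. Per-stage counts are logged to
#' stderr as machine-parseable `stage <name> input_n <n> output_n <n>`
#' lines.
#'
#' @param counts,candidates_gtf,candidates_fasta,annotation_gtf,hits,orthologs_fasta
#'   Input file paths.
#' @param out_dir Output directory.
#' @param config A [funnelConfig()].
#' @param dry_run Validate and read inputs, run nothing, write nothing.
#' @return The [FunnelReport-class] (invisibly `NULL` for a dry run).
#' @export
runPipeline <- function(counts, candidates_gtf, candidates_fasta,
                        annotation_gtf, hits, orthologs_fasta,
                        out_dir = ".", config = funnelConfig(),
                        dry_run = FALSE) {
    paths <- c(counts = counts, candidates_gtf = candidates_gtf,
               candidates_fasta = candidates_fasta,
               annotation_gtf = annotation_gtf, hits = hits,
               orthologs_fasta = orthologs_fasta)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
        stop("missing input file(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
    cm <- readCountsMatrix(counts)
    tx <- readCandidateGtf(candidates_gtf)
    sq <- Biostrings::readDNAStringSet(candidates_fasta)
    names(sq) <- sub("\\s.*", "", names(sq))
    ann <- readAnnotationGtf(annotation_gtf)
    ht <- readHitTable(hits)
    orth <- Biostrings::readDNAStringSet(orthologs_fasta)
    names(orth) <- sub("\\s.*", "", names(orth))
    if (dry_run) {
        message("dry run: inputs validated (",
                nrow(cm), " features x ", ncol(cm), " experiments)")
        return(invisible(NULL))
    }
    t0 <- Sys.time()
    report <- runFunnel(cm, transcripts = tx, sequences = sq,
                        annotation = ann, hits = ht,
                        ortholog_sequences = orth, config = config)
    st <- stageCounts(report)
    for (i in seq_len(nrow(st)))
        message(sprintf("stage %s input_n %d output_n %d",
                        st$stage[i], st$n_in[i], st$n_out[i]))
    message(sprintf("pipeline done in %.1f s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeReport(report, file.path(out_dir, "funnel_report"))
    final <- survivors(report, "conservation")
    if (length(final)) {
        perms <- enumeratePermutations(config$unit, config$min_len,
                                       config$max_len, config$both_strands)
        ann_tab <- scanTemplates(as.character(sq[final]), perms)
        utils::write.table(ann_tab,
                           file.path(out_dir, "candidate_templates.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report
}

#' Serialize and restore funnel reports
#'
#' `writeReport()` writes the same content in two encodings: a JSON file
#' (`<base>.json`, round-trippable with `readReport()`) and two TSV tables
#' (`<base>_stages.tsv` with survivor ids collapsed comma-separated, and
#' `<base>_ranking.tsv`).
#'
#' @param report A [FunnelReport-class].
#' @param base Output path prefix.
#' @return `writeReport()`: invisibly the written paths; `readReport()`: the
#'   restored [FunnelReport-class].
#' @export
writeReport <- function(report, base) {
    stopifnot(is(report, "FunnelReport"))
    dir.create(dirname(base), showWarnings = FALSE, recursive = TRUE)
    st <- report@stages
    st$survivor_ids <- vapply(report@survivors[st$stage], paste,
                              character(1), collapse = ",")
    paths <- c(json = paste0(base, ".json"),
               stages = paste0(base, "_stages.tsv"),
               ranking = paste0(base, "_ranking.tsv"))
    utils::write.table(st, paths["stages"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(report@ranking, paths["ranking"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    payload <- list(stages = report@stages,
                    survivors = report@survivors,
                    ranking = report@ranking,
                    config = report@config)
    jsonlite::write_json(payload, paths["json"], auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(paths)
}

#' @rdname writeReport
#' @param path JSON path written by `writeReport()`.
#' @export
readReport <- function(path) {
    p <- jsonlite::read_json(path, simplifyVector = TRUE)
    surv <- lapply(p$survivors, function(v) {
        if (is.null(v) || !length(v)) character(0) else as.character(v)
    })
    ranking <- as.data.frame(p$ranking, stringsAsFactors = FALSE)
    if (!nrow(ranking))
        ranking <- data.frame(id = character(), mean_tpm = numeric(),
                              template_length = integer(),
                              n_relatives = integer(),
                              stringsAsFactors = FALSE)
    cfg <- as.list(p$config)
    new("FunnelReport",
        stages = as.data.frame(p$stages, stringsAsFactors = FALSE),
        survivors = surv, ranking = ranking, config = cfg)
}

#' First funnel stage at which each feature was removed
#'
#' For each id, the name of the first stage whose survivor set does not
#' contain it, or `"survivor"` when it passes every stage. Features absent
#' from the funnel input are reported as removed at the first stage.
#'
#' @param report A [FunnelReport-class].
#' @param ids Feature ids to classify.
#' @return Named character vector.
#' @export
removalStage <- function(report, ids) {
    stopifnot(is(report, "FunnelReport"))
    st <- report@stages$stage
    out <- vapply(ids, function(id) {
        for (s in st) if (!id %in% report@survivors[[s]]) return(s)
        "survivor"
    }, character(1))
    stats::setNames(out, ids)
}
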