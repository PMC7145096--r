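#' @include funnel.R conservation.R
NULL

.DEFAULT_PANEL <- c("Arabidopsis_thaliana", "Arabidopsis_lyrata",
                    "Capsella_rubella", "Brassica_oleracea", "Brassica_rapa",
                    "Eutrema_salsugineum", "Schrenkiella_parvula",
                    "Aethionema_arabicum", "Tarenaya_hassleriana")

#' Configuration of the synthetic RIP-seq dataset generator
#'
#' Defines the study conditions emulated by [generateDataset()]: 20 pull-down
#' experiments, a panel of one query species plus eight relatives, a planted
#' template-bearing TER transcript, one decoy per funnel stage, and
#' negative-binomial background counts with an IP-enrichment multiplier for
#' the planted TER.
#'
#' @param seed Integer RNG seed; a fixed seed makes the dataset
#'   reproducible.
#' @param n_experiments Number of IP experiments (default 20).
#' @param n_background Number of background transcripts (default 1000).
#' @param background_length_range Min/max background transcript length in nt.
#' @param planted_template_len Template length planted in the TER and in the
#'   conserved decoys (default 11 nt; must be at least `min_template_len`).
#' @param nb_mean,nb_dispersion Negative-binomial mean and size (dispersion)
#'   of per-experiment background counts.
#' @param ip_enrichment_factor Multiplier (>= 1) on the planted TER's count
#'   mean, emulating immunoprecipitation enrichment.
#' @param low_expression_mean Count mean of the low-expression decoy, chosen
#'   with `low_expression_length` so its expected mean TPM sits well below 1.
#' @param low_expression_length Length of the low-expression decoy in nt.
#' @param substitution_rate Per-site substitution probability applied when
#'   deriving ortholog sequences (template window excluded).
#' @param unit Telomere repeat unit.
#' @param min_template_len,max_template_len Template screen length range.
#' @param n_known_genes Number of annotated genes.
#' @param species_panel Species names; the first is the query species.
#' @return Validated named list of class `synthetic_config`.
#' @export
syntheticConfig <- function(seed = 1L, n_experiments = 20L,
                            n_background = 1000L,
                            background_length_range = c(400L, 1500L),
                            planted_template_len = 11L,
                            nb_mean = 100, nb_dispersion = 10,
                            ip_enrichment_factor = 50,
                            low_expression_mean = 0.1,
                            low_expression_length = 5000L,
                            substitution_rate = 0.1,
                            unit = "TTTAGGG",
                            min_template_len = 9L, max_template_len = 19L,
                            n_known_genes = 10L,
                            species_panel = .DEFAULT_PANEL) {
    cfg <- list(seed = as.integer(seed),
                n_experiments = as.integer(n_experiments),
                n_background = as.integer(n_background),
                background_length_range =
                    as.integer(background_length_range),
                planted_template_len = as.integer(planted_template_len),
                nb_mean = as.numeric(nb_mean),
                nb_dispersion = as.numeric(nb_dispersion),
                ip_enrichment_factor = as.numeric(ip_enrichment_factor),
                low_expression_mean = as.numeric(low_expression_mean),
                low_expression_length = as.integer(low_expression_length),
                substitution_rate = as.numeric(substitution_rate),
                unit = unit,
                min_template_len = as.integer(min_template_len),
                max_template_len = as.integer(max_template_len),
                n_known_genes = as.integer(n_known_genes),
                species_panel = species_panel)
    if (cfg$planted_template_len < cfg$min_template_len)
        stop("planted_template_len must be >= min_template_len",
             call. = FALSE)
    if (cfg$planted_template_len > min(cfg$background_length_range))
        stop("planted template longer than the shortest transcript",
             call. = FALSE)
    if (cfg$ip_enrichment_factor < 1)
        stop("ip_enrichment_factor must be >= 1", call. = FALSE)
    if (cfg$substitution_rate < 0 || cfg$substitution_rate > 1)
        stop("substitution_rate must be in [0, 1]", call. = FALSE)
    if (cfg$n_experiments < 1L || cfg$n_background < 1L)
        stop("need at least one experiment and one background transcript",
             call. = FALSE)
    if (length(cfg$species_panel) < 4L)
        stop("species panel too small for a conservation screen",
             call. = FALSE)
    class(cfg) <- "synthetic_config"
    cfg
}

.BASES <- c("A", "C", "G", "T")

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                              collapse = "")

## Random sequence rejected until it carries no telomeric run of
## >= min_len on either strand.
.cleanSeq <- function(n, perms) {
    repeat {
        s <- .randSeq(n)
        if (is.null(longestTemplate(s, perms))) return(s)
    }
}

## Window of the infinite tandem repetition of `unit` (or its reverse
## complement) starting at circular offset `offset`.
.permWindow <- function(unit, len, offset, strand) {
    u <- if (strand == "-") revComp(unit) else unit
    p <- nchar(u)
    tandem <- strrep(u, ceiling((len + p) / p))
    substr(tandem, offset + 1L, offset + len)
}

## Plant a telomeric window into a clean host so that the longest template
## on either strand is exactly `target_len` (`mutate = TRUE` substitutes the
## window's central base, for the mutated-template decoy, and then requires
## the longest template to fall below `min_len`).
.plantTemplate <- function(host_len, tpl_len, perms, unit,
                           mutate = FALSE, min_len = 9L) {
    ## verification scan must be able to see windows shorter than the screen
    ## minimum (the short-template decoy plants an 8-nt window)
    vperms <- if (tpl_len < perms@min_len)
        enumeratePermutations(unit, tpl_len, perms@max_len,
                              perms@both_strands) else perms
    repeat {
        host <- .cleanSeq(host_len, perms)
        offset <- sample.int(nchar(unit), 1L) - 1L
        strand <- sample(c("+", "-"), 1L)
        w <- .permWindow(unit, tpl_len, offset, strand)
        if (mutate) {
            mid <- (tpl_len + 1L) %/% 2L
            orig <- substr(w, mid, mid)
            substr(w, mid, mid) <- sample(setdiff(.BASES, orig), 1L)
        }
        pos <- sample.int(host_len - tpl_len - 1L, 1L)  # 0-based insert pos
        s <- host
        substr(s, pos + 1L, pos + tpl_len) <- w
        best <- longestTemplate(s, vperms)
        ok <- if (mutate) {
            b9 <- longestTemplate(s, perms)
            is.null(b9) || b9$length < min_len
        } else {
            !is.null(best) && best$length == tpl_len && best$start == pos
        }
        if (ok) return(list(sequence = s, start = pos, len = tpl_len,
                            strand = strand, window = w))
    }
}

.mutateSeq <- function(seq, rate, protect = NULL) {
    if (rate == 0) return(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    idx <- which(stats::runif(length(ch)) < rate)
    if (!is.null(protect))
        idx <- idx[idx <= protect[1L] | idx > protect[2L]]
    for (i in idx) ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
    paste(ch, collapse = "")
}

#' Generate a ground-truth-labelled synthetic dataset
#'
#' Builds the downstream products of a telomerase RIP-seq study at desk
#' scale: background transcripts free of telomeric runs (rejection-sampled),
#' a planted template-bearing TER, one decoy per funnel stage
#' (low-expression, genic-overlap, 8-nt short-template, mutated-template,
#' non-conserved), a counts matrix, a known-gene annotation, per-species
#' ortholog sequences with a homology hit table, a synthetic chromosome, and
#' a truth table recording each transcript's class, designed removal stage
#' and planted template coordinates. Fully deterministic given the seed.
#'
#' @param config A [syntheticConfig()].
#' @return A [SyntheticDataset-class].
#' @examples
#' ds <- generateDataset(syntheticConfig(seed = 1, n_background = 20))
#' @export
generateDataset <- function(config = syntheticConfig()) {
    stopifnot(inherits(config, "synthetic_config"))
    set.seed(config$seed)
    perms <- enumeratePermutations(config$unit, config$min_template_len,
                                   config$max_template_len, TRUE)

    n_bg <- config$n_background
    bg_ids <- sprintf("bg_%04d", seq_len(n_bg))
    decoy_ids <- c("decoy_lowexp", "decoy_genic", "decoy_shorttpl",
                   "decoy_muttpl", "decoy_noncons")
    ids <- c(bg_ids, "ter_1", decoy_ids)

    lr <- config$background_length_range
    bg_len <- sample(lr[1L]:lr[2L], n_bg, replace = TRUE)
    seqs <- character(length(ids))
    names(seqs) <- ids
    truth <- data.frame(
        id = ids,
        class = c(rep("background", n_bg), "ter", "low_expression",
                  "genic_overlap", "short_template", "mutated_template",
                  "non_conserved"),
        designed_stage = c(rep("template", n_bg), "survivor", "mean_tpm",
                           "overlap", "template", "template",
                           "conservation"),
        template_start = NA_integer_, template_len = NA_integer_,
        template_strand = NA_character_,
        stringsAsFactors = FALSE)

    for (i in seq_len(n_bg)) seqs[bg_ids[i]] <- .cleanSeq(bg_len[i], perms)

    plant <- function(id, host_len, tpl_len, mutate = FALSE) {
        p <- .plantTemplate(host_len, tpl_len, perms, config$unit,
                            mutate = mutate,
                            min_len = config$min_template_len)
        seqs[id] <<- p$sequence
        k <- match(id, truth$id)
        truth$template_start[k] <<- p$start
        truth$template_len[k] <<- p$len
        truth$template_strand[k] <<- p$strand
    }
    tlen <- config$planted_template_len
    plant("ter_1", 600L, tlen)
    plant("decoy_lowexp", config$low_expression_length, tlen)
    plant("decoy_genic", 600L, tlen)
    plant("decoy_shorttpl", 600L, config$min_template_len - 1L)
    plant("decoy_muttpl", 600L, tlen, mutate = TRUE)
    plant("decoy_noncons", 600L, tlen)

    ## coordinates on one synthetic chromosome, all candidates intergenic
    ## except the genic decoy, whose annotated gene straddles it
    gaps <- sample(200:500, length(ids), replace = TRUE)
    widths <- nchar(seqs)
    starts <- integer(length(ids))  # 1-based
    cursor <- 1L
    for (i in seq_along(ids)) {
        cursor <- cursor + gaps[i]
        starts[i] <- cursor
        cursor <- cursor + widths[i]
    }
    strands <- sample(c("+", "-"), length(ids), replace = TRUE)
    transcripts <- GenomicRanges::GRanges(
        "chr1",
        IRanges::IRanges(start = starts, width = widths),
        strand = strands,
        type = "exon", source = "TERscreen",
        transcript_id = ids, gene_id = ids)
    names(transcripts) <- ids

    gi <- match("decoy_genic", ids)
    gene_starts <- starts[gi] + 50L
    gene_ends <- starts[gi] + widths[gi] + 100L
    cursor <- cursor + 1000L
    for (g in seq_len(max(config$n_known_genes - 1L, 0L))) {
        w <- sample(800:2000, 1L)
        gene_starts <- c(gene_starts, cursor)
        gene_ends <- c(gene_ends, cursor + w - 1L)
        cursor <- cursor + w + sample(200:500, 1L)
    }
    annotation <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(start = gene_starts, end = gene_ends),
        strand = sample(c("+", "-"), length(gene_starts), replace = TRUE),
        type = "gene", source = "TAIR10_like",
        gene_id = sprintf("AT_gene_%03d", seq_along(gene_starts)))

    counts <- generateCounts(config, truth)

    orth <- generateOrthologs(seqs, truth, config)

    ## synthetic chromosome: random background with candidate loci written in
    chrom_len <- cursor + 500L
    chrom <- sample(.BASES, chrom_len, replace = TRUE)
    for (i in seq_along(ids)) {
        s <- if (strands[i] == "-") revComp(seqs[[i]]) else seqs[[i]]
        chrom[starts[i]:(starts[i] + widths[i] - 1L)] <-
            strsplit(s, "", fixed = TRUE)[[1L]]
    }
    genome <- Biostrings::DNAStringSet(paste(chrom, collapse = ""))
    names(genome) <- "chr1"

    new("SyntheticDataset",
        sequences = Biostrings::DNAStringSet(seqs),
        transcripts = transcripts,
        annotation = annotation,
        counts = counts,
        hits = orth$hits,
        ortholog_sequences = Biostrings::DNAStringSet(orth$sequences),
        genome = genome,
        truth = truth,
        config = unclass(config))
}

#' Generate the synthetic counts matrix
#'
#' Independent negative-binomial counts per feature and experiment:
#' background features at `nb_mean`, the planted TER at
#' `nb_mean * ip_enrichment_factor`, and the low-expression decoy at
#' `low_expression_mean`.
#'
#' @param config A [syntheticConfig()].
#' @param truth Truth table with columns `id` and `class` (from
#'   [generateDataset()]).
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as inside [generateDataset()]).
#' @return Integer matrix, rows = `truth$id`, columns = experiments.
#' @export
generateCounts <- function(config, truth, seed = NULL) {
    stopifnot(inherits(config, "synthetic_config"),
              all(c("id", "class") %in% names(truth)))
    if (!is.null(seed)) set.seed(seed)
    mu <- rep(config$nb_mean, nrow(truth))
    mu[truth$class == "ter"] <- config$nb_mean * config$ip_enrichment_factor
    mu[truth$class == "low_expression"] <- config$low_expression_mean
    n <- nrow(truth)
    ne <- config$n_experiments
    counts <- matrix(
        stats::rnbinom(n * ne, size = config$nb_dispersion, mu = mu),
        nrow = n, ncol = ne,
        dimnames = list(truth$id, sprintf("exp_%02d", seq_len(ne))))
    storage.mode(counts) <- "integer"
    counts
}

#' Generate ortholog sequences and the homology hit table
#'
#' Derives, for each conserved candidate, one ortholog per relative species
#' by per-site substitution at the configured rate with the planted template
#' window shielded from mutation, and writes matching hit-table rows with
#' E-values far below the cutoff. The non-conserved decoy receives
#' template-bearing orthologs in only two relatives plus two above-cutoff
#' rows, so it fails the >= 3 relatives rule by construction. Background
#' transcripts get no hits.
#'
#' @inheritParams generateCounts
#' @param sequences Named character vector (or DNAStringSet) of candidate
#'   sequences.
#' @return List with `sequences` (named character vector of ortholog
#'   sequences, names `species|candidate_ort`) and `hits` (12-column
#'   data.frame).
#' @export
generateOrthologs <- function(sequences, truth, config, seed = NULL) {
    stopifnot(inherits(config, "synthetic_config"))
    if (!is.null(seed)) set.seed(seed)
    if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
    relatives <- config$species_panel[-1L]
    conserved <- truth$id[truth$class %in%
        c("ter", "low_expression", "genic_overlap", "short_template",
          "mutated_template")]
    noncons <- truth$id[truth$class == "non_conserved"]

    orth_seqs <- character()
    rows <- list()
    addRow <- function(cand, sp, sid, seqlen, mism, evalue) {
        rows[[length(rows) + 1L]] <<- data.frame(
            qseqid = cand, sseqid = sid,
            pident = round(100 * (1 - mism / seqlen), 2),
            length = seqlen, mismatch = mism, gapopen = 0L,
            qstart = 1L, qend = seqlen, sstart = 1L, send = seqlen,
            evalue = evalue,
            bitscore = round(2 * seqlen * (1 - mism / seqlen), 1),
            stringsAsFactors = FALSE)
    }
    derive <- function(cand, sp, evalue) {
        k <- match(cand, truth$id)
        protect <- if (!is.na(truth$template_start[k]))
            c(truth$template_start[k],
              truth$template_start[k] + truth$template_len[k]) else NULL
        s <- .mutateSeq(sequences[[cand]], config$substitution_rate, protect)
        sid <- sprintf("%s|%s_ort", sp, cand)
        orth_seqs[sid] <<- s
        addRow(cand, sp, sid, nchar(s),
               sum(strsplit(s, "")[[1L]] !=
                   strsplit(sequences[[cand]], "")[[1L]]), evalue)
    }
    for (cand in conserved) for (sp in relatives)
        derive(cand, sp, 10^-stats::runif(1L, 30, 50))
    for (cand in noncons) {
        for (sp in relatives[1:2])
            derive(cand, sp, 10^-stats::runif(1L, 30, 50))
        # divergent remnants in two more species: hits above the cutoff
        for (sp in relatives[3:4])
            derive(cand, sp, 10^-stats::runif(1L, 1, 3))
    }
    hits <- if (length(rows)) do.call(rbind, rows) else {
        d <- as.data.frame(stats::setNames(rep(list(character(0)), 12L),
                                           .HIT_COLS))
        .coerceHits(d)
    }
    list(sequences = orth_seqs, hits = hits)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `candidates.fa`, `candidates.gtf`, `annotation.gtf`, `counts.tsv`
#' (first column `feature_id`, header row of experiment ids), `hits.tsv`
#' (12-column tabular), `orthologs.fa`, `genome.fa`, `truth.json` and
#' `config.yaml` into `dir`.
#'
#' @param ds A [SyntheticDataset-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
writeSyntheticDataset <- function(ds, dir) {
    stopifnot(is(ds, "SyntheticDataset"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(candidates_fasta = file.path(dir, "candidates.fa"),
               candidates_gtf = file.path(dir, "candidates.gtf"),
               annotation_gtf = file.path(dir, "annotation.gtf"),
               counts = file.path(dir, "counts.tsv"),
               hits = file.path(dir, "hits.tsv"),
               orthologs_fasta = file.path(dir, "orthologs.fa"),
               genome_fasta = file.path(dir, "genome.fa"),
               truth = file.path(dir, "truth.json"),
               config = file.path(dir, "config.yaml"))
    Biostrings::writeXStringSet(ds@sequences, paths["candidates_fasta"])
    rtracklayer::export(ds@transcripts, paths["candidates_gtf"],
                        format = "gtf")
    rtracklayer::export(ds@annotation, paths["annotation_gtf"],
                        format = "gtf")
    writeCountsMatrix(ds@counts, paths["counts"])
    writeHitTable(ds@hits, paths["hits"])
    Biostrings::writeXStringSet(ds@ortholog_sequences,
                                paths["orthologs_fasta"])
    Biostrings::writeXStringSet(ds@genome, paths["genome_fasta"])
    jsonlite::write_json(ds@truth, paths["truth"], dataframe = "columns",
                         na = "null")
    yaml::write_yaml(ds@config, paths["config"])
    invisible(paths)
}

#' @rdname syntheticDataset-accessors
#' @export
setMethod("truthTable", "SyntheticDataset", function(x) x@truth)

#' Accessors for synthetic datasets
#'
#' @param x A [SyntheticDataset-class].
#' @return `truthTable()`: the truth data.frame; `candidateSequences()`: the
#'   candidate [Biostrings::DNAStringSet]; `countsMatrix()`: the counts
#'   matrix.
#' @name syntheticDataset-accessors
NULL

#' @rdname syntheticDataset-accessors
#' @export
setMethod("candidateSequences", "SyntheticDataset", function(x) x@sequences)

#' @rdname syntheticDataset-accessors
#' @export
setMethod("countsMatrix", "SyntheticDataset", function(x) x@counts)

setMethod("show", "SyntheticDataset", function(object) {
    tr <- object@truth
    cat(sprintf(
        "SyntheticDataset: %d transcripts x %d experiments (seed %d)\n",
        nrow(object@counts), ncol(object@counts), object@config$seed))
    cat("  classes:", paste(sprintf("%s=%d", names(table(tr$class)),
                                    table(tr$class)), collapse = ", "), "\n")
    cat(sprintf("  orthologs: %d sequences across %d species\n",
                length(object@ortholog_sequences),
                length(unique(sub("\\|.*", "",
                                  names(object@ortholog_sequences))))))
})
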