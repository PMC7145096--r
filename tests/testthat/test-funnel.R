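test_that("TPM normalization accounts for length and depth", {
    one <- computeTPM(matrix(7L, 1, 1, dimnames = list("f", "e")),
                      c(f = 500))
    expect_equal(one[1, 1], 1e6)
    two <- computeTPM(matrix(c(10L, 10L), 2, 1,
                             dimnames = list(c("a", "b"), "e")),
                      c(a = 1000, b = 2000))
    expect_equal(unname(two[, 1]), c(2 / 3, 1 / 3) * 1e6,
                 tolerance = 1e-12)
    zero <- computeTPM(matrix(0L, 3, 4, dimnames = list(letters[1:3],
                                                        NULL)),
                       c(a = 100, b = 200, c = 300))
    expect_true(all(zero == 0))
})

test_that("TPM columns with any counts sum to one million", {
    set.seed(31)
    counts <- matrix(rpois(200, 40), 20, 10,
                     dimnames = list(sprintf("f%02d", 1:20), NULL))
    lens <- sample(200:2000, 20)
    tpm <- computeTPM(counts, lens)
    expect_equal(unname(colSums(tpm)), rep(1e6, 10), tolerance = 1e-6)
    # independent recomputation of one column
    rate <- counts[, 3] / (lens / 1000)
    expect_equal(unname(tpm[, 3]), unname(1e6 * rate / sum(rate)))
})

test_that("TPM rejects invalid lengths and shapes", {
    m <- matrix(1L, 2, 2, dimnames = list(c("a", "b"), NULL))
    expect_error(computeTPM(m, c(a = 0, b = 10)), "positive")
    expect_error(computeTPM(m, c(10, 20, 30)), "do not match")
    expect_error(computeTPM(m, c(a = 10)), "no length")
})

test_that("mean-expression filter is strict and uses all experiments", {
    tpm <- rbind(flat = rep(1, 20),
                 burst = c(20, rep(0, 19)),
                 above = rep(1.01, 20))
    colnames(tpm) <- sprintf("e%02d", 1:20)
    expect_identical(meanExpressionFilter(tpm, 1), "above")
    # survivor set equals independent recomputation on a random fixture
    set.seed(8)
    tpm2 <- matrix(runif(100 * 20, 0, 3), 100, 20,
                   dimnames = list(sprintf("f%03d", 1:100), NULL))
    expect_identical(meanExpressionFilter(tpm2, 1),
                     rownames(tpm2)[apply(tpm2, 1, mean) > 1])
})

test_that("overlap filter discards >= 1 bp exonic overlap, any strand", {
    cand <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(100, 300, 501), width = 50),
        strand = c("+", "-", "+"),
        transcript_id = c("inside", "partial", "abutting"))
    genes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(50, 340, 551), end = c(200, 360, 600)),
        strand = "-")
    surv <- overlapFilter(cand, genes)
    # GTF-style 1-based closed intervals: [501,550] does not touch [551,600]
    expect_identical(surv, "abutting")
    # stranded mode retains opposite-strand overlaps
    surv_s <- overlapFilter(cand, genes, stranded = TRUE)
    expect_setequal(surv_s, c("inside", "abutting"))
})

test_that("overlap filter matches a brute-force interval oracle", {
    set.seed(12)
    cand <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = sample(1:5000, 60), width = sample(50:400, 60,
                                                                    TRUE)),
        transcript_id = sprintf("c%02d", 1:60))
    genes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = sample(1:5000, 15),
                         width = sample(100:800, 15, TRUE)))
    surv <- overlapFilter(cand, genes)
    cs <- BiocGenerics::start(cand); ce <- BiocGenerics::end(cand)
    gs <- BiocGenerics::start(genes); ge <- BiocGenerics::end(genes)
    brute <- cand$transcript_id[vapply(seq_along(cand), function(i) {
        !any(cs[i] <= ge & gs <= ce[i])
    }, logical(1))]
    expect_setequal(surv, brute)
})

test_that("candidates on unannotated chromosomes are retained with warning", {
    cand <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 100),
                                   transcript_id = "lonely")
    genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e6))
    expect_warning(surv <- overlapFilter(cand, genes), "chrX")
    expect_identical(surv, "lonely")
})

test_that("template filter keeps >= 9 nt domains on either strand", {
    perms <- enumeratePermutations()
    seqs <- c(
        planted12 = paste0(strrep("C", 30), "TTTAGGGTTTAG", strrep("C", 30)),
        short8 = paste0(strrep("C", 30), "TTAGGGTT", strrep("C", 30)),
        rc_only = paste0(strrep("G", 30), "CCCTAAACCCT", strrep("G", 30)))
    tf <- templateFilter(seqs, permutations = perms, min_template_len = 9)
    expect_setequal(tf$survivors, c("planted12", "rc_only"))
    expect_identical(tf$matches$length[tf$matches$seq_id == "planted12"], 12L)
    expect_error(templateFilter(seqs, ids = c("planted12", "ghost")),
                 "ghost")
})

test_that("candidate ranking is by descending mean TPM with id tie-break", {
    tpm <- rbind(a = rep(10, 4), b = rep(3, 4), c = rep(7, 4))
    colnames(tpm) <- paste0("e", 1:4)
    expect_identical(rankCandidates(c("a", "b", "c"), tpm)$id,
                     c("a", "c", "b"))
    tied <- rbind(z = rep(5, 4), m = rep(5, 4), a = rep(5, 4))
    colnames(tied) <- paste0("e", 1:4)
    expect_identical(rankCandidates(c("z", "m", "a"), tied)$id,
                     c("a", "m", "z"))
    set.seed(3)
    tpm5 <- matrix(runif(20), 5, 4, dimnames = list(letters[1:5], NULL))
    r <- rankCandidates(letters[1:5], tpm5)
    expect_identical(r$id, letters[1:5][order(-rowMeans(tpm5))])
})

test_that("funnel stages nest, counts decrease, and order is fixed", {
    ds <- generateDataset(small_config(seed = 21))
    rep <- runFunnel(ds)
    st <- stageCounts(rep)
    expect_identical(st$stage,
                     c("mean_tpm", "overlap", "template", "conservation"))
    expect_true(all(st$n_out <= st$n_in))
    expect_identical(st$n_in[-1], st$n_out[-4])
    sv <- survivors(rep)
    for (k in 2:4)
        expect_true(all(sv[[st$stage[k]]] %in% sv[[st$stage[k - 1]]]))
})

test_that("shuffling feature order does not change the survivor sets", {
    ds <- generateDataset(small_config(seed = 22))
    rep1 <- runFunnel(ds)
    set.seed(99)
    perm <- sample(nrow(countsMatrix(ds)))
    rep2 <- runFunnel(countsMatrix(ds)[perm, ],
                      transcripts = ds@transcripts,
                      sequences = candidateSequences(ds)[perm],
                      annotation = ds@annotation, hits = ds@hits,
                      ortholog_sequences = ds@ortholog_sequences)
    for (s in stageCounts(rep1)$stage)
        expect_setequal(survivors(rep1, s), survivors(rep2, s))
    expect_identical(ranking(rep1)$id, ranking(rep2)$id)
})

test_that("an empty candidate set yields an all-zero report", {
    counts <- matrix(integer(), 0, 3,
                     dimnames = list(character(), paste0("e", 1:3)))
    rep <- runFunnel(counts,
                     transcripts = GenomicRanges::GRanges(),
                     sequences = setNames(character(), character()),
                     annotation = GenomicRanges::GRanges(),
                     hits = generateOrthologs(character(),
                         data.frame(id = character(), class = character(),
                                    template_start = integer(),
                                    template_len = integer()),
                         syntheticConfig())$hits,
                     ortholog_sequences = character())
    expect_true(all(stageCounts(rep)$n_in == 0))
    expect_true(all(stageCounts(rep)$n_out == 0))
    expect_identical(nrow(ranking(rep)), 0L)
})
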