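test_that("hit tables parse, reject malformed lines, and round-trip", {
    tmp <- tempfile(fileext = ".tsv")
    writeLines(c(
        "cand1\tArabidopsis_lyrata|cand1_ort\t95.5\t600\t27\t0\t1\t600\t1\t600\t1e-30\t1100.5",
        "cand1\tCapsella_rubella|cand1_ort\t90.0\t600\t60\t0\t1\t600\t1\t600\t1e-20\t900",
        "cand2\tBrassica_rapa|cand2_ort\t88.2\t500\t59\t1\t1\t500\t1\t500\t0.001\t700"),
        tmp)
    h <- readHitTable(tmp)
    expect_identical(nrow(h), 3L)
    expect_identical(h$species,
                     c("Arabidopsis_lyrata", "Capsella_rubella",
                       "Brassica_rapa"))
    expect_equal(h$evalue, c(1e-30, 1e-20, 1e-3))

    empty <- tempfile(); file.create(empty)
    expect_identical(nrow(readHitTable(empty)), 0L)

    bad <- tempfile()
    writeLines(c("a\tb\tc"), bad)
    expect_error(readHitTable(bad), "line 1")

    # write/read identity on a generated table
    ds <- generateDataset(small_config(seed = 4, n_background = 5))
    out <- tempfile(fileext = ".tsv")
    writeHitTable(ds@hits, out)
    back <- readHitTable(out)
    expect_identical(back$qseqid, ds@hits$qseqid)
    expect_identical(back$sseqid, ds@hits$sseqid)
    expect_equal(back$evalue, ds@hits$evalue, tolerance = 1e-6)
    expect_equal(back$bitscore, ds@hits$bitscore, tolerance = 1e-6)
    expect_identical(back$mismatch, ds@hits$mismatch)
})

test_that("presence calls respect the E-value cutoff and best-hit rule", {
    perms <- enumeratePermutations()
    tpl10 <- paste0(strrep("C", 20), "TTAGGGTTTA", strrep("C", 20))
    no_tpl <- strrep("C", 50)
    hit <- function(cand, sp, sid, evalue, bits) {
        data.frame(qseqid = cand, sseqid = sid, pident = 90, length = 50,
                   mismatch = 5, gapopen = 0, qstart = 1, qend = 50,
                   sstart = 1, send = 50, evalue = evalue, bitscore = bits,
                   stringsAsFactors = FALSE)
    }
    seqs <- c("sp1|a" = tpl10, "sp2|a" = tpl10, "sp2|a2" = no_tpl)

    # 1e-4 at cutoff 1e-5: above the cutoff, species stays absent
    m1 <- buildOrthologMatrix(hit("a", "sp1", "sp1|a", 1e-4, 100), seqs,
                              perms, query_species = "q")
    expect_identical(presenceMatrix(m1)["a", "sp1"], "absent")

    # 1e-6 with a planted 10-nt template: present_with_template
    m2 <- buildOrthologMatrix(hit("a", "sp1", "sp1|a", 1e-6, 100), seqs,
                              perms, query_species = "q")
    expect_identical(presenceMatrix(m2)["a", "sp1"], "present_with_template")

    # two hits in one species; only the lower-scoring one bears a template:
    # the best hit decides, so the species is present without template
    two <- rbind(hit("a", "sp2", "sp2|a", 1e-10, 80),
                 hit("a", "sp2", "sp2|a2", 1e-12, 200))
    m3 <- buildOrthologMatrix(two, seqs, perms, query_species = "q")
    expect_identical(presenceMatrix(m3)["a", "sp2"], "present")

    # missing subject sequence: present with a warning
    expect_warning(
        m4 <- buildOrthologMatrix(hit("a", "sp3", "sp3|gone", 1e-9, 100),
                                  seqs, perms, query_species = "q"),
        "sp3")
    expect_identical(presenceMatrix(m4)["a", "sp3"], "present")
})

test_that("conservation filter requires template orthologs in >= 3 relatives", {
    mk <- function(n_with) {
        sp <- c("query", paste0("rel", 1:8))
        m <- matrix("absent", 2, 9, dimnames = list(c("x", "y"), sp))
        m["x", 1 + seq_len(n_with)] <- "present_with_template"
        m["y", 2:3] <- "present_with_template"
        new("OrthologMatrix", matrix = m, query_species = "query")
    }
    expect_identical(conservationFilter(mk(3)), c("x"))
    expect_identical(conservationFilter(mk(2)), character(0))
    # randomized matrices match a brute-force recount oracle
    set.seed(17)
    sp <- c("query", paste0("rel", 1:8))
    for (i in 1:25) {
        vals <- matrix(sample(c("absent", "present",
                                "present_with_template"), 9 * 6,
                              replace = TRUE),
                       6, 9, dimnames = list(paste0("c", 1:6), sp))
        om <- new("OrthologMatrix", matrix = vals, query_species = "query")
        brute <- rownames(vals)[vapply(seq_len(6), function(r) {
            sum(vals[r, -1] == "present_with_template") >= 3
        }, logical(1))]
        expect_setequal(conservationFilter(om, 3), brute)
        # counts never exceed presence, presence never exceeds panel - 1
        expect_true(all(relativeCounts(om) <=
                        relativeCounts(om, status = "present")))
        expect_true(all(relativeCounts(om, status = "present") <= 8))
    }
})

test_that("lowering the E-value cutoff never adds a presence mark", {
    ds <- generateDataset(small_config(seed = 30, n_background = 5))
    perms <- enumeratePermutations()
    cutoffs <- c(1e-3, 1e-5, 1e-10, 1e-40)
    rank <- c(absent = 0L, present = 1L, present_with_template = 2L)
    prev <- NULL
    for (ct in cutoffs) {
        m <- presenceMatrix(buildOrthologMatrix(
            ds@hits, ds@ortholog_sequences, perms, evalue_cutoff = ct))
        if (!is.null(prev))
            expect_true(all(rank[m] <= rank[prev]))
        prev <- m
    }
})

test_that("the branch-sites LRT reproduces the chi-squared decision rule", {
    # delta-lnL 1.92: statistic 3.84, p at the alpha = 0.05 boundary
    r <- branchSiteLRT(-1000, -1001.92)
    expect_equal(r$statistic, 3.84)
    expect_equal(r$p_value, 0.05, tolerance = 1e-2)
    # the exact critical value is qchisq(.95, 1)/2 = 1.9207; the decision
    # flips there
    crit <- qchisq(0.95, 1) / 2
    expect_false(branchSiteLRT(crit - 1e-6, 0)$significant)
    expect_true(branchSiteLRT(crit + 1e-6, 0)$significant)
    # no improvement: statistic clamped, p = 1
    r0 <- branchSiteLRT(-50, -50)
    expect_identical(r0$statistic, 0)
    expect_identical(r0$p_value, 1)
    expect_false(r0$significant)
    rneg <- branchSiteLRT(-52, -50)
    expect_identical(rneg$statistic, 0)
    expect_identical(rneg$p_value, 1)
    expect_error(branchSiteLRT(NaN, 0), "finite")
})

test_that("LRT p-values agree with numerical integration of the density", {
    for (d in c(0.5, 1.92, 3, 5, 9)) {
        r <- branchSiteLRT(0, -d)
        expect_equal(r$p_value, oracle_chisq1_tail(2 * d),
                     tolerance = 1e-7, info = paste("delta", d))
    }
    # monotone non-increasing in delta-lnL
    ps <- vapply(seq(0, 6, by = 0.25),
                 function(d) branchSiteLRT(d, 0)$p_value, numeric(1))
    expect_true(all(diff(ps) <= 0))
})
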