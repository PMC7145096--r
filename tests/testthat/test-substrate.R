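tpl <- templateRNA("CUAAACCCUAAACCC")
ggg <- substrateOligo("N15-GGG", 18, "GGG")

test_that("register prediction maximizes terminal pairing, ties to the 3' end", {
    r <- predictRegister(tpl, ggg)
    o <- oracle_register("CUAAACCCUAAACCC", c(0L, 15L), "GGG")
    expect_true(r$annealed)
    expect_identical(r$register, o$p)
    expect_identical(r$paired_length, o$k)
    expect_identical(r$nucleotides_added, o$p)  # region starts at 0

    # single-T tail pairs template A; the most-3' A wins the tie
    tt <- substrateOligo("N17-T", 18, "T")
    rt <- predictRegister(tpl, tt)
    ot <- oracle_register("CUAAACCCUAAACCC", c(0L, 15L), "T")
    expect_identical(rt$register, ot$p)
    expect_identical(rt$register, 11L)

    # random tails against random templates agree with the brute oracle
    set.seed(23)
    for (i in 1:40) {
        ts <- chartr("T", "U", rand_dna(sample(10:24, 1)))
        t2 <- suppressWarnings(templateRNA(ts))
        tail <- rand_dna(sample(1:3, 1))
        ol <- substrateOligo("probe", 18, tail)
        got <- predictRegister(t2, ol)
        want <- oracle_register(ts, c(0L, nchar(ts)), tail)
        if (want$k == 0L) {
            expect_false(got$annealed)
        } else {
            expect_identical(got$register, want$p)
            expect_identical(got$paired_length, want$k)
        }
    }
})

test_that("no pairing register yields a flagged no-anneal result, not an error", {
    # template of all A can pair only T tails
    t_a <- suppressWarnings(templateRNA("AAAAAAAAAA"))
    r <- predictRegister(t_a, ggg)
    expect_false(r$annealed)
    expect_true(is.na(r$register))
    expect_true(is.na(predictProductDifference(t_a, ggg, ggg)))
})

test_that("product differences live on the 0..period-1 scale", {
    expect_identical(predictProductDifference(tpl, ggg, ggg), 0L)
    set.seed(41)
    for (i in 1:60) {
        len <- sample(12:30, 1)
        tail <- rand_dna(sample(1:3, 1))
        ol <- substrateOligo("o", len, tail)
        d <- predictProductDifference(tpl, ol, ggg)
        if (!is.na(d)) {
            expect_gte(d, 0L)
            expect_lte(d, 6L)
            # one full repeat added to the oligo leaves the difference fixed
            ol7 <- substrateOligo("o7", len + 7L, tail)
            expect_identical(predictProductDifference(tpl, ol7, ggg), d)
        }
    }
})

test_that("an oligo suite of rotation suffixes matches the register oracle", {
    # template spanning ~1.5 repeats of the C-rich strand
    ts <- "CUAAACCCUAA"
    t2 <- suppressWarnings(templateRNA(ts))
    suffixes <- c("GGG", "GGT", "GTT", "TTT", "TTA", "TAG", "AGG")
    base <- substrateOligo("base", 18, "GGG")
    for (sfx in suffixes) {
        ol <- substrateOligo(paste0("N15-", sfx), 18, sfx)
        got <- predictProductDifference(t2, ol, base)
        o <- oracle_register(ts, c(0L, nchar(ts)), sfx)
        ob <- oracle_register(ts, c(0L, nchar(ts)), "GGG")
        want <- if (o$k == 0L) NA_integer_ else
            as.integer((o$p - ob$p) %% 7)
        expect_identical(got, want, info = sfx)
    }
})

test_that("quadrant scoring partitions the rung interval into seven bins", {
    expect_identical(assignQuadrant(10, 10, 24), 0L)
    expect_identical(assignQuadrant(17, 10, 24), 3L)  # midpoint
    expect_identical(assignQuadrant(10 + 0.99 * 14, 10, 24), 6L)
    expect_error(assignQuadrant(24, 10, 24), "outside")
    expect_error(assignQuadrant(5, 10, 24), "outside")
    expect_error(assignQuadrant(1, 3, 3), "below")
    # monotone, and each of the 7 bins is hit
    xs <- seq(0, 0.9999, length.out = 400)
    qs <- vapply(xs, assignQuadrant, integer(1), lower_rung = 0,
                 upper_rung = 1)
    expect_true(all(diff(qs) >= 0))
    expect_setequal(unique(qs), 0:6)
})

test_that("profiles validate the 0-6 scale and force the baseline to zero", {
    obs <- matrix(c(0, 0, 3, 5, 1, NA), 2, 3,
                  dimnames = list(c("A_thaliana", "B_rapa"),
                                  c("N15-GGG", "N15-TAG", "N15-GTT")))
    p <- buildProfile(obs, "N15-GGG")
    expect_s4_class(p, "UtilizationProfile")
    expect_true(all(profileMatrix(p)[, "N15-GGG"] == 0))
    expect_true(is.na(profileMatrix(p)["B_rapa", "N15-GTT"]))
    bad <- obs; bad[1, 2] <- 7
    expect_error(buildProfile(bad, "N15-GGG"), "0..6")
    expect_error(buildProfile(obs, "N15-XXX"), "baseline")
})

test_that("a species sharing every cell with the reference is at distance 0", {
    oligos <- paste0("o", 1:10)
    ref <- matrix(0L, 1, 10, dimnames = list("A_thaliana", oligos))
    same <- matrix(0L, 1, 10, dimnames = list("A_arabicum", oligos))
    expect_identical(profileDistance(ref, same), 0)
    one_off <- same; one_off[1, 4] <- 1L
    expect_equal(profileDistance(ref, one_off), 0.1)
    expect_equal(profileDistance(ref, one_off, method = "hamming"), 0.1)
})

test_that("profile distance is a metric on complete profiles", {
    set.seed(19)
    oligos <- paste0("o", 1:8)
    mk <- function() matrix(sample(0:6, 8, TRUE), 1, 8,
                            dimnames = list("s", oligos))
    for (i in 1:30) {
        a <- mk(); b <- mk(); cc <- mk()
        dab <- profileDistance(a, b)
        expect_gte(dab, 0)
        expect_equal(dab, profileDistance(b, a))           # symmetry
        expect_identical(profileDistance(a, a), 0)          # identity
        expect_lte(dab, profileDistance(a, cc) + profileDistance(cc, b) +
                       1e-12)                               # triangle
    }
    disjoint <- matrix(0L, 1, 2, dimnames = list("s", c("x1", "x2")))
    expect_error(profileDistance(mk(), disjoint), "share no oligos")
})

test_that("UPGMA trees are ultrametric and match an independent oracle", {
    d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
    t2 <- upgmaCluster(d2)
    expect_equal(unname(t2$edge.length), c(2, 2))

    # identical profiles merge first at height zero
    d3 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3,
                 dimnames = list(letters[1:3], letters[1:3]))
    t3 <- upgmaCluster(d3)
    coph <- ape::cophenetic.phylo(t3)
    expect_equal(coph["a", "b"], 0)

    set.seed(77)
    for (i in 1:8) {
        pts <- matrix(rnorm(5 * 3), 5)
        rownames(pts) <- paste0("sp", 1:5)
        d5 <- as.matrix(dist(pts))
        t5 <- upgmaCluster(d5)
        expect_same_upgma(t5, d5)
        # ultrametric: all leaves equidistant from the root
        depth <- ape::node.depth.edgelength(t5)[seq_len(5)]
        expect_lt(max(depth) - min(depth), 1e-9)
    }
    asym <- matrix(c(0, 1, 2, 0), 2,
                   dimnames = list(c("a", "b"), c("a", "b")))
    expect_error(upgmaCluster(asym), "symmetric")
})
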