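# Independent brute-force oracles used to cross-check the implementation.
# Everything here deliberately avoids the package's own code paths.

oracle_rc <- function(s) {
    if (!nzchar(s)) return(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1L]]),
          collapse = "")
}

oracle_windows <- function(unit, min_len, max_len, both = TRUE) {
    units <- if (both) c(unit, oracle_rc(unit)) else unit
    out <- character()
    for (u in units) {
        p <- nchar(u)
        tandem <- strrep(u, ceiling((max_len + p) / p))
        for (L in min_len:max_len) for (o in 0:(p - 1L))
            out <- c(out, substr(tandem, o + 1L, o + L))
    }
    unique(out)
}

# Naive substring scan + same-phase merge + containment collapse; mirrors the
# collapsed-match contract through an independent route (vectorized substring
# equality instead of per-position comparison against the infinite repeat).
oracle_scan <- function(seq, unit = "TTTAGGG", min_len = 9L, max_len = 19L,
                        both = TRUE) {
    seq <- toupper(seq)
    n <- nchar(seq)
    units <- if (both) c("+" = unit, "-" = oracle_rc(unit)) else
        c("+" = unit)
    res <- NULL
    for (st in names(units)) {
        u <- units[[st]]
        p <- nchar(u)
        tandem <- strrep(u, ceiling((max_len + p) / p))
        raw_start <- integer(); raw_len <- integer(); raw_phase <- integer()
        for (L in min_len:max_len) {
            if (n < L) next
            pos <- seq_len(n - L + 1L)
            frag <- substring(seq, pos, pos + L - 1L)
            for (o in 0:(p - 1L)) {
                w <- substr(tandem, o + 1L, o + L)
                hit <- which(frag == w) - 1L  # 0-based
                if (length(hit)) {
                    raw_start <- c(raw_start, hit)
                    raw_len <- c(raw_len, rep(L, length(hit)))
                    raw_phase <- c(raw_phase, (o - hit) %% p)
                }
            }
        }
        if (!length(raw_start)) next
        # merge overlapping/adjacent same-phase windows into runs
        runs <- NULL
        for (ph in unique(raw_phase)) {
            sel <- raw_phase == ph
            s <- raw_start[sel]; e <- s + raw_len[sel]
            o <- order(s)
            s <- s[o]; e <- e[o]
            cs <- s[1L]; ce <- e[1L]
            for (i in seq_along(s)[-1L]) {
                if (s[i] <= ce) ce <- max(ce, e[i])
                else { runs <- rbind(runs, c(cs, ce)); cs <- s[i]; ce <- e[i] }
            }
            runs <- rbind(runs, c(cs, ce))
        }
        runs <- unique(runs)
        keep <- vapply(seq_len(nrow(runs)), function(i) {
            !any(runs[, 1L] <= runs[i, 1L] & runs[, 2L] >= runs[i, 2L] &
                 (runs[, 2L] - runs[, 1L]) > (runs[i, 2L] - runs[i, 1L]))
        }, logical(1))
        runs <- runs[keep, , drop = FALSE]
        ln <- pmin(runs[, 2L] - runs[, 1L], max_len)
        res <- rbind(res, data.frame(
            start = runs[, 1L], length = as.integer(ln), strand = st,
            matched_seq = substring(seq, runs[, 1L] + 1L, runs[, 1L] + ln),
            stringsAsFactors = FALSE))
    }
    if (is.null(res))
        return(data.frame(start = integer(), length = integer(),
                          strand = character(), matched_seq = character(),
                          stringsAsFactors = FALSE))
    res <- res[order(res$start, res$strand), , drop = FALSE]
    rownames(res) <- NULL
    res
}

# random DNA sequence
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# chi-squared(1) upper tail by numerical integration of the density
oracle_chisq1_tail <- function(q) {
    if (q <= 0) return(1)
    stats::integrate(function(x) exp(-x / 2) / sqrt(2 * pi * x),
                     q, Inf, rel.tol = 1e-10)$value
}

# brute-force register enumeration for the substrate model
oracle_register <- function(template_seq, region, tail) {
    tpl <- strsplit(template_seq, "")[[1L]]
    partner <- c(A = "U", T = "A", G = "C", C = "G")
    t_rev <- rev(strsplit(tail, "")[[1L]])
    best <- list(k = 0L, p = NA_integer_)
    for (p in region[1L]:(region[2L] - 1L)) {
        k <- 0L
        for (j in seq_along(t_rev)) {
            pos <- p + j - 1L
            if (pos >= region[2L]) break
            if (tpl[pos + 1L] != partner[[t_rev[j]]]) break
            k <- j
        }
        if (k > best$k || (k == best$k && k > 0L)) best <- list(k = k, p = p)
    }
    best
}

# Simultaneous topology + height check for UPGMA: cophenetic distances of
# the returned phylo tree must equal the hclust(average) cophenetic matrix.
expect_same_upgma <- function(tree, d) {
    h <- stats::hclust(stats::as.dist(d), method = "average")
    ref <- as.matrix(stats::cophenetic(h))
    got <- ape::cophenetic.phylo(tree)
    expect_equal(got[rownames(ref), colnames(ref)], ref, tolerance = 1e-8)
}

# Shrunk test fixture: with only a few dozen background transcripts the
# library is so shallow that a single stray read would push the
# low-expression decoy's mean TPM over 1, so its count mean is set to zero
# here; the generator's full-scale default keeps the stochastic mean.
small_config <- function(seed = 1L, n_background = 60L, ...) {
    syntheticConfig(seed = seed, n_background = n_background,
                    low_expression_mean = 0, ...)
}
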