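#' @include AllGenerics.R
NULL

#' Telomerase RNA template for the substrate-register model
#'
#' Light-weight description of a TER template region: the RNA sequence
#' (5'->3') and the 0-based half-open interval of the template domain within
#' it. A warning is raised when the template region is far from the expected
#' ~1.5x repeat period, the canonical span that lets telomerase both anneal a
#' substrate and synthesize a full repeat.
#'
#' @param sequence RNA character scalar over ACGU (case-insensitive; T is
#'   accepted and converted to U).
#' @param region Integer length-2 vector: 0-based half-open template-domain
#'   interval. Default: the whole sequence.
#' @param period Telomere repeat period used for the span warning
#'   (default 7).
#' @return List of class `TemplateRNA` with `sequence` and `region`.
#' @export
templateRNA <- function(sequence, region = NULL, period = 7L) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    sequence <- chartr("Tt", "Uu", toupper(sequence))
    bad <- regexpr("[^ACGU]", sequence)
    if (bad != -1L)
        stop(sprintf("non-ACGU character '%s' in template RNA at position %d",
                     substr(sequence, bad, bad), bad), call. = FALSE)
    n <- nchar(sequence)
    if (is.null(region)) region <- c(0L, n)
    region <- as.integer(region)
    if (length(region) != 2L || region[1L] < 0L || region[2L] > n ||
        region[1L] >= region[2L])
        stop("template region must be a non-empty 0-based half-open interval within the sequence",
             call. = FALSE)
    span <- region[2L] - region[1L]
    if (abs(span - 1.5 * period) > period)
        warning(sprintf(
            "template region spans %d nt; ~%.1f nt (1.5x the %d-nt repeat) is typical",
            span, 1.5 * period, period), call. = FALSE)
    structure(list(sequence = sequence, region = region),
              class = "TemplateRNA")
}

#' Telomerase substrate oligo
#'
#' A TRAP substrate: its total length, and its 3'-terminal nucleotides able
#' to Watson-Crick pair with the TER template (1-3 nt in the assay design).
#'
#' @param name Identifier, e.g. `"N15-GGG"`.
#' @param length Total oligo length in nt.
#' @param three_prime_tail DNA string of telomere-pairing 3' nucleotides.
#' @param full_sequence Optional full oligo sequence; the tail must be its
#'   suffix.
#' @return List of class `SubstrateOligo`.
#' @export
substrateOligo <- function(name, length, three_prime_tail,
                           full_sequence = NULL) {
    three_prime_tail <- .checkDNA(three_prime_tail, "3' tail")
    length <- as.integer(length)
    stopifnot(is.character(name), length(name) == 1L, length >= 1L,
              nchar(three_prime_tail) >= 1L,
              nchar(three_prime_tail) <= length)
    if (!is.null(full_sequence)) {
        full_sequence <- .checkDNA(full_sequence, "full oligo sequence")
        if (nchar(full_sequence) != length)
            stop("full_sequence length disagrees with 'length'", call. = FALSE)
        if (!endsWith(full_sequence, three_prime_tail))
            stop("three_prime_tail must be a suffix of full_sequence",
                 call. = FALSE)
    }
    structure(list(name = name, length = length,
                   three_prime_tail = three_prime_tail,
                   full_sequence = full_sequence),
              class = "SubstrateOligo")
}

## DNA base -> RNA Watson-Crick partner
.WC_RNA <- c(A = "U", T = "A", G = "C", C = "G")

#' Predict the annealing register of a substrate on a TER template
#'
#' Models Watson-Crick base-pairing between the 3' end of the DNA substrate
#' and the template domain. At a register, the oligo's 3'-terminal nucleotide
#' pairs with template position `p` and successive upstream oligo nucleotides
#' pair with successive downstream (3'-ward) template positions. Among all
#' registers within the template region with at least one contiguous
#' 3'-terminal pair, the register with the longest contiguous pairing wins;
#' ties go to the register closest to the template region's 3' end (largest
#' `p`). Extension then runs to the template region's 5' boundary, so the
#' number of nucleotides added is `p - region_start`.
#'
#' @param template A [templateRNA()].
#' @param oligo A [substrateOligo()].
#' @return List with `annealed` (logical), `register` (0-based template
#'   index paired with the oligo 3' terminus), `paired_length` and
#'   `nucleotides_added` (all `NA` when no register pairs).
#' @export
predictRegister <- function(template, oligo) {
    stopifnot(inherits(template, "TemplateRNA"),
              inherits(oligo, "SubstrateOligo"))
    tpl <- strsplit(template$sequence, "", fixed = TRUE)[[1L]]
    r0 <- template$region[1L]
    r1 <- template$region[2L]  # half-open end
    tail <- rev(strsplit(oligo$three_prime_tail, "", fixed = TRUE)[[1L]])
    m <- length(tail)
    best_p <- NA_integer_
    best_k <- 0L
    for (p in r0:(r1 - 1L)) {
        k <- 0L
        while (k < m && p + k < r1 &&
               tpl[p + k + 1L] == .WC_RNA[[tail[k + 1L]]]) {
            k <- k + 1L
        }
        if (k > best_k || (k == best_k && k > 0L)) {  # ties -> largest p
            best_k <- k
            best_p <- p
        }
    }
    if (best_k == 0L)
        return(list(annealed = FALSE, register = NA_integer_,
                    paired_length = NA_integer_,
                    nucleotides_added = NA_integer_))
    list(annealed = TRUE, register = best_p, paired_length = best_k,
         nucleotides_added = best_p - r0)
}

#' Predicted product-length difference between two substrates
#'
#' Telomerase products seeded by different substrates differ in length by
#' the difference in (oligo length + nucleotides added before the template
#' 5' boundary), reduced modulo the repeat period: products one full repeat
#' apart land on the same rung of the product ladder. For the 7-nt plant
#' repeat the result is the 0-6 scale of observed product differences.
#'
#' @param template A [templateRNA()].
#' @param oligo,baseline [substrateOligo()] objects; the baseline is the
#'   reference substrate (e.g. N15-GGG).
#' @param period Repeat period (default 7).
#' @return Integer in `[0, period)`, or `NA` when either substrate fails to
#'   anneal.
#' @export
predictProductDifference <- function(template, oligo, baseline, period = 7L) {
    period <- as.integer(period)
    stopifnot(period >= 1L)
    ro <- predictRegister(template, oligo)
    rb <- predictRegister(template, baseline)
    if (!ro$annealed || !rb$annealed) return(NA_integer_)
    as.integer(((oligo$length + ro$nucleotides_added) -
                (baseline$length + rb$nucleotides_added)) %% period)
}

#' Score a gel band position into a product-difference quadrant
#'
#' The space between two consecutive baseline-oligo bands on the sequencing
#' gel is divided into seven quadrants; the quadrant in which a band migrates
#' is its observed product difference. Band positions are abstract migration
#' coordinates, monotone in product size.
#'
#' @param band_position Band migration coordinate.
#' @param lower_rung,upper_rung Coordinates of the flanking baseline bands
#'   (`lower_rung < upper_rung`); the band must lie in
#'   `[lower_rung, upper_rung)`.
#' @param n_quadrants Number of quadrants (default 7).
#' @return Integer in `[0, n_quadrants - 1]`.
#' @examples
#' assignQuadrant(0.5, 0, 1)  # 3
#' @export
assignQuadrant <- function(band_position, lower_rung, upper_rung,
                           n_quadrants = 7L) {
    stopifnot(is.finite(band_position), is.finite(lower_rung),
              is.finite(upper_rung))
    if (lower_rung >= upper_rung)
        stop("lower_rung must be below upper_rung", call. = FALSE)
    if (band_position < lower_rung || band_position >= upper_rung)
        stop(sprintf("band position %g outside rung interval [%g, %g)",
                     band_position, lower_rung, upper_rung), call. = FALSE)
    q <- floor(n_quadrants * (band_position - lower_rung) /
               (upper_rung - lower_rung))
    as.integer(min(max(q, 0), n_quadrants - 1L))
}

#' Build a substrate utilization profile
#'
#' Validates a species-by-oligo matrix of observed product differences
#' (integers 0-6, `NA` for missing observations) and forces the baseline
#' column to zero (every product is measured relative to the baseline
#' substrate, so its own difference is zero by construction).
#'
#' @param observations Numeric matrix, rows = species, columns = oligos.
#' @param baseline Column name of the baseline oligo.
#' @return A [UtilizationProfile-class].
#' @export
buildProfile <- function(observations, baseline) {
    observations <- as.matrix(observations)
    if (!baseline %in% colnames(observations))
        stop("baseline oligo '", baseline, "' not among profile columns",
             call. = FALSE)
    observations[, baseline] <- 0
    storage.mode(observations) <- "integer"
    new("UtilizationProfile", values = observations, baseline = baseline)
}

#' @rdname profileMatrix
#' @export
setMethod("profileMatrix", "UtilizationProfile", function(x) x@values)

#' Accessors for utilization profiles
#'
#' @param x A [UtilizationProfile-class].
#' @return `profileMatrix()`: the species-by-oligo integer matrix;
#'   `baselineOligo()`: the baseline column name.
#' @name profileMatrix
#' @aliases baselineOligo
NULL

#' @rdname profileMatrix
#' @export
setMethod("baselineOligo", "UtilizationProfile", function(x) x@baseline)

setMethod("show", "UtilizationProfile", function(object) {
    v <- object@values
    cat(sprintf("UtilizationProfile: %d species x %d oligos (baseline %s)\n",
                nrow(v), ncol(v), object@baseline))
    print(v)
})

#' Distance between substrate utilization profiles
#'
#' Mean absolute difference of product-difference values over oligos shared
#' by both profiles, skipping cells missing in either (default), or the
#' Hamming fraction of differing cells (`method = "hamming"`, treating the
#' 0-6 shading as categorical).
#'
#' @param a,b [UtilizationProfile-class] objects (or single-species profile
#'   rows as named vectors).
#' @param method `"mean_abs"` (default) or `"hamming"`.
#' @return Non-negative numeric distance. For complete profiles over the same
#'   species and oligos both methods are metrics.
#' @export
profileDistance <- function(a, b, method = c("mean_abs", "hamming")) {
    method <- match.arg(method)
    va <- if (is(a, "UtilizationProfile")) a@values else rbind(a)
    vb <- if (is(b, "UtilizationProfile")) b@values else rbind(b)
    shared <- intersect(colnames(va), colnames(vb))
    if (!length(shared))
        stop("profiles share no oligos", call. = FALSE)
    if (!identical(nrow(va), nrow(vb)))
        stop("profiles have different species counts", call. = FALSE)
    da <- va[, shared, drop = FALSE]
    db <- vb[, shared, drop = FALSE]
    ok <- !is.na(da) & !is.na(db)
    if (!any(ok)) stop("no shared non-missing cells", call. = FALSE)
    if (method == "mean_abs") mean(abs(da[ok] - db[ok]))
    else mean(da[ok] != db[ok])
}

#' Pairwise distances between the species of one profile
#'
#' Symmetric species-by-species distance matrix (see [profileDistance()]),
#' suitable for [upgmaCluster()].
#'
#' @param profile A [UtilizationProfile-class].
#' @param method Passed to [profileDistance()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
speciesDistances <- function(profile, method = "mean_abs") {
    v <- profileMatrix(profile)
    n <- nrow(v)
    d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j > i) {
            d[i, j] <- profileDistance(v[i, , drop = FALSE],
                                       v[j, , drop = FALSE],
                                       method = method)
            d[j, i] <- d[i, j]
        }
    }
    d
}
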