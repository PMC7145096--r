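#' @include AllClasses.R
NULL

#' UPGMA clustering of a species distance matrix
#'
#' Standard unweighted pair group method with arithmetic mean: repeatedly
#' merges the closest pair of clusters at height d/2 and averages distances
#' weighted by cluster sizes, producing a rooted ultrametric tree. Tie-breaks
#' are deterministic: among equally close pairs, the pair whose
#' lexicographically smallest member labels sort first is merged.
#'
#' @param d Symmetric numeric matrix with zero diagonal and labelled rows
#'   (or a [stats::dist]).
#' @return An [ape::phylo] rooted ultrametric tree with branch lengths.
#' @examples
#' d <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' upgmaCluster(d)  # both leaves at height 2
#' @export
upgmaCluster <- function(d) {
    if (inherits(d, "dist")) d <- as.matrix(d)
    stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2L)
    if (is.null(rownames(d)))
        rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)) ||
        any(diag(d) != 0))
        stop("distance matrix must be symmetric with zero diagonal",
             call. = FALSE)
    labels <- rownames(d)
    n <- length(labels)
    clusters <- lapply(seq_len(n), function(i) list(
        members = labels[i], height = 0, size = 1L, newick = labels[i],
        rep = labels[i]))
    D <- d
    while (length(clusters) > 1L) {
        k <- length(clusters)
        # find minimum off-diagonal distance, tie-break by representative
        # (lexicographically smallest member) labels of the ordered pair
        best <- NULL
        for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
            pair_rep <- sort(c(clusters[[i]]$rep, clusters[[j]]$rep))
            if (is.null(best) ||
                D[i, j] < best$dist - 1e-15 ||
                (abs(D[i, j] - best$dist) <= 1e-15 &&
                 (pair_rep[1L] < best$rep[1L] ||
                  (pair_rep[1L] == best$rep[1L] &&
                   pair_rep[2L] < best$rep[2L])))) {
                best <- list(i = i, j = j, dist = D[i, j], rep = pair_rep)
            }
        }
        i <- best$i; j <- best$j
        ci <- clusters[[i]]; cj <- clusters[[j]]
        h <- best$dist / 2
        merged <- list(
            members = c(ci$members, cj$members),
            height = h,
            size = ci$size + cj$size,
            newick = sprintf("(%s:%.10g,%s:%.10g)",
                             ci$newick, h - ci$height,
                             cj$newick, h - cj$height),
            rep = min(ci$rep, cj$rep))
        # weighted average of distances to the remaining clusters
        rest <- setdiff(seq_len(k), c(i, j))
        newD <- matrix(0, k - 1L, k - 1L)
        if (length(rest)) {
            newD[seq_along(rest), seq_along(rest)] <-
                D[rest, rest, drop = FALSE]
            dnew <- (ci$size * D[i, rest] + cj$size * D[j, rest]) /
                (ci$size + cj$size)
            newD[k - 1L, seq_along(rest)] <- dnew
            newD[seq_along(rest), k - 1L] <- dnew
        }
        clusters <- c(clusters[rest], list(merged))
        D <- newD
    }
    ape::read.tree(text = paste0(clusters[[1L]]$newick, ";"))
}

#' Write a tree in Newick format
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @export
writeTreeNewick <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}
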