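# p-distance matrices and Neighbor-Joining trees over haplotype sets.
#
# The NJ agglomeration (Q-criterion with the Studier-Keppler update) is
# implemented here directly rather than wrapped, since the haplotype tree is
# part of the analysis being provided; ape is used for tree representation
# and, in the test suite, as an independent cross-check.

#' Pairwise p-distance matrix over jointly aligned sequences
#'
#' p-distance = mismatches / compared columns, with pairwise deletion of
#' columns where either sequence has a gap (`-`) or an ambiguity (any
#' non-A/C/G/T letter).
#'
#' @param aligned Named character vector of equal-length gapped sequences
#'   (e.g. from [align_haplotypes()]).
#' @return A symmetric numeric matrix with zero diagonal, entries in
#'   \[0, 1\], dimnames from `names(aligned)`.
#' @export
pdistance_matrix <- function(aligned) {
  stopifnot(length(aligned) >= 2L, !is.null(names(aligned)))
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not jointly aligned (unequal lengths)", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(aligned), ""))
  ok <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  n <- length(aligned)
  d <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      ncomp <- sum(comp)
      if (ncomp == 0L) {
        stop("no comparable columns between '", names(aligned)[i], "' and '",
             names(aligned)[j], "'", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(mat[i, comp] != mat[j, comp]) / ncomp
    }
  }
  d
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Canonical NJ: at each step the pair minimizing the Q-criterion
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined, with limb lengths
#' `l_i = d(i,j)/2 + (r_i - r_j)/(2(n-2))` and the Studier-Keppler distance
#' update. Ties are broken by the lowest pair of node indices (original
#' input order, internal nodes numbered after the tips), which makes the
#' output deterministic. The last three nodes are joined to a central node
#' by the three-point closed form, giving the usual unrooted representation.
#'
#' @param d Symmetric distance matrix with dimnames (>= 3 taxa).
#' @param clamp_negative If `TRUE`, negative branch lengths are clamped to
#'   zero; by default they are reported as computed.
#' @return An object of class `haplotype_tree`: `newick` (lengths printed
#'   with 6 decimals), `phylo` (an [ape::read.tree()] object) and `labels`.
#' @export
nj_tree <- function(d, clamp_negative = FALSE) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n0 <- nrow(d)
  if (n0 < 3L) stop("Neighbor-Joining requires at least 3 taxa", call. = FALSE)
  if (is.null(dimnames(d))) {
    dimnames(d) <- list(paste0("t", seq_len(n0)), paste0("t", seq_len(n0)))
  }
  if (max(abs(d - t(d))) > 1e-9 || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  labels <- rownames(d)
  clamp <- function(x) if (clamp_negative) max(x, 0) else x
  len <- function(x) sprintf("%.6f", clamp(x))       # serialized Newick
  lenf <- function(x) sprintf("%.17g", clamp(x))     # full-precision internal
  # active nodes: newick fragment + original index order for tie-breaks
  frag <- as.list(labels)
  fragf <- as.list(labels)
  ord <- seq_len(n0)
  nextidx <- n0 + 1L
  D <- d
  while (length(frag) > 3L) {
    n <- length(frag)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    # candidate pairs at the minimum; pick lowest (ord_i, ord_j), i < j
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- order(pmin(ord[cand[, 1]], ord[cand[, 2]]),
                 pmax(ord[cand[, 1]], ord[cand[, 2]]))
    i <- cand[key[1], 1]; j <- cand[key[1], 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    newfrag <- paste0("(", frag[[i]], ":", len(li), ",",
                      frag[[j]], ":", len(lj), ")")
    newfragf <- paste0("(", fragf[[i]], ":", lenf(li), ",",
                       fragf[[j]], ":", lenf(lj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    fragf <- c(fragf[keep], newfragf)
    ord <- c(ord[keep], nextidx)
    nextidx <- nextidx + 1L
  }
  # three-point closed form for the final unrooted join
  a <- D[1, 2]; b <- D[1, 3]; cc <- D[2, 3]
  l1 <- (a + b - cc) / 2
  l2 <- (a + cc - b) / 2
  l3 <- (b + cc - a) / 2
  newick <- paste0("(", frag[[1]], ":", len(l1), ",",
                   frag[[2]], ":", len(l2), ",",
                   frag[[3]], ":", len(l3), ");")
  newickf <- paste0("(", fragf[[1]], ":", lenf(l1), ",",
                    fragf[[2]], ":", lenf(l2), ",",
                    fragf[[3]], ":", lenf(l3), ");")
  phylo <- ape::read.tree(text = newickf)
  structure(list(newick = newick, phylo = phylo, labels = labels),
            class = "haplotype_tree")
}

#' @export
print.haplotype_tree <- function(x, ...) {
  cat("Neighbor-Joining tree, ", length(x$labels), " tips\n", sep = "")
  cat(x$newick, "\n")
  invisible(x)
}

#' @export
plot.haplotype_tree <- function(x, ...) {
  ape::plot.phylo(x$phylo, type = "unrooted", ...)
}

#' Write a tree in Newick format
#'
#' @param tree A `haplotype_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}
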