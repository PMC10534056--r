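new_sfs_table <- function(counts, n) {
  M_in <- if (n >= 3L) sum(counts[2:(n - 1L)]) else 0L
  structure(list(n = as.integer(n), counts = counts, M_in = M_in),
            class = "sfs_table")
}

#' @export
print.sfs_table <- function(x, ...) {
  cat("site frequency spectrum: n =", x$n, "cells,",
      sum(x$counts), "mutations, M_in =", x$M_in, "\n")
  invisible(x)
}

#' @export
as.data.frame.sfs_table <- function(x, ...) {
  data.frame(k = seq_len(x$n), count = as.integer(x$counts))
}

#' Site frequency spectrum from a binary genotype matrix
#'
#' Computes `M_n^k`, the number of variants carried by exactly k of the n
#' sampled cells, for k = 1..n, and the shared-mutation count
#' `M_in = sum over k = 2..n-1` (excluding private and clonal variants).
#'
#' @param gm binary matrix, rows = cells, columns = variants. Entries must
#'   be 0/1 and no variant column may be all-zero.
#' @return an `"sfs_table"`: list with `n`, `counts` (length n, indexed by
#'   k) and `M_in`.
#' @export
sfs_from_genotypes <- function(gm) {
  gm <- as.matrix(gm)
  if (!all(gm %in% c(0, 1))) stop_data("genotype matrix must be binary 0/1")
  n <- nrow(gm)
  if (n < 2L) stop_data("need at least 2 cells")
  if (ncol(gm) > 0L) {
    ks <- colSums(gm)
    if (any(ks == 0)) stop_data("all-zero variant column(s)")
    counts <- tabulate(ks, nbins = n)
  } else {
    counts <- integer(n)
  }
  new_sfs_table(counts, n)
}

# number of tips below the child node of each edge
tips_per_edge <- function(tree) {
  n <- n_tips(tree)
  nnode <- tree$Nnode
  cnt <- c(rep(1L, n), integer(nnode))
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    cnt[ord$edge[e, 1L]] <- cnt[ord$edge[e, 1L]] + cnt[ord$edge[e, 2L]]
  }
  cnt[tree$edge[, 2L]]
}

# tip index sets below the child node of each edge (small trees)
tipsets_per_edge <- function(tree) {
  n <- n_tips(tree)
  sets <- c(as.list(seq_len(n)), vector("list", tree$Nnode))
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(tree$edge[, 2L], function(ch) sets[[ch]])
}

#' Site frequency spectrum from a mutation-annotated tree
#'
#' Each edge subtending k tips contributes its mutation count to `M_n^k`;
#' pendant edges contribute to k = 1 and the shared count `M_in` is the
#' total number of mutations on internal edges, which ties the
#' shared-mutation estimator to the internal branch length
#' (E[M_in] = nu E[L_in] = n nu / r).
#'
#' @param tree a `"phylo"` tree with a `mutations` field (see
#'   [overlay_mutations()]).
#' @return an `"sfs_table"`.
#' @export
sfs_from_tree <- function(tree) {
  tree <- validate_tree(tree)
  if (is.null(tree$mutations)) {
    stop_data("tree has no per-edge mutation counts; see overlay_mutations()")
  }
  n <- n_tips(tree)
  k <- tips_per_edge(tree)
  counts <- integer(n)
  for (e in seq_along(k)) counts[k[e]] <- counts[k[e]] + tree$mutations[e]
  new_sfs_table(counts, n)
}

#' Binary genotype matrix implied by a mutation-annotated tree
#'
#' Propagates each edge's mutations to all tips below that edge, yielding
#' the cell-by-variant presence/absence matrix a perfect variant caller
#' would recover. Mainly used to cross-check [sfs_from_tree()] against
#' [sfs_from_genotypes()].
#'
#' @param tree a `"phylo"` tree with a `mutations` field.
#' @return binary matrix, rows = cells (named by tip label), columns =
#'   variants.
#' @export
genotypes_from_tree <- function(tree) {
  tree <- validate_tree(tree)
  if (is.null(tree$mutations)) {
    stop_data("tree has no per-edge mutation counts; see overlay_mutations()")
  }
  n <- n_tips(tree)
  sets <- tipsets_per_edge(tree)
  total <- sum(tree$mutations)
  gm <- matrix(0L, nrow = n, ncol = total,
               dimnames = list(tree$tip.label, NULL))
  col <- 0L
  for (e in seq_along(sets)) {
    m <- tree$mutations[e]
    if (m > 0L) {
      gm[sets[[e]], col + seq_len(m)] <- 1L
      col <- col + m
    }
  }
  gm
}

#' Expected site frequency spectrum under neutral exponential growth
#'
#' For a neutrally expanding birth-death clone, as the clone age grows the
#' expected number of mutations shared by exactly k of the n sampled cells
#' approaches
#' \deqn{E[M_n^k] = \frac{n\nu}{r}\cdot\frac{1}{k(k-1)}, \quad k \ge 2.}
#' Summed over k >= 2 the expectation telescopes to `n nu / r`, the
#' expected shared-mutation total.
#'
#' @param n sample size.
#' @param nu mutation rate per unit time.
#' @param r net growth rate.
#' @param k number of carrier cells (vectorised; all entries >= 2).
#' @return expected mutation counts, same length as `k`.
#' @export
expected_sfs <- function(n, nu, r, k) {
  if (any(k < 2)) stop_data("the neutral expectation is stated for k >= 2")
  (n * nu / r) / (k * (k - 1))
}

#' Averaged-SFS neutrality check across clones
#'
#' Clones differ in sample size and mutation burden, so each clone's
#' spectrum is first normalised by its own shared-mutation total `M_in`;
#' the per-clone expected curve is normalised the same way,
#' `[1/(k(k-1))] / [sum_{j=2}^{n-1} 1/(j(j-1))]`, and k is truncated to the
#' largest range common to all clones (2..min(n)-1). Each clone gets equal
#' weight in the average. The report gives, per k, the mean normalised
#' observed frequency with a t-based confidence interval of the mean, the
#' mean expected frequency, and whether the expectation lies inside the
#' interval.
#'
#' @param sfs_list a list of at least 2 `"sfs_table"` objects, each with
#'   `M_in >= 1`.
#' @param conf confidence level for the interval of the mean (default 0.95).
#' @return a data.frame with columns `k`, `mean_obs`, `ci_low`, `ci_high`,
#'   `expected`, `within`; the number of clones used is in
#'   `attr(, "n_clones")`.
#' @export
neutrality_check <- function(sfs_list, conf = 0.95) {
  stopifnot(is.list(sfs_list))
  if (length(sfs_list) < 2L) {
    stop_data("need at least 2 clones for a confidence interval of the mean")
  }
  ok <- vapply(sfs_list, function(s) inherits(s, "sfs_table"), logical(1))
  if (!all(ok)) stop_data("all elements must be sfs_table objects")
  m_in <- vapply(sfs_list, function(s) as.numeric(s$M_in), numeric(1))
  if (any(m_in < 1)) stop_data("every clone needs M_in >= 1")
  n_min <- min(vapply(sfs_list, function(s) s$n, integer(1)))
  if (n_min < 4L) stop_data("smallest clone must have n >= 4 cells")
  ks <- 2:(n_min - 1L)
  obs <- sapply(sfs_list, function(s) s$counts[ks] / s$M_in)
  expd <- sapply(sfs_list, function(s) {
    norm <- sum(1 / (2:(s$n - 1L) * (2:(s$n - 1L) - 1L)))
    (1 / (ks * (ks - 1))) / norm
  })
  obs <- matrix(obs, nrow = length(ks))
  expd <- matrix(expd, nrow = length(ks))
  C <- length(sfs_list)
  mean_obs <- rowMeans(obs)
  se <- apply(obs, 1L, stats::sd) / sqrt(C)
  tq <- stats::qt(1 - (1 - conf) / 2, df = C - 1L)
  out <- data.frame(k = ks, mean_obs = mean_obs,
                    ci_low = mean_obs - tq * se,
                    ci_high = mean_obs + tq * se,
                    expected = rowMeans(expd))
  eps <- 1e-9 * pmax(abs(out$expected), abs(out$mean_obs))  # float guard
  out$within <- out$expected >= out$ci_low - eps &
    out$expected <= out$ci_high + eps
  attr(out, "n_clones") <- C
  out
}

#' Read and write simple SFS / genotype text formats
#'
#' `read_genotypes()` reads a delimited 0/1 cell-by-variant table (cells in
#' rows, header optional); `write_sfs()` writes an SFS as a two-column
#' (k, count) tab-separated file.
#'
#' @param path file path.
#' @param sep field separator.
#' @param header whether the genotype file has a header row.
#' @return `read_genotypes()` returns a binary matrix.
#' @export
read_genotypes <- function(path, sep = "\t", header = FALSE) {
  gm <- as.matrix(utils::read.table(path, sep = sep, header = header,
                                    row.names = NULL))
  storage.mode(gm) <- "integer"
  gm
}

#' @rdname read_genotypes
#' @param sfs an `"sfs_table"`.
#' @export
write_sfs <- function(sfs, path) {
  stopifnot(inherits(sfs, "sfs_table"))
  utils::write.table(as.data.frame(sfs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
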