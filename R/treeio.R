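#' Read an ultrametric time tree from a Newick string
#'
#' Parses a rooted binary tree with branch lengths in time units. Parsing is
#' strict: every non-root edge must carry a branch length and every internal
#' node must be binary (the birth-death model underlying the estimators is
#' binary). Ultrametricity is deliberately *not* enforced here; use
#' [check_ultrametric()] for that, so that malformed user trees can still be
#' inspected.
#'
#' @param text a Newick string (or a file path if `file = TRUE`).
#' @param resolve_polytomies if `TRUE`, multifurcations are resolved
#'   deterministically (left-to-right, inserting zero-length edges) via
#'   [ape::multi2di()]; if `FALSE` (default) a polytomy is an error.
#' @param file treat `text` as a file path containing one or more trees.
#' @return an [ape::read.tree()] `"phylo"` object (or a list of them when
#'   `file = TRUE` and the file holds several trees).
#' @seealso [write_newick()], [check_ultrametric()]
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):2,(C:2.5,D:2.5):0.5);")
#' coalescence_depths(tr)$depths
read_newick <- function(text, resolve_polytomies = FALSE, file = FALSE) {
  tr <- tryCatch(
    if (file) ape::read.tree(text) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr)) stop_data("Newick parse failure")
  if (inherits(tr, "multiPhylo")) {
    return(lapply(tr, function(t) validate_tree(t, resolve_polytomies)))
  }
  validate_tree(tr, resolve_polytomies)
}

validate_tree <- function(tr, resolve_polytomies = FALSE) {
  if (!is_phylo(tr)) stop_data("not a phylo object")
  n <- length(tr$tip.label)
  if (n < 2L) stop_data("tree must have at least 2 tips")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop_data("missing branch length(s): every non-root edge needs a length")
  }
  if (any(tr$edge.length < 0)) stop_data("negative branch length(s)")
  kids <- tabulate(tr$edge[, 1L], nbins = n + tr$Nnode)
  if (any(kids[kids > 0L] > 2L)) {
    if (!resolve_polytomies) {
      stop_data("tree contains polytomies; set resolve_polytomies = TRUE ",
                "to insert zero-length edges deterministically")
    }
    tr <- ape::multi2di(tr, random = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) stop_data("duplicate tip labels")
  tr
}

#' Write a tree to a Newick string
#'
#' @param tree a `"phylo"` object.
#' @param digits number of significant digits for branch lengths.
#' @return a Newick string. Zero-length edges are emitted as `":0"`, not
#'   dropped, so round trips preserve the edge-length multiset.
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(is_phylo(tree))
  ape::write.tree(tree, digits = digits)
}

#' Check that a tree is ultrametric
#'
#' A tree is ultrametric when all root-to-tip path lengths agree, which is
#' expected for trees whose tips are cells sampled at a single timepoint.
#' The test is relative: it passes iff
#' `max(depth) - min(depth) <= tol * max(depth)`, so it is invariant under
#' rescaling of all branch lengths.
#'
#' @param tree a `"phylo"` object.
#' @param tol relative tolerance (default `1e-6`, intended to absorb float
#'   noise in trees made ultrametric upstream).
#' @return an object of class `"ultrametric_check"`: a list with elements
#'   `pass`, `tip_depths` (named per-tip root-to-tip lengths), `max_depth`,
#'   `min_depth` and `tol`.
#' @export
check_ultrametric <- function(tree, tol = 1e-6) {
  tree <- validate_tree(tree)
  n <- n_tips(tree)
  depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
  names(depths) <- tree$tip.label
  mx <- max(depths)
  mn <- min(depths)
  structure(
    list(pass = (mx - mn) <= tol * mx, tip_depths = depths,
         max_depth = mx, min_depth = mn, tol = tol),
    class = "ultrametric_check"
  )
}

#' @export
print.ultrametric_check <- function(x, ...) {
  cat("ultrametric:", if (x$pass) "pass" else "FAIL", "\n")
  cat("max_depth:", format(x$max_depth, digits = 10), "\n")
  cat("min_depth:", format(x$min_depth, digits = 10), "\n")
  cat("relative_tol:", x$tol, "\n")
  cat("n_tips:", length(x$tip_depths), "\n")
  invisible(x)
}

#' Coalescence times of an ultrametric tree
#'
#' Collects the n-1 internal-node depths H_1, ..., H_(n-1), measured
#' *backward* from the tip level (the present). The calendar time of a
#' coalescence is `T - H_i`. The deepest depth is the root (most recent
#' common ancestor of the sample).
#'
#' @param tree an ultrametric `"phylo"` object.
#' @param T clone age at sampling, if known externally. Defaults to the
#'   root depth (i.e. the tree is assumed to span exactly the observed
#'   history); supplying the true clone age only matters for stem handling
#'   and diagnostics, never for the estimators.
#' @param tol relative ultrametricity tolerance passed to
#'   [check_ultrametric()].
#' @return a [coal_times()] object.
#' @export
coalescence_depths <- function(tree, T = NULL, tol = 1e-6) {
  chk <- check_ultrametric(tree, tol = tol)
  if (!chk$pass) {
    stop_data("tree is not ultrametric (relative spread ",
              format((chk$max_depth - chk$min_depth) / chk$max_depth),
              "); inspect with check_ultrametric()")
  }
  n <- n_tips(tree)
  nh <- ape::node.depth.edgelength(tree)
  tip_level <- mean(nh[seq_len(n)])
  depths <- tip_level - nh[(n + 1L):(n + tree$Nnode)]
  depths <- pmax(depths, 0)
  coal_times(depths, T = T, n = n)
}

#' Container for coalescence times
#'
#' Holds the n-1 node depths of an n-tip ultrametric tree, measured backward
#' from the tip level, plus the (possibly unknown) clone age `T` at sampling.
#'
#' @param depths numeric vector of n-1 depths. Depths produced by
#'   [coalescence_depths()] are positive and at most `T`; the unconditional
#'   asymptotic sampler ([sample_coal_times_approx()]) can produce values
#'   outside (0, T), which are tolerated here and flagged downstream.
#' @param T clone age at sampling (time units) or `NULL` if unknown.
#' @param n number of tips; defaults to `length(depths) + 1`.
#' @return an object of class `"coal_times"`.
#' @export
coal_times <- function(depths, T = NULL, n = length(depths) + 1L) {
  stopifnot(is.numeric(depths), length(depths) >= 1L, !anyNA(depths))
  if (n != length(depths) + 1L) {
    stop_data("n must equal length(depths) + 1")
  }
  if (is.null(T)) T <- NA_real_
  stopifnot(length(T) == 1L)
  structure(list(depths = as.numeric(depths), T = as.numeric(T),
                 n = as.integer(n)),
            class = "coal_times")
}

#' @export
print.coal_times <- function(x, ...) {
  cat("coalescence times: n =", x$n, "tips,", length(x$depths), "depths\n")
  cat("T:", if (is.na(x$T)) "unknown" else format(x$T), "\n")
  cat("depth range: [", format(min(x$depths)), ",", format(max(x$depths)),
      "]\n")
  invisible(x)
}

as_coal_times <- function(x, tol = 1e-6) {
  if (inherits(x, "coal_times")) return(x)
  if (is_phylo(x)) return(coalescence_depths(x, tol = tol))
  stop_data("expected a coal_times object or a phylo tree")
}

#' Internal and external branch-length totals
#'
#' External (pendant) edges are those ending in a tip; everything else below
#' the most recent common ancestor is internal. Any stem edge above the MRCA
#' (`root.edge`) is excluded. The external/internal ratio is the star-shape
#' diagnostic used by [diagnose()]: values >= 3 indicate the regime in which
#' the analytical estimators and their confidence intervals are reliable.
#'
#' @param tree a `"phylo"` object.
#' @return an object of class `"branch_lengths"`: list with `internal_total`,
#'   `external_total`, `ratio` (`Inf` when there are no internal edges) and
#'   `total`.
#' @export
branch_length_totals <- function(tree) {
  tree <- validate_tree(tree)
  n <- n_tips(tree)
  pendant <- tree$edge[, 2L] <= n
  ext <- sum(tree$edge.length[pendant])
  int <- sum(tree$edge.length[!pendant])
  structure(
    list(internal_total = int, external_total = ext,
         ratio = if (int > 0) ext / int else Inf,
         total = int + ext),
    class = "branch_lengths"
  )
}

#' @export
print.branch_lengths <- function(x, ...) {
  cat("internal_total:", format(x$internal_total), "\n")
  cat("external_total:", format(x$external_total), "\n")
  cat("ratio_ext_int:", format(x$ratio), "\n")
  invisible(x)
}

#' Extract the induced subtree on a subset of tips
#'
#' Returns the clade spanned by `tips`, suppressing unary nodes by summing
#' edge lengths; the stem above the new MRCA is dropped. Intended for manual
#' clone annotation, e.g. isolating one clonal expansion from a larger tree
#' or removing nested subclones before estimation.
#'
#' @param tree a `"phylo"` object.
#' @param tips character vector of tip labels (at least 2).
#' @return a `"phylo"` object on `tips`.
#' @export
extract_clade <- function(tree, tips) {
  tree <- validate_tree(tree)
  if (length(tips) < 2L) stop_data("need at least 2 tips")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) {
    stop_data("unknown tip label(s): ", paste(unknown, collapse = ", "))
  }
  sub <- ape::keep.tip(tree, tips)
  sub$root.edge <- NULL
  sub
}
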