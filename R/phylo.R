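#' Neighbor-joining tree from a distance matrix
#'
#' Wraps `ape::nj()`. Negative branch lengths (a known NJ artifact) are
#' clamped to zero and the deficit is transferred to the adjacent branch
#' (the parent-side edge of the same node), a common display convention.
#'
#' @param d Symmetric numeric matrix with zero diagonal (or `dist`), at
#'   least three taxa, no `NA`/`NaN`.
#' @return Unrooted `ape::phylo`.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("d must be square")
  if (nrow(d) < 3) abort("need at least 3 taxa")
  if (any(!is.finite(d))) abort("distance matrix contains NA/NaN/Inf")
  if (any(abs(d - t(d)) > 1e-8)) abort("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) abort("distance matrix diagonal must be zero")
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tr)
}

clamp_negative_edges <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]          # negative
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    adj <- which(tr$edge[, 2] == parent)  # parent-side edge, if any
    if (length(adj) == 1)
      tr$edge.length[adj] <- tr$edge.length[adj] + deficit
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `reps` times; the percentage of replicate trees containing
#' each internal edge's bipartition is attached as the node label.
#'
#' @param aln A nucleotide [alignment()].
#' @param reps Bootstrap replicates (>= 1; 2000 is the conventional value).
#' @param seed Seed for resampling.
#' @param method,gamma_shape Distance options as in [distance_matrix()].
#' @return Rooted-display `ape::phylo` with `node.label` support percentages
#'   (`NA` at the root).
#' @export
nj_bootstrap <- function(aln, reps = 2000, seed = NULL,
                         method = c("jc", "tn", "p"), gamma_shape = Inf) {
  method <- match.arg(method)
  if (reps < 1) abort("reps must be >= 1")
  if (is.null(seed)) abort("seed is required")
  aln <- complete_deletion(aln)
  x <- code_alignment(aln)
  L <- ncol(x)
  n <- nrow(x)
  pairs <- utils::combn(n, 2)
  dist_from_cols <- function(cols) {
    d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      d[i, j] <- d[j, i] <- pair_dist_coded(x[i, ], x[j, ], cols, method,
                                            gamma_shape)
    }
    d
  }
  main <- nj_tree(dist_from_cols(seq_len(L)))
  boots <- with_seed(seed, {
    lapply(seq_len(reps), function(r) {
      d <- dist_from_cols(sample.int(L, L, replace = TRUE))
      if (any(!is.finite(d))) NULL else nj_tree(d)
    })
  })
  boots <- boots[!vapply(boots, is.null, TRUE)]
  if (!length(boots)) abort("all bootstrap replicates failed (saturation)")
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- as.character(round(100 * counts / length(boots), 1))
  main
}

#' Root a tree on an outgroup
#'
#' The root is placed at the midpoint of the edge separating the
#' (necessarily monophyletic) outgroup from the rest.
#'
#' @param tree Unrooted or rooted `ape::phylo`.
#' @param outgroup Character vector of outgroup tip labels.
#' @return Rooted `ape::phylo`.
#' @export
root_tree <- function(tree, outgroup) {
  miss <- setdiff(outgroup, tree$tip.label)
  if (length(miss))
    abort(paste0("outgroup tips not in tree: ", paste(miss, collapse = ", ")))
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
    error = function(e) abort(paste0("cannot root: ", conditionMessage(e))))
  if (!ape::is.monophyletic(rooted, outgroup))
    abort("outgroup is not monophyletic")
  # split the bisected edge evenly between the two root children
  root_node <- ape::Ntip(rooted) + 1L
  kids <- which(rooted$edge[, 1] == root_node)
  if (length(kids) == 2) {
    tot <- sum(rooted$edge.length[kids])
    rooted$edge.length[kids] <- tot / 2
  }
  rooted
}

node_depths <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  depth <- numeric(n_all)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge)))
    depth[ord$edge[e, 2]] <- depth[ord$edge[e, 1]] + ord$edge.length[e]
  depth
}

clade_tips <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  if (node <= n_tip) return(node)
  unlist(lapply(which(tree$edge[, 1] == node),
                function(e) clade_tips(tree, tree$edge[e, 2])))
}

#' Linearize a rooted tree under a molecular clock
#'
#' Each internal node's height is the mean, over its descendant leaves, of
#' the leaf-to-node path length; tips sit at height zero. Heights are then
#' clamped to be non-decreasing root-ward and branch lengths rebuilt from
#' them, yielding an ultrametric (clock-like) tree. This is an unweighted
#' leaf-averaging approximation of the two-cluster linearized-tree
#' construction used by clock-dating software.
#'
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @return Ultrametric `ape::phylo`; node heights (substitutions/site,
#'   indexed tips first then internal nodes) in attribute `"node_heights"`.
#' @export
linearize <- function(tree) {
  if (!ape::is.rooted(tree)) abort("linearize needs a rooted tree")
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  depth <- node_depths(tree)
  h <- numeric(n_all)
  for (nd in (n_tip + 1):n_all) {
    tips <- clade_tips(tree, nd)
    h[nd] <- mean(depth[tips] - depth[nd])
  }
  # enforce parent >= child, tips upward
  post <- rev(ape::reorder.phylo(tree, "cladewise")$edge[, 1])
  for (parent in unique(post)) {
    kids <- tree$edge[tree$edge[, 1] == parent, 2]
    h[parent] <- max(h[parent], max(h[kids]))
  }
  out <- tree
  out$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
  attr(out, "node_heights") <- h
  out
}

#' Calibration point for clock dating
#'
#' @param taxon_a,taxon_b Tip labels (character vectors) whose most recent
#'   common ancestor is the calibrated split.
#' @param time Age of that split in Mya (> 0).
#' @return A `calibration` object.
#' @export
calibration <- function(taxon_a, taxon_b, time) {
  if (time <= 0) abort("calibration time must be positive")
  structure(list(taxon_a = taxon_a, taxon_b = taxon_b, time = time),
            class = "calibration")
}

#' Date the nodes of a linearized tree against one calibration
#'
#' Every node's age is `height * time / height_cal`, where `height_cal` is
#' the height of the calibration pair's most recent common ancestor. The
#' implied substitution rate is `height_cal / time` (substitutions per site
#' per My).
#'
#' @param linearized Output of [linearize()].
#' @param cal A [calibration()].
#' @return A `clade_dating` object; see [tidy.clade_dating()].
#' @export
date_nodes <- function(linearized, cal) {
  h <- attr(linearized, "node_heights")
  if (is.null(h)) abort("date_nodes expects a linearize()d tree")
  mrca <- ape::getMRCA(linearized, c(cal$taxon_a, cal$taxon_b))
  if (is.null(mrca)) abort("calibration taxa do not identify a node")
  h_cal <- h[mrca]
  if (h_cal <= 0) abort("calibration node has zero height")
  n_tip <- ape::Ntip(linearized)
  nodes <- (n_tip + 1):(n_tip + linearized$Nnode)
  dates <- tibble(
    node = nodes,
    leaf_set = vapply(nodes, function(nd)
      paste(sort(linearized$tip.label[clade_tips(linearized, nd)]),
            collapse = "|"), ""),
    height = h[nodes],
    date_mya = h[nodes] * cal$time / h_cal)
  structure(list(tree = linearized, rate = h_cal / cal$time,
                 calibration = cal, calibration_node = mrca, dates = dates),
            class = "clade_dating")
}

#' @export
print.clade_dating <- function(x, ...) {
  cat(sprintf("<clade_dating> %d nodes, rate %.3g subs/site/My, calibration %.1f Mya\n",
              nrow(x$dates), x$rate, x$calibration$time))
  print(x$dates)
  invisible(x)
}

#' Tidy a clade dating
#'
#' @param x A `clade_dating` from [date_nodes()].
#' @param ... Unused.
#' @return Tibble with one row per internal node: `node`, `leaf_set`,
#'   `height` (substitutions/site) and `date_mya`.
#' @export
tidy.clade_dating <- function(x, ...) x$dates

#' @rdname tidy.clade_dating
#' @export
glance.clade_dating <- function(x, ...) {
  tibble(rate = x$rate, calibration_time = x$calibration$time,
         calibration_node = x$calibration_node, n_nodes = nrow(x$dates))
}

#' Age of the split between two leaves, in Mya
#'
#' Convenience accessor: the dated age of the most recent common ancestor
#' of `a` and `b`.
#'
#' @param dating A `clade_dating`.
#' @param a,b Tip labels.
#' @return Numeric age in Mya.
#' @export
node_date <- function(dating, a, b) {
  nd <- ape::getMRCA(dating$tree, c(a, b))
  dating$dates$date_mya[dating$dates$node == nd]
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot dated duplication nodes
#'
#' @param object A `clade_dating`.
#' @param ... Unused.
#' @return A ggplot: node ages with the calibration node highlighted.
#' @export
autoplot.clade_dating <- function(object, ...) {
  df <- object$dates
  df$calibration <- df$node == object$calibration_node
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(leaf_set, date_mya),
                                   y = date_mya, fill = calibration)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "node age (Mya)", fill = "calibration node") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
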