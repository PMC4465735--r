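## Distance-based tree-with-support backend: p/JC69/K2P distances,
## neighbour-joining, nonparametric bootstrap with bipartition counting,
## and clade-support extraction.  The backend substitutes for external ML
## engines in the rarefaction machinery: it supplies replicate trees and
## bipartition frequencies, and any function mapping a distance matrix to a
## phylo can be plugged in.

#' Pairwise distance matrix from an alignment
#'
#' Distances are computed over comparable columns (both sequences showing an
#' unambiguous base), i.e. with pairwise deletion.  Pairs sharing fewer than
#' `min_overlap` comparable columns are assigned a flagged large distance
#' (twice the largest finite distance) and marked in the `flagged`
#' attribute.
#'
#' @param alignment Character matrix (taxa x columns).
#' @param model `"p"` (proportion of differing sites), `"JC69"`
#'   (`-3/4 log(1 - 4p/3)`) or `"K2P"` (Kimura two-parameter).
#' @param min_overlap Minimum comparable columns per pair.
#' @return Symmetric numeric matrix with taxa as dimnames and a `flagged`
#'   logical matrix attribute.
#' @export
distance_matrix <- function(alignment, model = c("p", "JC69", "K2P"),
                            min_overlap = 100) {
  model <- match.arg(model)
  codes <- matrix(match(alignment, DNA_BASES, nomatch = 0L),
                  nrow = nrow(alignment))
  n <- nrow(codes)
  taxa <- rownames(alignment)
  if (any(rowSums(codes > 0L) == 0))
    stop("taxon with zero non-missing sites: ",
         paste(taxa[rowSums(codes > 0L) == 0], collapse = ", "))
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  flagged <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- codes[i, ]; b <- codes[j, ]
      comp <- a > 0L & b > 0L
      nc <- sum(comp)
      if (nc < min_overlap) {
        d[i, j] <- d[j, i] <- NA_real_
        flagged[i, j] <- flagged[j, i] <- TRUE
        next
      }
      aa <- a[comp]; bb <- b[comp]
      p <- mean(aa != bb)
      val <- switch(model,
        p = p,
        JC69 = if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_,
        K2P = {
          ts <- mean((aa == 1L & bb == 3L) | (aa == 3L & bb == 1L) |
                       (aa == 2L & bb == 4L) | (aa == 4L & bb == 2L))
          tv <- p - ts
          arg1 <- 1 - 2 * ts - tv; arg2 <- 1 - 2 * tv
          if (arg1 > 0 && arg2 > 0) -0.5 * log(arg1 * sqrt(arg2))
          else NA_real_
        })
      if (is.na(val)) {
        d[i, j] <- d[j, i] <- NA_real_
        flagged[i, j] <- flagged[j, i] <- TRUE
      } else d[i, j] <- d[j, i] <- val
    }
  }
  if (any(flagged)) {
    big <- 2 * max(d[!flagged & upper.tri(d)], 0.75, na.rm = TRUE)
    d[is.na(d)] <- big
  }
  attr(d, "flagged") <- flagged
  d
}

#' Neighbour-joining tree
#'
#' Standard neighbour joining (via `ape::nj`); rows/columns are reordered by
#' taxon label first, so ties in the Q criterion are broken identically
#' regardless of input order.
#'
#' @param distances Symmetric numeric matrix with taxon dimnames.
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(distances) {
  distances <- as.matrix(distances)
  if (nrow(distances) < 4) stop("neighbour joining needs >= 4 taxa")
  if (any(!is.finite(distances))) stop("non-finite distances")
  o <- order(rownames(distances))
  ape::nj(distances[o, o])
}

## ---- bipartitions ---------------------------------------------------------

## Tip-label sets below each internal edge of a tree.
tree_splits <- function(tree) {
  nt <- ape::Ntip(tree)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  tr <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  internal <- which(tree$edge[, 2] > nt)
  out <- lapply(internal, function(e)
    sort(tree$tip.label[desc[[tree$edge[e, 2]]]]))
  names(out) <- tree$edge[internal, 2]
  ## drop trivial splits (all tips or all-but-one)
  keep <- vapply(out, function(s)
    length(s) >= 2 && length(s) <= nt - 2, logical(1))
  out[keep]
}

## Canonical key of a bipartition: the side not containing the reference
## (alphabetically first) taxon.
split_key <- function(tipset, all_tips) {
  anchor <- min(all_tips)
  side <- if (anchor %in% tipset) setdiff(all_tips, tipset) else tipset
  paste(sort(side), collapse = ";")
}

## Count bipartitions over a list of trees; returns a named integer vector.
count_splits <- function(trees, all_tips) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (tr in trees) {
    for (s in tree_splits(tr)) {
      k <- split_key(s, all_tips)
      env[[k]] <- (if (is.null(env[[k]])) 0L else env[[k]]) + 1L
    }
  }
  keys <- ls(env)
  stats::setNames(vapply(keys, function(k) env[[k]], integer(1)), keys)
}

#' Bootstrap node support on a distance tree
#'
#' Columns are resampled with replacement (`n_reps` replicates); a tree is
#' inferred per replicate with the distance backend, and bipartition
#' frequencies are mapped onto the tree inferred from the original
#' alignment.  When `codon_aware = TRUE` whole codon triplets are resampled
#' instead of single columns.
#'
#' @param alignment Character matrix (taxa x columns).
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param model Distance model, see [distance_matrix()].
#' @param codon_aware Resample codon triplets (requires length divisible
#'   by 3).
#' @param min_overlap Passed to the per-replicate distance computation.
#' @param tree_fun Backend mapping a distance matrix to a `phylo`
#'   (default [nj_tree()]); an external inference wrapper can be plugged in.
#' @return A `support_tree`: `tree` (best tree), `support` (data frame:
#'   node, split key, support in [0, 100]), `split_counts`, `n_reps_used`,
#'   `taxa`.
#' @export
bootstrap_support <- function(alignment, n_reps = 100, seed = 1,
                              model = "p", codon_aware = FALSE,
                              min_overlap = 100, tree_fun = nj_tree) {
  stopifnot(n_reps >= 1)
  taxa <- rownames(alignment)
  n <- length(taxa)
  L <- ncol(alignment)
  best <- tree_fun(distance_matrix(alignment, model = model,
                                   min_overlap = min_overlap))

  ## precomputed per-column pair indicators for fast replicate distances
  codes <- matrix(match(alignment, DNA_BASES, nomatch = 0L), nrow = n)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  comp <- matrix(FALSE, np, L); mism <- matrix(FALSE, np, L)
  tran <- if (model == "K2P") matrix(FALSE, np, L) else NULL
  for (k in seq_len(np)) {
    a <- codes[pairs[1, k], ]; b <- codes[pairs[2, k], ]
    comp[k, ] <- a > 0L & b > 0L
    mism[k, ] <- comp[k, ] & a != b
    if (!is.null(tran))
      tran[k, ] <- (a == 1L & b == 3L) | (a == 3L & b == 1L) |
        (a == 2L & b == 4L) | (a == 4L & b == 2L)
  }

  set.seed(seed)
  rep_trees <- vector("list", n_reps)
  failures <- 0L
  big_flag <- 5
  for (r in seq_len(n_reps)) {
    if (codon_aware && L %% 3 == 0) {
      cs <- sample.int(L / 3, L / 3, replace = TRUE)
      idx <- rep((cs - 1) * 3, each = 3) + rep(1:3, times = L / 3)
    } else {
      idx <- sample.int(L, L, replace = TRUE)
    }
    nc <- rowSums(comp[, idx, drop = FALSE])
    nm <- rowSums(mism[, idx, drop = FALSE])
    p <- ifelse(nc > 0, nm / nc, NA_real_)
    val <- switch(model,
      p = p,
      JC69 = ifelse(!is.na(p) & p < 0.75, -0.75 * log(1 - 4 * p / 3),
                    NA_real_),
      K2P = {
        nts <- rowSums(tran[, idx, drop = FALSE])
        ts <- ifelse(nc > 0, nts / nc, NA_real_)
        tv <- p - ts
        a1 <- 1 - 2 * ts - tv; a2 <- 1 - 2 * tv
        ifelse(!is.na(a1) & a1 > 0 & a2 > 0, -0.5 * log(a1 * sqrt(a2)),
               NA_real_)
      })
    flag <- is.na(val) | nc < min_overlap
    if (any(flag)) {
      mx <- if (all(flag)) big_flag else 2 * max(val[!flag], 0.75)
      val[flag] <- mx
    }
    d <- matrix(0, n, n, dimnames = list(taxa, taxa))
    d[t(pairs)] <- val; d[t(pairs[2:1, , drop = FALSE])] <- val
    tr <- tryCatch(tree_fun(d), error = function(e) NULL)
    if (is.null(tr)) failures <- failures + 1L else rep_trees[[r]] <- tr
  }
  if (failures > 0.1 * n_reps)
    stop(failures, " of ", n_reps, " bootstrap replicates failed")
  rep_trees <- Filter(Negate(is.null), rep_trees)
  counts <- count_splits(rep_trees, taxa)

  best_splits <- tree_splits(best)
  keys <- vapply(best_splits, split_key, character(1), all_tips = taxa)
  supp <- vapply(keys, function(k) {
    ct <- counts[k]
    100 * (if (is.na(ct)) 0 else ct) / length(rep_trees)
  }, numeric(1))
  support <- data.frame(node = as.integer(names(best_splits)),
                        split = unname(keys), support = unname(supp),
                        stringsAsFactors = FALSE)
  structure(list(tree = best, support = support, split_counts = counts,
                 n_reps_used = length(rep_trees), taxa = taxa),
            class = "support_tree")
}

#' Define a clade to track
#'
#' @param name Clade label.
#' @param taxa Taxa in the clade (non-empty proper subset of study taxa).
#' @param kind `"monophyly"` (the bipartition separating exactly these taxa)
#'   or `"mrca"` (the smallest bipartition side containing the named taxa on
#'   the best tree).
#' @return A `clade_definition`.
#' @export
clade_definition <- function(name, taxa, kind = c("monophyly", "mrca")) {
  structure(list(name = name, taxa = sort(taxa), kind = match.arg(kind)),
            class = "clade_definition")
}

#' Bootstrap support for a clade
#'
#' @param x A `support_tree`, or a list of replicate trees (`multiPhylo` or
#'   plain list of `phylo`) for direct bipartition counting.
#' @param clade A [clade_definition()].
#' @return Support percentage in `[0, 100]`.
#' @export
clade_support <- function(x, clade) {
  if (inherits(x, "support_tree")) {
    taxa <- x$taxa
    if (!all(clade$taxa %in% taxa))
      stop("clade taxa not a subset of tree leaves")
    key <- if (clade$kind == "monophyly") {
      split_key(clade$taxa, taxa)
    } else {
      ## smallest bipartition side on the best tree containing the clade
      sides <- tree_splits(x$tree)
      cand <- list()
      for (s in sides) {
        comp <- setdiff(taxa, s)
        if (all(clade$taxa %in% s)) cand <- c(cand, list(s))
        if (all(clade$taxa %in% comp)) cand <- c(cand, list(comp))
      }
      if (!length(cand)) return(0)
      best_side <- cand[[which.min(lengths(cand))]]
      split_key(best_side, taxa)
    }
    ct <- x$split_counts[key]
    return(100 * (if (is.na(ct)) 0 else unname(ct)) / x$n_reps_used)
  }
  ## list of replicate trees: frequency of the exact bipartition
  trees <- if (inherits(x, "multiPhylo")) unclass(x) else x
  taxa <- sort(trees[[1]]$tip.label)
  if (!all(clade$taxa %in% taxa))
    stop("clade taxa not a subset of tree leaves")
  key <- split_key(clade$taxa, taxa)
  hits <- vapply(trees, function(tr) {
    ks <- vapply(tree_splits(tr), split_key, character(1), all_tips = taxa)
    key %in% ks
  }, logical(1))
  100 * mean(hits)
}

#' Average internal-node bootstrap support
#'
#' @param support_tree A `support_tree`.
#' @return Mean support over internal edges (percentage).
#' @export
average_node_support <- function(support_tree) {
  if (nrow(support_tree$support) == 0) stop("no internal edges")
  mean(support_tree$support$support)
}

#' Count nodes above a support threshold
#'
#' @param support_tree A `support_tree`.
#' @param threshold Support threshold; the count uses strict `>`.
#' @return Number of internal edges with support strictly above `threshold`.
#' @export
count_nodes_above <- function(support_tree, threshold) {
  sum(support_tree$support$support > threshold)
}

#' @export
print.support_tree <- function(x, ...) {
  cat("Support tree over", length(x$taxa), "taxa;",
      nrow(x$support), "internal edges;",
      sprintf("mean support %.1f%% (%d replicates)\n",
              mean(x$support$support), x$n_reps_used))
  invisible(x)
}

#' Write a support tree as newick with supports as node labels
#'
#' @param support_tree A `support_tree`.
#' @param file Output path.
#' @export
write_support_tree <- function(support_tree, file) {
  tr <- support_tree$tree
  nt <- ape::Ntip(tr)
  lab <- rep("", tr$Nnode)
  lab[support_tree$support$node - nt] <-
    sprintf("%.0f", support_tree$support$support)
  tr$node.label <- lab
  ape::write.tree(tr, file = file)
}
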