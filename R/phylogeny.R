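# Composite-likelihood TN93 distances, minimum-evolution tree search
# (neighbor-joining start, close-neighbor-interchange refinement under the
# ordinary-least-squares total branch length), column bootstrap, and
# cluster/supercluster assignment from the collapsed tree.

NUC <- c("A", "C", "G", "T")

# per-pair substitution-category counts under pairwise deletion
pair_counts <- function(m, i, j) {
  a <- m[i, ]; b <- m[j, ]
  keep <- a %in% NUC & b %in% NUC
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  diffc <- a != b
  pur <- (a %in% c("A", "G")) & (b %in% c("A", "G"))
  pyr <- (a %in% c("C", "T")) & (b %in% c("C", "T"))
  c(n = n,
    p1 = sum(diffc & pur), # purine transitions
    p2 = sum(diffc & pyr), # pyrimidine transitions
    q = sum(diffc & !pur & !pyr)) # transversions
}

# closed-form TN93 distance from category proportions and base frequencies
tn93_closed <- function(p1, p2, q, pi) {
  gR <- pi["A"] + pi["G"]; gY <- pi["C"] + pi["T"]
  k1c <- 2 * pi["A"] * pi["G"]; k2c <- 2 * pi["C"] * pi["T"]
  if (p1 + p2 + q == 0) return(0)
  w1 <- 1 - gR * p1 / k1c - q / (2 * gR)
  w2 <- 1 - gY * p2 / k2c - q / (2 * gY)
  w3 <- 1 - q / (2 * gR * gY)
  # a degenerate base composition (some pi = 0) or saturation leaves the
  # log arguments undefined or non-positive
  if (!all(is.finite(c(w1, w2, w3))) || any(c(w1, w2, w3) <= 0)) {
    return(NA_real_)
  }
  unname(-(k1c / gR) * log(w1) - (k2c / gY) * log(w2) -
           2 * (gR * gY - k1c * gY / (2 * gR) - k2c * gR / (2 * gY)) * log(w3))
}

# expected TN93 category proportions at distance d with rate ratios k1, k2
tn93_expected <- function(d, k1, k2, pi) {
  gR <- pi["A"] + pi["G"]; gY <- pi["C"] + pi["T"]
  # per-unit-time normalization so that d = substitutions/site
  denom <- 2 * (pi["A"] * pi["G"] * k1 + pi["C"] * pi["T"] * k2 + gR * gY)
  bt <- d / denom # beta * t
  e1 <- exp(-bt)
  e2 <- exp(-(gR * k1 + gY) * bt)
  e3 <- exp(-(gY * k2 + gR) * bt)
  EP1 <- (2 * pi["A"] * pi["G"] / gR) * (gR + gY * e1 - e2)
  EP2 <- (2 * pi["C"] * pi["T"] / gY) * (gY + gR * e1 - e3)
  EQ <- 2 * gR * gY * (1 - e1)
  c(p1 = unname(EP1), p2 = unname(EP2), q = unname(EQ))
}

pair_loglik <- function(d, k1, k2, pi, cnt) {
  e <- tn93_expected(d, k1, k2, pi)
  p0 <- max(1 - sum(e), 1e-12)
  e <- pmax(e, 1e-12)
  (cnt["n"] - cnt["p1"] - cnt["p2"] - cnt["q"]) * log(p0) +
    cnt["p1"] * log(e["p1"]) + cnt["p2"] * log(e["p2"]) + cnt["q"] * log(e["q"])
}

profile_d <- function(k1, k2, pi, cnt, upper = 8) {
  if (cnt["p1"] + cnt["p2"] + cnt["q"] == 0) return(list(d = 0, ll = 0))
  opt <- optimize(function(d) pair_loglik(d, k1, k2, pi, cnt),
                  interval = c(1e-9, upper), maximum = TRUE, tol = 1e-8)
  list(d = opt$maximum, ll = opt$objective)
}

#' Composite-likelihood TN93 evolutionary distances
#'
#' Tamura-Nei (TN93) distances with base frequencies pooled over the whole
#' alignment and the two transition/transversion rate ratios estimated
#' jointly across all pairs by maximizing the composite (summed over pairs)
#' log-likelihood, each pair's distance profiled out numerically. With
#' `method = "closed_form"` (also the fallback when the joint optimization
#' fails) the analytic TN93 distance is computed per pair from its category
#' proportions and the pooled frequencies. Gap columns are excluded per pair
#' (pairwise deletion). A saturated pair (negative logarithm argument)
#' yields `NA` with a warning.
#'
#' @param aln A `cgap_codon_alignment` or nucleotide character matrix.
#' @param method `"composite"` (default) or `"closed_form"`.
#' @param rates Optional list with `k1`, `k2` to reuse previously estimated
#'   rate ratios (used by the bootstrap).
#' @return Object of class `cgap_mcl`: list with `distances` (symmetric
#'   matrix), `rates` (`k1`, `k2`, `pi`), and `method`.
#' @export
mcl_distances <- function(aln, method = c("composite", "closed_form"),
                          rates = NULL) {
  method <- match.arg(method)
  m <- if (inherits(aln, "cgap_codon_alignment")) as_nucleotide_matrix(aln) else aln
  ids <- rownames(m)
  n <- nrow(m)
  tabs <- table(factor(m[m %in% NUC], levels = NUC))
  pi <- as.numeric(tabs) / sum(tabs)
  names(pi) <- NUC
  pairs <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  cnts <- lapply(seq_len(nrow(pairs)), function(r) {
    pair_counts(m, pairs[r, 1L], pairs[r, 2L])
  })
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  used <- method
  if (method == "composite" && is.null(rates)) {
    comp_ll <- function(par) {
      k1 <- exp(par[1L]); k2 <- exp(par[2L])
      -sum(vapply(cnts, function(cnt) profile_d(k1, k2, pi, cnt)$ll, double(1)))
    }
    fit <- tryCatch(
      optim(log(c(4, 4)), comp_ll, method = "Nelder-Mead",
            control = list(maxit = 200, reltol = 1e-7)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value)) {
      warn("joint composite-likelihood optimization failed; falling back to per-pair TN93")
      used <- "closed_form"
    } else {
      rates <- list(k1 = exp(fit$par[1L]), k2 = exp(fit$par[2L]))
    }
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    cnt <- cnts[[r]]
    if (cnt["n"] == 0) { D[i, j] <- D[j, i] <- NA_real_; next }
    d <- if (used == "composite") {
      profile_d(rates$k1, rates$k2, pi, cnt)$d
    } else {
      tn93_closed(cnt["p1"] / cnt["n"], cnt["p2"] / cnt["n"],
                  cnt["q"] / cnt["n"], pi)
    }
    if (is.na(d)) {
      warn(sprintf("saturated pair %s / %s: distance undefined", ids[i], ids[j]))
    }
    D[i, j] <- D[j, i] <- d
  }
  structure(list(distances = D, rates = c(rates, list(pi = pi)), method = used),
            class = "cgap_mcl")
}

#' OLS branch lengths and total tree length
#'
#' Fits ordinary-least-squares branch lengths to a tree given a distance
#' matrix; the total (summed) branch length is the minimum-evolution score
#' of the topology.
#'
#' @param tree An unrooted `phylo` tree.
#' @param dmat Symmetric distance matrix over the tip labels.
#' @return List with `tree` (branch lengths replaced by OLS estimates) and
#'   `total` (OLS total branch length).
#' @export
ols_branch_lengths <- function(tree, dmat) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  X <- phangorn::designTree(tree)
  dv <- as.dist(dmat[attr(X, "Labels") %||% tree$tip.label,
                     attr(X, "Labels") %||% tree$tip.label])
  fit <- lm.fit(as.matrix(X), as.vector(dv))
  b <- fit$coefficients
  # design columns are named "parent<->child"; map onto the edge matrix
  edge_key <- paste0(tree$edge[, 1L], "<->", tree$edge[, 2L])
  tree$edge.length <- unname(b[match(edge_key, colnames(X))])
  list(tree = tree, total = sum(b))
}

nj_tree <- function(D) {
  keep <- rowSums(is.na(D)) == 0
  if (!all(keep)) {
    warn(sprintf("dropping %d taxa with missing distances", sum(!keep)))
    D <- D[keep, keep, drop = FALSE]
  }
  ape::nj(as.dist(D))
}

me_search <- function(D, start = NULL) {
  tree <- start %||% nj_tree(D)
  tree <- ape::unroot(tree)
  fit <- ols_branch_lengths(tree, D)
  repeat {
    improved <- FALSE
    nbrs <- phangorn::nni(fit$tree)
    for (ci in seq_along(nbrs)) {
      cand <- nbrs[[ci]] # [[ reattaches tip labels on compressed multiPhylo
      cf <- ols_branch_lengths(cand, D)
      if (cf$total < fit$total - 1e-10) {
        fit <- cf
        improved <- TRUE
        break # first improvement, deterministic traversal order
      }
    }
    if (!improved) break
  }
  fit
}

#' Minimum-evolution tree with bootstrap supports
#'
#' Builds a neighbor-joining starting tree from composite-likelihood TN93
#' distances and refines it by close-neighbor-interchange, accepting any
#' swap that lowers the ordinary-least-squares total branch length (first
#' improvement in a deterministic traversal). Bootstrap replicates resample
#' nucleotide alignment columns with replacement, recompute distances
#' (closed-form TN93 reusing the point-estimate rate ratios) and the tree,
#' and count bipartition occurrences; internal branches below the collapse
#' threshold are contracted in `collapsed_tree`.
#'
#' @param aln A `cgap_codon_alignment`, or a distance matrix (in which case
#'   `n_bootstrap` must be 0).
#' @param n_bootstrap Bootstrap replicates (default 100; the protocol-scale
#'   default in [protocol_config()] is 1000).
#' @param seed Seed for the bootstrap resampling.
#' @param collapse Support percentage below which branches are collapsed.
#' @param method Distance method for the point estimate, see
#'   [mcl_distances()].
#' @return Object of class `cgap_phylo`: `tree` (node labels = supports),
#'   `collapsed_tree`, `distances`, `ols_length`, `supports`,
#'   `n_bootstrap`.
#' @export
me_tree <- function(aln, n_bootstrap = 100L, seed = 1L, collapse = 50,
                    method = "composite") {
  from_matrix <- is.matrix(aln) && is.numeric(aln)
  if (from_matrix) {
    if (n_bootstrap > 0L) abort("bootstrap needs an alignment, not a matrix")
    D <- aln
    rates <- NULL
  } else {
    mcl <- mcl_distances(aln, method = method)
    D <- mcl$distances
    rates <- mcl$rates
  }
  fit <- me_search(D)
  supports <- NULL
  tree <- fit$tree
  collapsed <- tree
  if (n_bootstrap > 0L) {
    m <- as_nucleotide_matrix(aln)
    m <- m[tree$tip.label, , drop = FALSE]
    set.seed(seed)
    boots <- vector("list", n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      Db <- mcl_distances(m[, cols, drop = FALSE], method = "closed_form",
                          rates = rates[c("k1", "k2")])$distances
      if (anyNA(Db)) Db[is.na(Db)] <- max(Db, na.rm = TRUE) * 2
      boots[[b]] <- me_search(Db)$tree
    }
    class(boots) <- "multiPhylo"
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    supports <- round(100 * counts / n_bootstrap, 1)
    tree$node.label <- supports
    collapsed <- tree
    collapsed$node.label[1L] <- 100 # root pseudo-node
    # zero-length internal branches carry no signal regardless of their
    # bootstrap count (identical sequences reproduce the same arbitrary
    # start topology in every replicate)
    collapsed <- ape::di2multi(collapsed, tol = 1e-8)
    collapsed <- phangorn::pruneTree(collapsed, collapse)
  }
  structure(
    list(tree = tree, collapsed_tree = collapsed, distances = D,
         ols_length = fit$total, supports = supports,
         n_bootstrap = as.integer(n_bootstrap)),
    class = "cgap_phylo"
  )
}

#' @export
print.cgap_phylo <- function(x, ...) {
  cat(sprintf("<minimum-evolution tree: %d tips, OLS length %.4f, %d bootstrap replicates>\n",
              length(x$tree$tip.label), x$ols_length, x$n_bootstrap))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cgap_phylo <- function(x, ...) {
  tibble(n_tips = length(x$tree$tip.label), ols_length = x$ols_length,
         n_bootstrap = x$n_bootstrap,
         min_support = if (length(x$supports)) min(x$supports) else NA_real_)
}

#' @exportS3Method generics::tidy
tidy.cgap_phylo <- function(x, ...) {
  tr <- x$tree
  ntip <- length(tr$tip.label)
  child <- tr$edge[, 2L]
  label <- rep(NA_character_, length(child))
  label[child <= ntip] <- tr$tip.label[child[child <= ntip]]
  support <- rep(NA_real_, length(child))
  if (length(x$supports)) {
    internal <- child > ntip
    support[internal] <- x$supports[child[internal] - ntip]
  }
  tibble(parent = tr$edge[, 1L], child = child,
         length = tr$edge.length, label = label, support = support)
}

#' Assign cluster and supercluster labels from a collapsed tree
#'
#' Known gene labels (`cluster_label` on the records) define the major gene
#' clusters; each label must be monophyletic in the collapsed tree or it is
#' flagged. Superclusters are the subtrees hanging off the midpoint root of
#' the collapsed tree, i.e. the deepest well-supported clades; they are
#' numbered by size (descending, ties by traversal order) and their member
#' clusters lettered `A`, `B`, ... by post-order appearance.
#'
#' @param phylo A `cgap_phylo` (its `collapsed_tree` is used) or a `phylo`.
#' @param records A `cgap_records` tibble with `cluster_label` filled for
#'   the tree's tips.
#' @return Tibble: `record_id`, `known_cluster`, `supercluster`, `cluster`
#'   (lettered name), `monophyletic`.
#' @export
assign_clusters <- function(phylo, records) {
  tree <- if (inherits(phylo, "cgap_phylo")) phylo$collapsed_tree else phylo
  labs <- setNames(records$cluster_label, records$id)
  if (!all(tree$tip.label %in% names(labs))) {
    abort("tree tips missing from record set")
  }
  tip_cluster <- labs[tree$tip.label]
  rooted <- phangorn::midpoint(tree)
  clusters <- unique(tip_cluster)
  # monophyly on the unrooted tree: the tip set (or its complement) must be
  # one side of some bipartition
  parts <- lapply(ape::prop.part(tree), function(p) sort(tree$tip.label[p]))
  ntips <- length(tree$tip.label)
  mono <- vapply(clusters, function(cl) {
    tips <- sort(tree$tip.label[tip_cluster == cl])
    if (length(tips) <= 1L || length(tips) >= ntips - 1L) return(TRUE)
    comp <- sort(setdiff(tree$tip.label, tips))
    any(vapply(parts, function(p) identical(p, tips) || identical(p, comp),
               logical(1)))
  }, logical(1))
  if (!all(mono)) {
    warn(sprintf("non-monophyletic known label(s): %s",
                 paste(clusters[!mono], collapse = ", ")))
  }
  # supercluster = root-child subtree of the midpoint-rooted collapsed tree
  ntip <- length(rooted$tip.label)
  root <- ntip + 1L
  kids <- rooted$edge[rooted$edge[, 1L] == root, 2L]
  tip_group <- integer(ntip)
  for (gi in seq_along(kids)) {
    tips <- if (kids[gi] <= ntip) kids[gi] else {
      which(rooted$tip.label %in%
              ape::extract.clade(rooted, kids[gi])$tip.label)
    }
    tip_group[tips] <- gi
  }
  # each cluster joins the supercluster holding the majority of its tips
  cl_group <- vapply(clusters, function(cl) {
    g <- tip_group[tip_cluster[rooted$tip.label] == cl]
    as.integer(names(sort(table(g), decreasing = TRUE))[1L])
  }, integer(1))
  # post-order tip appearance for deterministic lettering
  po <- ape::reorder.phylo(rooted, "postorder")
  postorder_tips <- rooted$tip.label[po$edge[po$edge[, 2L] <= ntip, 2L]]
  first_seen <- vapply(clusters, function(cl) {
    min(match(rooted$tip.label[tip_cluster[rooted$tip.label] == cl],
              postorder_tips))
  }, numeric(1))
  group_sizes <- table(factor(tip_group, levels = seq_along(kids)))
  group_rank <- order(-as.integer(group_sizes), seq_along(kids))
  sc_number <- match(cl_group, group_rank)
  out <- tibble(known_cluster = clusters, supercluster = as.character(sc_number),
                order_in_sc = first_seen)
  out <- dplyr::arrange(out, .data$supercluster, .data$order_in_sc)
  out <- dplyr::mutate(dplyr::group_by(out, .data$supercluster),
                       cluster = paste0(.data$supercluster,
                                        LETTERS[dplyr::row_number()]))
  out <- dplyr::ungroup(out)
  res <- tibble(record_id = tree$tip.label,
                known_cluster = unname(tip_cluster))
  res <- dplyr::left_join(res, out[, c("known_cluster", "supercluster", "cluster")],
                          by = "known_cluster")
  res$monophyletic <- mono[res$known_cluster]
  res
}
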