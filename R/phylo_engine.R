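#' Read a rooted, branch-length-bearing Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces the contract the
#' comparative machinery needs: branch lengths present and nonnegative, tip
#' labels unique. Polytomies and zero-length branches are permitted.
#'
#' @param path Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in '", path,
                                            "': ", conditionMessage(e)),
                   warning = function(w) stop("Newick parse error in '", path,
                                              "': ", conditionMessage(w)))
  if (is.null(tree)) stop("Newick parse error in '", path, "'")
  check_tree(tree)
  tree
}

# Contract checks shared by readers and simulators.
check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("branch lengths must be nonnegative and complete")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  invisible(tree)
}

#' Prune a tree to a set of tips
#'
#' Induced subtree on `keep`: dropped lineages are removed, unifurcations
#' collapsed with branch lengths summed, so the root-to-tip depth of every kept
#' tip is unchanged.
#'
#' @param tree An [ape::phylo] tree.
#' @param keep Tip labels to retain (at least 3, all present in the tree).
#' @return Pruned tree.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0) {
    stop("tips not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(keep) < 3) {
    stop("fewer than 3 taxa retained (", length(keep),
         "); comparative analysis needs at least 3")
  }
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Tip depths (root-to-tip path lengths)
#'
#' @param tree An [ape::phylo] tree.
#' @return Named numeric vector of depths per tip.
#' @export
tip_depths <- function(tree) {
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  stats::setNames(depths[seq_len(n)], tree$tip.label)
}

is_ultrametric <- function(tree, rel_tol = 1e-6) {
  d <- tip_depths(tree)
  (max(d) - min(d)) <= rel_tol * max(d)
}

new_phylo_cov <- function(C, model, parameters = list()) {
  structure(list(taxa = rownames(C), C = C, model = model,
                 parameters = parameters),
            class = "phylo_cov")
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat("Phylogenetic covariance (", x$model, "), ", length(x$taxa),
      " taxa\n", sep = "")
  if (length(x$parameters) > 0) {
    cat("  parameters:",
        paste(names(x$parameters), signif(unlist(x$parameters), 4),
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Brownian-motion covariance matrix
#'
#' `C[i, j]` is the branch length shared by the root-to-tip paths of tips i and
#' j; the diagonal holds tip depths. Zero-length terminal branches risk a
#' singular matrix and are jittered by `1e-8` times the tree depth, with a
#' warning.
#'
#' @param tree An [ape::phylo] tree.
#' @return A `phylo_cov` object (fields `taxa`, `C`, `model`, `parameters`).
#' @export
bm_covariance <- function(tree) {
  check_tree(tree)
  term <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[term] == 0)) {
    warning("zero-length terminal branches: jittering diagonal to keep the ",
            "covariance matrix nonsingular")
    C <- ape::vcv.phylo(tree)
    diag(C) <- diag(C) + 1e-8 * max(diag(C))
  } else {
    C <- ape::vcv.phylo(tree)
  }
  new_phylo_cov(C, "BM")
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies all off-diagonal entries by `lambda`, leaving the diagonal
#' untouched: `lambda = 1` is the original (Brownian) covariance, `lambda = 0`
#' a star phylogeny.
#'
#' @param cov A `phylo_cov` (or plain matrix).
#' @param lambda Signal parameter in \[0, 1\].
#' @return A `phylo_cov` with `model = "lambda"`.
#' @export
lambda_transform <- function(cov, lambda) {
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]")
  }
  C <- if (inherits(cov, "phylo_cov")) cov$C else cov
  d <- diag(C)
  C2 <- C * lambda
  diag(C2) <- d
  new_phylo_cov(C2, "lambda", list(lambda = lambda))
}

#' Ornstein-Uhlenbeck covariance
#'
#' Stationary OU covariance on an ultrametric tree of depth `T`:
#' \deqn{C_{ij} = \frac{1}{2\alpha} e^{-2\alpha (T - t_{ij})}
#'   (1 - e^{-2\alpha t_{ij}})}
#' where `t_ij` is the shared path length under BM. The limit `alpha -> 0`
#' recovers the BM covariance and is evaluated analytically below
#' `alpha = 1e-9`.
#'
#' @param tree Ultrametric [ape::phylo] tree (relative tip-depth spread within
#'   `1e-6`).
#' @param alpha Attraction strength, \eqn{\ge 0}.
#' @return A `phylo_cov` with `model = "OU"`.
#' @export
ou_transform <- function(tree, alpha) {
  if (alpha < 0) stop("alpha must be nonnegative")
  if (!is_ultrametric(tree)) {
    stop("OU covariance requires an ultrametric tree ",
         "(relative tip-depth spread exceeds 1e-6)")
  }
  bm <- bm_covariance(tree)
  Tdepth <- max(diag(bm$C))
  if (alpha < 1e-9) {
    C <- bm$C
  } else {
    C <- (1 / (2 * alpha)) * exp(-2 * alpha * (Tdepth - bm$C)) *
      (1 - exp(-2 * alpha * bm$C))
    dimnames(C) <- dimnames(bm$C)
  }
  new_phylo_cov(C, "OU", list(alpha = alpha))
}

#' Early-burst covariance
#'
#' Brownian motion with exponentially decaying rate `exp(r t)`, `r <= 0`:
#' \deqn{C_{ij} = (e^{r t_{ij}} - 1)/r} with `t_ij` the BM shared path length;
#' `r = 0` recovers BM.
#'
#' @param tree An [ape::phylo] tree.
#' @param r Rate-decay parameter, \eqn{\le 0}.
#' @return A `phylo_cov` with `model = "EB"`.
#' @export
eb_transform <- function(tree, r) {
  if (r > 0) stop("early-burst parameter r must be <= 0")
  bm <- bm_covariance(tree)
  if (abs(r) < 1e-9) {
    C <- bm$C
  } else {
    C <- (exp(r * bm$C) - 1) / r
    dimnames(C) <- dimnames(bm$C)
  }
  new_phylo_cov(C, "EB", list(r = r))
}
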