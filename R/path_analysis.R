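#' Construct a directed acyclic path model
#'
#' @param name Model label.
#' @param edges Two-column character matrix or data frame of directed edges
#'   (`from`, `to`).
#' @param nodes Node labels; defaults to those appearing in `edges`.
#' @return Object of class `path_model` with `name`, `nodes`, `edges`.
#' @export
path_model <- function(name, edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns (from, to)")
  colnames(edges) <- c("from", "to")
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) {
    stop("duplicate edges are not allowed")
  }
  if (is.null(nodes)) nodes <- sort(unique(as.vector(edges)))
  if (!all(as.vector(edges) %in% nodes)) {
    stop("edges reference nodes outside the node set")
  }
  m <- structure(list(name = name, nodes = nodes, edges = edges),
                 class = "path_model")
  topological_order(m)  # errors on cycles
  m
}

#' @export
print.path_model <- function(x, ...) {
  cat("Path model '", x$name, "': ",
      paste(x$edges[, 1], "->", x$edges[, 2], collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Kahn's algorithm with lexicographic tie-breaking, so claim ordering is
# deterministic.
topological_order <- function(model) {
  nodes <- model$nodes
  edges <- model$edges
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) indeg[edges[i, 2]] <- indeg[edges[i, 2]] + 1L
  order_out <- character(0)
  remaining <- nodes
  while (length(remaining) > 0) {
    ready <- sort(remaining[indeg[remaining] == 0L])
    if (length(ready) == 0) stop("graph is cyclic: no topological order exists")
    v <- ready[1]
    order_out <- c(order_out, v)
    remaining <- setdiff(remaining, v)
    ch <- edges[edges[, 1] == v, 2]
    indeg[ch] <- indeg[ch] - 1L
  }
  order_out
}

parents_of <- function(model, node) {
  sort(unique(model$edges[model$edges[, 2] == node, 1]))
}

#' Directional-separation basis set of a DAG
#'
#' One conditional-independence claim per non-adjacent pair: with `x` before
#' `y` in topological order, `x` is claimed independent of `y` given the union
#' of the parents of `x` and the parents of `y`. Ordering of claims is
#' deterministic (topological with lexicographic tie-breaks).
#'
#' @param model A [path_model()].
#' @return List of claims, each `list(x, y, conditioning)`.
#' @export
basis_set <- function(model) {
  ord <- topological_order(model)
  edges <- model$edges
  adjacent <- function(a, b) {
    any((edges[, 1] == a & edges[, 2] == b) |
          (edges[, 1] == b & edges[, 2] == a))
  }
  claims <- list()
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (j <= i) next
      x <- ord[i]; y <- ord[j]
      if (adjacent(x, y)) next
      cond <- sort(union(parents_of(model, x), parents_of(model, y)))
      claims[[length(claims) + 1]] <- list(x = x, y = y,
                                           conditioning = setdiff(cond, c(x, y)))
    }
  }
  claims
}

#' Test one independence claim by phylogenetic regression
#'
#' Regresses `y` on the conditioning variables plus `x` under Brownian-motion
#' PGLS and returns the two-sided p-value of `x`'s coefficient (t with n - p
#' degrees of freedom, p the number of design columns).
#'
#' @param claim One claim from [basis_set()].
#' @param data Data frame of variables, rows named by taxon.
#' @param tree Tree pruned to the rows of `data`.
#' @param cov Optional precomputed `phylo_cov` for `tree` (avoids recomputing
#'   across many claims).
#' @return The p-value.
#' @export
test_claim <- function(claim, data, tree, cov = NULL) {
  vars <- c(claim$conditioning, claim$x, claim$y)
  if (!all(vars %in% colnames(data))) {
    stop("claim variables absent from data: ",
         paste(setdiff(vars, colnames(data)), collapse = ", "))
  }
  data <- data[tree$tip.label, , drop = FALSE]
  if (nrow(data) < 5) stop("claim test needs at least 5 shared taxa")
  if (is.null(cov)) cov <- bm_covariance(tree)
  X <- cbind(1, as.matrix(data[, c(claim$conditioning, claim$x), drop = FALSE]))
  y <- data[[claim$y]]
  fit <- gls_fit(y, X, cov)
  x_col <- ncol(X)
  t_stat <- fit$beta[x_col] / fit$se[x_col]
  2 * stats::pt(abs(t_stat), df = fit$n - fit$p, lower.tail = FALSE)
}

#' Fisher's C statistic
#'
#' Combines the basis-set p-values: `C = -2 sum(log p)`, chi-square with `2k`
#' degrees of freedom under the model. P-values are floored at 1e-300 before
#' the log. An empty claim list (saturated model) gives C = 0 with p = 1.
#'
#' @param p_values Claim p-values.
#' @return List: `C`, `df`, `p_value`.
#' @export
fishers_c <- function(p_values) {
  k <- length(p_values)
  if (k == 0) return(list(C = 0, df = 0L, p_value = 1))
  p <- pmax(p_values, 1e-300)
  C <- -2 * sum(log(p))
  list(C = C, df = 2L * k,
       p_value = stats::pchisq(C, df = 2 * k, lower.tail = FALSE))
}

#' C-statistic information criterion (corrected)
#'
#' `CICc = C + 2 q n / (n - 1 - q)`, the small-sample information criterion
#' for d-separation path models.
#'
#' @param C Fisher's C.
#' @param q Parameter count of the model.
#' @param n Number of taxa.
#' @return CICc value.
#' @export
cicc <- function(C, q, n) {
  if (n <= q + 1) stop("CICc undefined for n <= q + 1")
  C + 2 * q * n / (n - 1 - q)
}

# Parameter count for CICc: directed edges + nodes (the convention of
# phylopath-style implementations), or edges only.
path_q <- function(model, q_method = c("edges_plus_nodes", "edges")) {
  q_method <- match.arg(q_method)
  nrow(model$edges) + if (q_method == "edges_plus_nodes") {
    length(model$nodes)
  } else 0L
}

#' Standardized path coefficients of a DAG
#'
#' Z-scores every variable on the analysis taxon set, then fits one
#' Brownian-motion PGLS per node with parents (node on all its parents); each
#' edge's coefficient is that parent's slope.
#'
#' @inheritParams test_claim
#' @param model A [path_model()].
#' @return Data frame: `from`, `to`, `estimate`, `se`.
#' @export
fit_path_coefficients <- function(model, data, tree, cov = NULL) {
  data <- data[tree$tip.label, model$nodes, drop = FALSE]
  data <- as.data.frame(scale(data))
  if (is.null(cov)) cov <- bm_covariance(tree)
  out <- data.frame(from = character(0), to = character(0),
                    estimate = numeric(0), se = numeric(0),
                    stringsAsFactors = FALSE)
  for (node in model$nodes) {
    pa <- parents_of(model, node)
    if (length(pa) == 0) next
    X <- cbind(1, as.matrix(data[, pa, drop = FALSE]))
    fit <- gls_fit(data[[node]], X, cov)
    for (i in seq_along(pa)) {
      out <- rbind(out, data.frame(from = pa[i], to = node,
                                   estimate = fit$beta[i + 1],
                                   se = fit$se[i + 1],
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Fit, rank and select candidate path models
#'
#' Fits every candidate on the common complete-case taxon set (so CICc values
#' are comparable), computes each model's d-separation claims, Fisher's C and
#' CICc, and ranks ascending by CICc with ties broken by fewer edges, then by
#' name.
#'
#' @param models List of [path_model()] objects (at least 2).
#' @param data Data frame of variables, rows named by taxon.
#' @param tree Tree containing the data taxa.
#' @param q_method `"edges_plus_nodes"` (default) or `"edges"`.
#' @param coefficients `"best"` (fit path coefficients for the winning model
#'   only), `"all"`, or `"none"`.
#' @return List of class `path_ranking`: `fits` (ranked list, each with
#'   `model`, `claims`, `p_values`, `C`, `df`, `model_p`, `q`, `CICc`,
#'   `coefficients`), `table` (summary data frame), `best`.
#' @export
rank_and_select <- function(models, data, tree,
                            q_method = "edges_plus_nodes",
                            coefficients = c("best", "all", "none")) {
  coefficients <- match.arg(coefficients)
  if (length(models) < 2) stop("need at least 2 candidate models")
  all_vars <- sort(unique(unlist(lapply(models, function(m) m$nodes))))
  if (!all(all_vars %in% colnames(data))) {
    stop("variables absent from data: ",
         paste(setdiff(all_vars, colnames(data)), collapse = ", "))
  }
  cc <- rownames(data)[stats::complete.cases(data[, all_vars, drop = FALSE])]
  taxa <- intersect(tree$tip.label, cc)
  if (length(taxa) < 5) stop("fewer than 5 complete-case taxa shared with tree")
  tree <- prune_to_taxa(tree, taxa)
  data <- data[tree$tip.label, , drop = FALSE]
  n <- length(taxa)
  cov <- bm_covariance(tree)

  fits <- lapply(models, function(m) {
    claims <- basis_set(m)
    p_values <- vapply(claims, test_claim, numeric(1), data = data,
                       tree = tree, cov = cov)
    fc <- fishers_c(p_values)
    q <- path_q(m, q_method)
    list(model = m, claims = claims, p_values = p_values, C = fc$C,
         df = fc$df, model_p = fc$p_value, q = q, CICc = cicc(fc$C, q, n),
         n = n, coefficients = NULL)
  })

  ord <- order(vapply(fits, `[[`, numeric(1), "CICc"),
               vapply(fits, function(f) nrow(f$model$edges), numeric(1)),
               vapply(fits, function(f) f$model$name, character(1)))
  fits <- fits[ord]

  if (coefficients == "all") {
    fits <- lapply(fits, function(f) {
      f$coefficients <- fit_path_coefficients(f$model, data, tree, cov)
      f
    })
  } else if (coefficients == "best") {
    fits[[1]]$coefficients <- fit_path_coefficients(fits[[1]]$model, data,
                                                    tree, cov)
  }

  tab <- data.frame(
    model = vapply(fits, function(f) f$model$name, character(1)),
    k_claims = vapply(fits, function(f) length(f$claims), numeric(1)),
    C = vapply(fits, `[[`, numeric(1), "C"),
    df = vapply(fits, function(f) as.numeric(f$df), numeric(1)),
    p = vapply(fits, `[[`, numeric(1), "model_p"),
    q = vapply(fits, function(f) as.numeric(f$q), numeric(1)),
    CICc = vapply(fits, `[[`, numeric(1), "CICc"),
    stringsAsFactors = FALSE
  )
  tab$delta_CICc <- tab$CICc - min(tab$CICc)
  structure(list(fits = fits, table = tab, best = fits[[1]], n = n),
            class = "path_ranking")
}

#' @export
print.path_ranking <- function(x, ...) {
  cat("Phylogenetic path analysis over", nrow(x$table), "candidate models,",
      "n =", x$n, "taxa\n")
  print(x$table, digits = 4)
  cat("Best model:", x$best$model$name, "\n")
  invisible(x)
}

#' Default candidate path models
#'
#' Five DAGs over woodiness (W), perenniality (P) and hybridization (H):
#' \itemize{
#'   \item m1: W -> P -> H (woodiness acts only through perenniality)
#'   \item m2: P -> W -> H (perenniality acts only through woodiness)
#'   \item m3: W -> P -> H plus W -> H
#'   \item m4: P -> W -> H plus P -> H
#'   \item m5: W -> H and P -> H with W -> P
#' }
#'
#' @param nodes Character vector of length 3 naming the woodiness,
#'   perenniality and hybridization variables, in that order.
#' @return List of five [path_model()] objects.
#' @export
default_candidate_set <- function(nodes = c("woodiness", "perenniality",
                                            "hybridization")) {
  W <- nodes[1]; P <- nodes[2]; H <- nodes[3]
  list(
    path_model("m1", rbind(c(W, P), c(P, H)), nodes = nodes),
    path_model("m2", rbind(c(P, W), c(W, H)), nodes = nodes),
    path_model("m3", rbind(c(W, P), c(P, H), c(W, H)), nodes = nodes),
    path_model("m4", rbind(c(P, W), c(W, H), c(P, H)), nodes = nodes),
    path_model("m5", rbind(c(W, H), c(P, H), c(W, P)), nodes = nodes)
  )
}
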