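#' Neighbour-joining tree from a distance matrix
#'
#' Standard agglomerative neighbour joining: repeatedly join the pair
#' minimizing the rate-corrected Q criterion
#' \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j}, assign branch lengths from the
#' three-point equations, and reduce the matrix. NJ is exact on additive
#' distances: it recovers the generating tree's topology and branch
#' lengths. Q ties are broken toward the lexicographically smallest label
#' pair so the result is deterministic. Negative branch-length estimates
#' are clamped to zero and the clamped deficit recorded in the
#' `"clamped"` attribute of the returned tree.
#'
#' @param matrix A `pairwise_dist` from [pairwise_matrix()] or a symmetric
#'   numeric matrix with dimnames.
#' @return An unrooted `phylo` tree (ape) with a trifurcating root node.
#' @export
neighbor_joining <- function(matrix) {
  D <- if (inherits(matrix, "pairwise_dist")) matrix$d else as.matrix(matrix)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(D))) stop("distance matrix must have labels")
  if (anyNA(D)) {
    bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)[1L, ]
    stop("distance matrix has undefined (saturated) cells, e.g. (",
         rownames(D)[bad[1L]], ", ", colnames(D)[bad[2L]],
         "); exclude or impute those pairs upstream")
  }
  if (!isTRUE(all.equal(D, t(D)))) stop("distance matrix must be symmetric")

  tips <- rownames(D)
  active <- seq_len(n)                 # current node ids
  # tie-break key: smallest leaf label in each active subtree
  key <- tips
  next_node <- n + 1L
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  clamped <- 0

  add_edge <- function(parent, child, len) {
    if (len < 0) { clamped <<- clamped + (-len); len <- 0 }
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, len)
  }

  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      ck <- apply(cand, 1L, function(ij) {
        k <- sort(c(key[ij[1L]], key[ij[2L]]))
        paste(k, collapse = "\r")
      })
      cand <- cand[order(ck), , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    u <- next_node; next_node <- next_node + 1L
    add_edge(u, active[i], bi)
    add_edge(u, active[j], bj)
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    D <- D2
    new_key <- min(key[c(i, j)])
    active <- c(active[keep], u)
    key <- c(key[keep], new_key)
    rownames(D) <- colnames(D) <- key
  }
  # final trifurcation: three-point equations
  f <- next_node
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  add_edge(f, active[1L], b1)
  add_edge(f, active[2L], b2)
  add_edge(f, active[3L], b3)

  # renumber: tips 1..n unchanged; internal nodes n+1..2n-2 with the
  # trifurcating root first (ape convention: root = n+1)
  internal <- c(f, setdiff(sort(unique(as.vector(edges[edges > n]))), f))
  map <- integer(max(internal))
  map[internal] <- n + seq_along(internal)
  renum <- edges
  renum[renum > n] <- map[renum[renum > n]]
  tr <- structure(list(edge = renum, edge.length = lens,
                       tip.label = tips, Nnode = length(internal)),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, order = "cladewise")
  attr(tr, "clamped") <- clamped
  tr
}

#' Test whether each species forms a cluster on a tree
#'
#' A species "clusters" when some edge of the unrooted tree separates
#' exactly that species' specimens from all other leaves, i.e. its tip set
#' is one side of a bipartition. Singleton species cluster trivially via
#' their pendant edge.
#'
#' @param tree A `phylo` tree with specimen-id tip labels.
#' @param taxonomy Taxonomy data.frame covering all tip labels.
#' @return data.frame with `species`, `n_specimens`, `is_cluster`.
#' @export
species_clusters <- function(tree, taxonomy) {
  stopifnot(inherits(tree, "phylo"))
  taxonomy <- validate_taxonomy(taxonomy)
  idx <- match(tree$tip.label, taxonomy$specimen_id)
  if (anyNA(idx)) {
    stop("tip label(s) absent from taxonomy: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  sp <- taxonomy$species[idx]
  ntip <- length(tree$tip.label)
  # every clade of the (arbitrarily rooted) representation; bipartitions
  # are each clade and its complement
  parts <- ape::prop.part(tree)
  clade_keys <- vapply(parts, function(p) paste(sort(p), collapse = ","),
                       character(1))
  all_tips <- seq_len(ntip)
  comp_keys <- vapply(parts, function(p)
    paste(sort(setdiff(all_tips, p)), collapse = ","), character(1))
  bipart <- unique(c(clade_keys, comp_keys))
  res <- do.call(rbind, lapply(sort(unique(sp)), function(s) {
    tip_set <- which(sp == s)
    is_cl <- length(tip_set) == 1L || length(tip_set) == ntip ||
      paste(sort(tip_set), collapse = ",") %in% bipart
    data.frame(species = s, n_specimens = length(tip_set),
               is_cluster = is_cl, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Write / read a tree in newick format
#'
#' Thin wrappers over ape's newick I/O; the round trip preserves topology
#' and branch lengths well beyond 6 decimals.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `write_newick` returns `path` invisibly; `read_newick` returns
#'   a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- cumsum(ifelse(strsplit(txt, "")[[1L]] == "(", 1L,
                  ifelse(strsplit(txt, "")[[1L]] == ")", -1L, 0L)))
  if (length(depth) && (any(depth < 0L) || utils::tail(depth, 1L) != 0L)) {
    pos <- if (any(depth < 0L)) which(depth < 0L)[1L] else nchar(txt)
    stop("malformed newick: unbalanced parenthesis at character ", pos)
  }
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: no tree in file")
  tr
}
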