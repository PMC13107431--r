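#' Convert structural similarity scores to evolutionary distances
#'
#' Applies the score-to-distance rule
#' `D(A, B) = min(S(A, A), S(B, B)) - S(A, B)`: the distance is the score
#' deficit of the pair relative to the best attainable score of its less
#' self-similar member. Self-score dominance (`S(A, B) <= min` of the
#' self-scores) makes every distance non-negative; a violation beyond
#' numerical noise is an error naming the offending pair.
#'
#' @param scores A `score_matrix` (from [build_core] or
#'   [restrict_scores]), or a plain symmetric numeric matrix with
#'   self-scores on the diagonal.
#' @return Symmetric non-negative distance matrix with zero diagonal and
#'   the model ids as dimnames.
#' @export
score_to_distance <- function(scores) {
  S <- if (inherits(scores, "score_matrix")) scores$S else as.matrix(scores)
  if (is.null(rownames(S))) rownames(S) <- colnames(S) <-
      paste0("m", seq_len(nrow(S)))
  self <- diag(S)
  n <- nrow(S)
  D <- outer(self, self, pmin) - S
  diag(D) <- 0
  bad <- which(D < -1e-9, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("self-score dominance violated for pair ",
         rownames(S)[bad[1, 1]], " / ", colnames(S)[bad[1, 2]],
         " (negative distance ", format(D[bad[1, , drop = FALSE]]), ")")
  D[D < 0] <- 0  # clip numerical noise
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical agglomerative neighbor joining (Saitou-Nei, with the
#' Studier-Keppler Q-criterion), which recovers the true tree exactly on
#' additive distance matrices. Negative branch lengths are clamped to
#' zero and the clamped deficit is reported via a message.
#'
#' @param D Symmetric distance matrix with labels as dimnames, n >= 3.
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")

  node_id <- seq_len(n)          # active cluster -> tree node id
  next_node <- n + 1L
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  clamped <- 0
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    if (len < 0) { clamped <<- clamped - len; len <- 0 }
    lens <<- c(lens, len)
  }

  while (length(node_id) > 3L) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    k <- which(Q == min(Q), arr.ind = TRUE)
    i <- k[1, 1]; j <- k[1, 2]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    u <- next_node; next_node <- next_node + 1L
    add_edge(u, node_id[i], li)
    add_edge(u, node_id[j], lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D <- rbind(cbind(D[-c(i, j), -c(i, j), drop = FALSE],
                     du[-c(i, j)]),
               c(du[-c(i, j)], 0))
    node_id <- c(node_id[-c(i, j)], u)
  }
  # resolve the final three clusters around one central node
  u <- next_node; next_node <- next_node + 1L
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  add_edge(u, node_id[1], l1)
  add_edge(u, node_id[2], l2)
  add_edge(u, node_id[3], l3)
  if (clamped > 0)
    message(sprintf("neighbor_joining: clamped %.4g of negative branch length",
                    clamped))

  build_phylo(n, labels, edges, lens, root = u)
}

# assemble an ape phylo object from an edge list rooted at 'root',
# renumbering internal nodes in preorder as ape requires
build_phylo <- function(ntip, labels, edges, lens, root) {
  children <- split(seq_len(nrow(edges)), edges[, 1])
  new_id <- integer(max(edges))
  new_id[seq_len(ntip)] <- seq_len(ntip)
  counter <- ntip
  out_e <- matrix(0L, 0, 2); out_l <- numeric(0)
  # iterative preorder over internal nodes
  assign_id <- function(node) {
    counter <<- counter + 1L
    new_id[node] <<- counter
  }
  assign_id(root)
  stack <- list(root)
  ord <- list()
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (ei in children[[as.character(node)]]) {
      ch <- edges[ei, 2]
      if (ch > ntip) assign_id(ch)
      ord[[length(ord) + 1L]] <- c(node, ch, ei)
      if (ch > ntip) stack[[length(stack) + 1L]] <- ch
    }
  }
  for (rec in ord) {
    out_e <- rbind(out_e, c(new_id[rec[1]], new_id[rec[2]]))
    out_l <- c(out_l, lens[rec[3]])
  }
  tr <- list(edge = out_e, edge.length = out_l, tip.label = labels,
             Nnode = counter - ntip)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' Root a tree with an outgroup
#'
#' Places the root on the edge separating the outgroup leaves from all
#' other leaves. The outgroup must form one side of an edge of the
#' unrooted tree; otherwise the violating leaves are reported. Support
#' labels are carried as edge labels so they stay attached to the correct
#' bipartitions.
#'
#' @param tree A `phylo` tree.
#' @param outgroup Character vector of leaf labels.
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  outgroup <- as.character(outgroup)
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("outgroup leaves not in tree: ", paste(missing, collapse = ", "))
  if (length(outgroup) > 1L && length(outgroup) < ape::Ntip(tree) - 1L) {
    splits <- bipartitions(tree)
    key <- canonical_split(outgroup, tree$tip.label)
    if (!key %in% splits)
      stop("outgroup {", paste(sort(outgroup), collapse = ", "),
           "} is not separable by a single edge of the tree")
  }
  if (length(outgroup) >= ape::Ntip(tree))
    stop("outgroup cannot contain every leaf")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
            edgelabel = TRUE)
}

# canonical string encoding of the bipartition induced by a leaf subset:
# use the side NOT containing the alphabetically first leaf
canonical_split <- function(side, all_labels) {
  ref <- sort(all_labels)[1]
  side <- sort(side)
  other <- sort(setdiff(all_labels, side))
  chosen <- if (ref %in% side) other else side
  paste(chosen, collapse = "\r")
}

# non-trivial bipartitions of an unrooted tree as canonical strings
bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- ape::Ntip(tree)
  labs <- tree$tip.label
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- labs[i]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  root <- ntip + 1L
  out <- character(0)
  for (e in seq_len(nrow(post$edge))) {
    ch <- post$edge[e, 2]
    if (ch <= ntip || ch == root) next
    side <- below[[ch]]
    if (length(side) >= 2L && length(side) <= ntip - 2L)
      out <- c(out, canonical_split(side, labs))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the non-trivial bipartitions present in exactly one of the two
#' trees. With `normalized = TRUE` the count is divided by the maximum
#' attainable value — the total number of non-trivial bipartitions in the
#' two trees (2(n-3) for two fully resolved trees) — giving a value in
#' `[0, 1]`. Multifurcating trees contribute only the bipartitions they
#' actually contain.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @param normalized Divide by the maximum attainable RF (default `TRUE`).
#' @return Numeric distance.
#' @export
rf_distance <- function(t1, t2, normalized = TRUE) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (!normalized) return(rf)
  denom <- length(b1) + length(b2)
  if (denom == 0L) return(0)
  rf / denom
}

#' Map replicate support onto a reference tree
#'
#' For each internal edge of `reference`, support is the percentage of
#' replicate trees whose bipartition set contains that edge's
#' bipartition, rounded to the nearest integer. Topology and branch
#' lengths of the reference are unchanged; supports are stored as
#' internal node labels (the standard Newick support dialect).
#'
#' @param reference A `phylo` tree.
#' @param replicates List of `phylo` trees over the same leaf set.
#' @return The reference tree with `node.label` holding supports.
#' @export
map_support <- function(reference, replicates) {
  stopifnot(inherits(reference, "phylo"))
  for (k in seq_along(replicates)) {
    r <- replicates[[k]]
    if (!inherits(r, "phylo") || !setequal(r$tip.label, reference$tip.label))
      stop("replicate ", k, " does not share the reference leaf set")
  }
  rep_sets <- lapply(replicates, bipartitions)
  ntip <- ape::Ntip(reference)
  labs <- reference$tip.label
  # leaf set below each internal node of the reference as in bipartitions()
  post <- ape::reorder.phylo(reference, "postorder")
  below <- vector("list", ntip + reference$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- labs[i]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  node_label <- rep("", reference$Nnode)
  for (node in (ntip + 1L):(ntip + reference$Nnode)) {
    side <- below[[node]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    key <- canonical_split(side, labs)
    if (length(rep_sets) == 0L) next
    frac <- mean(vapply(rep_sets, function(s) key %in% s, logical(1)))
    node_label[node - ntip] <- as.character(round(100 * frac))
  }
  reference$node.label <- node_label
  reference
}

#' Read trees from a Newick file
#'
#' Standard Newick with branch lengths; internal node labels are read as
#' support values (the `-sup`-style dialect). Returns a list of trees
#' even for a single-tree file.
#'
#' @param path Newick file (one or more semicolon-terminated trees).
#' @return List of `phylo` trees.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  check_newick_syntax(txt, path)
  trees <- ape::read.tree(text = txt)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(trees) || length(trees) == 0L)
    stop("no trees parsed from '", path, "'")
  unclass(trees)
}

check_newick_syntax <- function(txt, src = "<text>") {
  depth <- 0
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") depth <- depth - 1
    if (depth < 0)
      stop("malformed Newick in '", src, "': unmatched ')' at character ", i)
  }
  if (depth != 0)
    stop("malformed Newick in '", src, "': ", depth, " unclosed '('")
  if (!grepl(";", txt))
    stop("malformed Newick in '", src, "': missing terminating ';'")
  invisible(TRUE)
}

#' Write trees to a Newick file
#' @param trees A `phylo` tree or list of trees.
#' @param path Output file.
#' @param digits Significant digits for branch lengths (default 10).
#' @return `path`, invisibly.
#' @export
write_newick <- function(trees, path, digits = 10) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, function(tr)
    ape::write.tree(tr, digits = digits), character(1))
  writeLines(txt, path)
  invisible(path)
}
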