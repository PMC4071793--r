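# Distance phylogenetics: Poisson-corrected amino-acid distances,
# neighbor joining with explicit tie-breaking and branch-length clamping,
# bootstrap supports, Newick output.  Trees are ape "phylo" objects.

#' Pairwise evolutionary distance matrix
#'
#' Computes p-distances or Poisson-corrected distances
#' (d = -ln(1 - p), expected substitutions per site) between all rows of an
#' alignment.  Ambiguous positions (gaps and X) are removed per sequence
#' pair (`deletion = "pairwise"`) or from all rows at once
#' (`deletion = "complete"`).
#'
#' @param msa an `aa_alignment` with at least 3 rows
#' @param model `"poisson"` (default) or `"p"`
#' @param deletion `"pairwise"` (default) or `"complete"`
#' @return symmetric numeric matrix with taxa ids as dimnames.
#' @export
pairwise_distance_matrix <- function(msa, model = c("poisson", "p"),
                                     deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  mat <- msa$mat
  n <- nrow(mat)
  if (n < 3) stop("at least 3 sequences required")
  ambiguous <- mat == "-" | mat == "X" | mat == "."
  if (deletion == "complete") {
    keep <- colSums(ambiguous) == 0
    if (!any(keep)) stop("no unambiguous columns under complete deletion")
    mat <- mat[, keep, drop = FALSE]
    ambiguous <- ambiguous[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      usable <- !ambiguous[i, ] & !ambiguous[j, ]
      nu <- sum(usable)
      if (nu == 0) stop("zero usable sites for pair ", rownames(mat)[i],
                        "/", rownames(mat)[j])
      p <- sum(mat[i, usable] != mat[j, usable]) / nu
      if (model == "poisson") {
        if (p >= 1) stop("p-distance of 1 for pair ", rownames(mat)[i], "/",
                         rownames(mat)[j], ": Poisson correction undefined")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining on a symmetric distance matrix using the
#' Q-criterion; ties in Q are broken by the smallest (i, j) index pair, and
#' negative branch lengths are clamped to zero with the deficit moved to
#' the sister branch, so the tree is unique and its leaf-to-leaf path
#' lengths are preserved.  Exact (topology and branch lengths) on additive
#' matrices.
#'
#' @param dm symmetric distance matrix with taxa ids as dimnames (>= 3 taxa)
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(dm)
  if (n < 3) stop("at least 3 taxa required")
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  frag <- ids            # Newick fragment per active node
  D <- dm
  active <- seq_len(n)
  while (length(active) > 3) {
    m <- length(active)
    Da <- D[active, active]
    r <- rowSums(Da)
    Q <- (m - 2) * Da - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    li <- Da[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Da[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    ai <- active[i]; aj <- active[j]
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[ai], li, frag[aj], lj)
    du <- (Da[i, ] + Da[j, ] - Da[i, j]) / 2
    # reuse slot ai for the new node
    D[ai, active] <- du; D[active, ai] <- du; D[ai, ai] <- 0
    frag[ai] <- newfrag
    active <- active[-j]
    active[active == ai] <- ai
  }
  a <- active
  Da <- D[a, a]
  l1 <- (Da[1, 2] + Da[1, 3] - Da[2, 3]) / 2
  l2 <- (Da[1, 2] + Da[2, 3] - Da[1, 3]) / 2
  l3 <- (Da[1, 3] + Da[2, 3] - Da[1, 2]) / 2
  ls <- pmax(c(l1, l2, l3), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[a[1]], ls[1], frag[a[2]], ls[2], frag[a[3]], ls[3])
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' NJ tree per replicate, and annotates each internal branch of the
#' full-data NJ tree with the fraction of replicate trees containing the
#' same bipartition (scale 0-1, stored as node labels).  Deterministic for
#' a given seed.
#'
#' @param msa an `aa_alignment`
#' @param n_reps bootstrap replicates (default 500)
#' @param seed RNG seed
#' @param model,deletion passed to [pairwise_distance_matrix()]
#' @return a `phylo` tree with `node.label` = supports in `[0,1]` (root
#'   label empty).
#' @export
bootstrap_support <- function(msa, n_reps = 500L, seed = 1L,
                              model = "poisson", deletion = "pairwise") {
  if (n_reps < 1) stop("n_reps must be at least 1")
  full <- neighbor_joining(pairwise_distance_matrix(msa, model, deletion))
  L <- ncol(msa$mat)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    sub <- new_alignment(msa$mat[, cols, drop = FALSE])
    trees[[r]] <- neighbor_joining(pairwise_distance_matrix(sub, model, deletion))
  }
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(full, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  sup <- counts / n_reps
  lab <- formatC(sup, format = "g")
  lab[1] <- ""   # root of the unrooted representation carries no split
  full$node.label <- lab
  attr(full, "supports") <- sup
  full
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with 6 significant digits; node labels
#' (bootstrap supports) appear after the closing parentheses.  Labels
#' containing Newick metacharacters are quoted.
#'
#' @param tree a `phylo`
#' @param path optional output file
#' @return the Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  meta <- grepl("[(),:;\\[\\] ]", tree$tip.label)
  tree$tip.label[meta] <- paste0("'", tree$tip.label[meta], "'")
  txt <- ape::write.tree(tree, digits = 6)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Distance matrix as TSV text (square, with header row and column)
#' @param dm distance matrix
#' @param path optional output file
#' @export
write_distance_tsv <- function(dm, path = NULL) {
  dm <- as.matrix(dm)
  lines <- c(paste(c("", colnames(dm)), collapse = "\t"),
             vapply(seq_len(nrow(dm)), function(i)
               paste(c(rownames(dm)[i], format(dm[i, ], digits = 6)),
                     collapse = "\t"), ""))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

# Unrooted bipartitions of a phylo tree as a canonical character set
# (used for topology comparison in tests and reports).
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  splits <- character(0)
  for (p in pp) {
    side <- sort(labs[p])
    other <- setdiff(tips, side)
    if (length(side) < 2 || length(other) < 2) next
    canon <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      side else other
    splits <- c(splits, paste(canon, collapse = ","))
  }
  unique(splits)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Counts bipartitions present in exactly one of the two trees.
#'
#' @param tree_a,tree_b `phylo` trees on the same taxa
#' @export
robinson_foulds <- function(tree_a, tree_b) {
  sa <- tree_bipartitions(tree_a)
  sb <- tree_bipartitions(tree_b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}
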