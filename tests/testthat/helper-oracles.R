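# Independent oracles used across the suite. These deliberately share no
# code with the package: a brute-force affine-gap Smith-Waterman DP, and
# an exhaustive-topology least-squares tree fitter.

# Brute-force Smith-Waterman with affine gaps (gap of length k costs
# open + k * ext), BLOSUM62. Returns the optimal local score.
sw_oracle <- function(a, b, open = 11, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  M <- matrix(0, n + 1, m + 1)   # match/mismatch state
  Ix <- matrix(-Inf, n + 1, m + 1) # gap in y (consume x)
  Iy <- matrix(-Inf, n + 1, m + 1) # gap in x (consume y)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[x[i], y[j]]
      M[i + 1, j + 1] <- max(0,
                             M[i, j] + s,
                             Ix[i, j] + s,
                             Iy[i, j] + s)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              Iy[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Tips below each edge's child node, as a logical incidence matrix
# (edges x tips).
.edge_tip_sets <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- max(phy$edge)
  below <- vector("list", n_node)
  for (t in seq_len(n_tip)) below[[t]] <- t
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]
    ch <- po$edge[k, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  t(vapply(seq_len(nrow(phy$edge)), function(k) {
    seq_len(n_tip) %in% below[[phy$edge[k, 2]]]
  }, logical(n_tip)))
}

# Ordinary least-squares branch lengths for a fixed topology against a
# distance matrix; returns the fit and residual sum of squares.
ls_fit_topology <- function(phy, D) {
  taxa <- rownames(D)
  tip_idx <- match(phy$tip.label, taxa)
  sets <- .edge_tip_sets(phy)
  pairs <- t(utils::combn(length(taxa), 2))
  A <- matrix(0, nrow(pairs), nrow(phy$edge))
  d <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]
    j <- pairs[r, 2]
    ti <- match(i, tip_idx)
    tj <- match(j, tip_idx)
    A[r, ] <- xor(sets[, ti], sets[, tj])
    d[r] <- D[i, j]
  }
  fit <- stats::lm.fit(A, d)
  list(lengths = fit$coefficients, ssq = sum(fit$residuals^2))
}

# Exhaustive search over all unrooted binary topologies (n <= 8): the
# least-squares-optimal tree for D, with fitted branch lengths.
ls_oracle_tree <- function(D) {
  taxa <- rownames(D)
  topos <- phangorn::allTrees(length(taxa), rooted = FALSE,
                              tip.label = taxa)
  best <- NULL
  best_ssq <- Inf
  for (k in seq_along(topos)) {
    t <- topos[[k]] # [[ restores tip labels from the multiPhylo wrapper
    f <- ls_fit_topology(t, D)
    if (f$ssq < best_ssq - 1e-12) {
      best_ssq <- f$ssq
      t$edge.length <- unname(f$lengths)
      best <- t
    }
  }
  list(tree = best, ssq = best_ssq)
}

# Random additive distance matrix from a random unrooted binary tree
# with positive branch lengths; returns both.
random_additive <- function(n, seed) {
  tr <- withr::with_seed(seed, {
    t <- ape::unroot(ape::rtree(n, rooted = TRUE))
    t$edge.length <- stats::runif(nrow(t$edge), 0.05, 1)
    t
  })
  D <- ape::cophenetic.phylo(tr)
  D <- D[sort(rownames(D)), sort(rownames(D))]
  list(tree = tr, D = D)
}

# Independent adjacency recount for the synteny fraction: walks the
# feature table directly.
synteny_oracle <- function(arch, genome, ref_labels) {
  slots <- arch$slots
  present <- slots[slots$status == "PRESENT", ]
  labs <- ref_labels[ref_labels %in% present$label]
  if (length(labs) < 2) return(NA_real_)
  cluster_tags <- c(unlist(slots$locus_tags),
                    unlist(arch$insertions$locus_tags))
  f <- genome$features
  f <- f[f$locus_tag %in% cluster_tags, ]
  f <- f[order(f$contig_id, f$start), ]
  tag1 <- vapply(labs, function(lb)
    present$locus_tags[[match(lb, present$label)]][1], character(1))
  hits <- 0
  for (i in seq_len(length(labs) - 1)) {
    p1 <- which(f$locus_tag == tag1[i])
    p2 <- which(f$locus_tag == tag1[i + 1])
    if (f$contig_id[p1] != f$contig_id[p2]) next
    if (abs(p1 - p2) != 1) next
    if (f$strand[p1] != f$strand[p2]) next
    hits <- hits + 1
  }
  hits / (length(labs) - 1)
}
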