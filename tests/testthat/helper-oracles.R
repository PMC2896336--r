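# Independent oracles: plain-R reimplementations used only to check the
# engine, written directly from the definitions (no shared code with the
# implementation beyond the replayed permutation streams).

ORACLE_PARTS <- list(c(0L), c(0L, 1L), c(0L, 2L))  # left-branch sets

oracle_gini <- function(w0, w1) {
  w <- w0 + w1
  1 - (w0^2 + w1^2) / w^2
}

# exhaustive search over candidates x partitions for the best weighted
# Gini decrease; same tie rules (lower SNP, earlier partition win on ties)
oracle_best_split <- function(geno, y, rows, candidates, w = c(1, 1)) {
  yy <- y[rows]
  W0 <- sum(w[1] * (yy == 0L))
  W1 <- sum(w[2] * (yy == 1L))
  W <- W0 + W1
  if (W0 == 0 || W1 == 0) return(NULL)
  gp <- oracle_gini(W0, W1)
  best <- NULL
  for (s in sort(candidates)) {
    g <- geno[rows, s]
    for (pi in 1:3) {
      inL <- g %in% ORACLE_PARTS[[pi]]
      if (!any(inL) || all(inL)) next
      L0 <- sum(w[1] * (yy[inL] == 0L)); L1 <- sum(w[2] * (yy[inL] == 1L))
      R0 <- W0 - L0; R1 <- W1 - L1
      WL <- L0 + L1; WR <- R0 + R1
      dec <- gp - (WL * oracle_gini(L0, L1) + WR * oracle_gini(R0, R1)) / W
      if (is.null(best) || dec > best$decrease) {
        best <- list(snp = s, partition = pi, decrease = dec)
      }
    }
  }
  best
}

# exhaustive-search CART: recursive, unpruned, all SNPs candidate at every
# node; returns a nested list
oracle_cart <- function(geno, y, rows, w = c(1, 1)) {
  yy <- y[rows]
  v0 <- sum(w[1] * (yy == 0L)); v1 <- sum(w[2] * (yy == 1L))
  sp <- oracle_best_split(geno, y, rows, seq_len(ncol(geno)), w)
  if (is.null(sp)) return(list(leaf = TRUE, v0 = v0, v1 = v1))
  inL <- geno[rows, sp$snp] %in% ORACLE_PARTS[[sp$partition]]
  list(leaf = FALSE, snp = sp$snp, partition = sp$partition,
       v0 = v0, v1 = v1,
       left = oracle_cart(geno, y, rows[inL], w),
       right = oracle_cart(geno, y, rows[!inL], w))
}

# compare a package tree (flat node table, root = row 1) with the nested
# oracle tree; returns TRUE or a description of the first mismatch
trees_identical <- function(tree, oracle, node = 1) {
  nd <- tree$nodes
  if (oracle$leaf) {
    if (!is.na(nd[node, "split_snp"])) {
      return(sprintf("node %d: expected leaf, found split", node))
    }
    if (abs(tree$votes[node, 1] - oracle$v0) > 1e-9 ||
        abs(tree$votes[node, 2] - oracle$v1) > 1e-9) {
      return(sprintf("node %d: vote mismatch", node))
    }
    return(TRUE)
  }
  if (is.na(nd[node, "split_snp"])) {
    return(sprintf("node %d: expected split on %d, found leaf", node,
                   oracle$snp))
  }
  if (nd[node, "split_snp"] != oracle$snp ||
      nd[node, "partition"] != oracle$partition) {
    return(sprintf("node %d: split (%d,%d) vs oracle (%d,%d)", node,
                   nd[node, "split_snp"], nd[node, "partition"],
                   oracle$snp, oracle$partition))
  }
  left <- trees_identical(tree, oracle$left, nd[node, "left"])
  if (!isTRUE(left)) return(left)
  trees_identical(tree, oracle$right, nd[node, "right"])
}

# drop one sample down a package tree (optionally reading SNP `perm_snp`
# from another row); returns the terminal's class vote
walk_tree_class <- function(tree, geno, i, perm_snp = NA, perm_row = NA) {
  nd <- tree$nodes
  node <- 1
  repeat {
    s <- nd[node, "split_snp"]
    if (is.na(s)) break
    src <- if (!is.na(perm_snp) && s == perm_snp) perm_row else i
    g <- geno[src, s]
    inL <- g %in% ORACLE_PARTS[[nd[node, "partition"]]]
    node <- if (inL) nd[node, "left"] else nd[node, "right"]
  }
  as.integer(tree$votes[node, 2] > tree$votes[node, 1])
}

# brute-force unwindowed LD pruning: repeatedly remove the SNP with the
# largest lm()-based multiple R2 above the threshold (ties: higher index)
oracle_ld_prune <- function(geno, threshold) {
  act <- seq_len(ncol(geno))
  repeat {
    if (length(act) < 2) break
    r2 <- vapply(seq_along(act), function(k) {
      y <- geno[, act[k]]
      if (stats::var(y) == 0) return(0)
      fit <- stats::lm(y ~ geno[, act[-k], drop = FALSE])
      suppressWarnings(summary(fit)$r.squared)
    }, numeric(1))
    over <- which(r2 > threshold)
    if (length(over) == 0) break
    worst <- over[r2[over] == max(r2[over])]
    act <- act[-worst[length(worst)]]
  }
  act
}
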