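# Gain-ratio categorical decision tree over window positions, with
# reduced-error pruning on a held-out slice of the training data.

entropy2 <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# idx: training row indices at this node
grow_tree_node <- function(enc, lab, idx, depth, max_depth, min_split) {
  npos <- sum(lab[idx] == 1L)
  nneg <- length(idx) - npos
  node <- list(n_pos = npos, n_neg = nneg,
               score = (npos - nneg) / max(1L, npos + nneg))
  if (npos == 0L || nneg == 0L || length(idx) < min_split ||
      depth >= max_depth) {
    node$leaf <- TRUE
    return(node)
  }
  parent_h <- entropy2(c(npos, nneg))
  best <- list(ratio = 0, pos = NA_integer_)
  for (j in seq_len(ncol(enc))) {
    v <- enc[idx, j]
    vals <- unique(v)
    if (length(vals) < 2L) next
    child_h <- 0
    split_counts <- integer(0)
    for (val in vals) {
      sub <- lab[idx][v == val]
      nv <- length(sub)
      split_counts <- c(split_counts, nv)
      child_h <- child_h + nv / length(idx) *
        entropy2(c(sum(sub == 1L), sum(sub == -1L)))
    }
    gain <- parent_h - child_h
    si <- entropy2(split_counts)
    if (gain > 1e-10 && si > 0) {
      ratio <- gain / si
      if (ratio > best$ratio + 1e-12) best <- list(ratio = ratio, pos = j)
    }
  }
  if (is.na(best$pos)) {
    node$leaf <- TRUE
    return(node)
  }
  node$leaf <- FALSE
  node$split_pos <- best$pos
  v <- enc[idx, best$pos]
  node$children <- list()
  for (val in sort(unique(v))) {
    node$children[[as.character(val)]] <-
      grow_tree_node(enc, lab, idx[v == val], depth + 1L, max_depth,
                     min_split)
  }
  node
}

# route each row of enc to its leaf score under `node`
tree_node_score <- function(node, enc, idx) {
  out <- numeric(length(idx))
  if (isTRUE(node$leaf) || !length(idx)) {
    out[] <- node$score
    return(out)
  }
  v <- enc[idx, node$split_pos]
  handled <- rep(FALSE, length(idx))
  for (key in names(node$children)) {
    sel <- v == as.integer(key)
    if (any(sel)) {
      out[sel] <- tree_node_score(node$children[[key]], enc, idx[sel])
      handled[sel] <- TRUE
    }
  }
  # unseen branch values fall back to this node's own class distribution
  out[!handled] <- node$score
  out
}

# reduced-error pruning: collapse any internal node whose replacement by a
# leaf does not increase held-out error
prune_node <- function(node, enc, lab, idx) {
  if (isTRUE(node$leaf)) return(node)
  v <- if (length(idx)) enc[idx, node$split_pos] else integer(0)
  for (key in names(node$children)) {
    sel <- if (length(idx)) v == as.integer(key) else logical(0)
    node$children[[key]] <- prune_node(node$children[[key]], enc, lab,
                                       idx[sel])
  }
  if (!length(idx)) {  # no hold-out evidence reaches this node: collapse
    node$leaf <- TRUE
    node$split_pos <- NULL
    node$children <- NULL
    return(node)
  }
  sub_dec <- ifelse(tree_node_score(node, enc, idx) > 0, 1L, -1L)
  leaf_dec <- rep(ifelse(node$score > 0, 1L, -1L), length(idx))
  err_sub <- sum(sub_dec != lab[idx])
  err_leaf <- sum(leaf_dec != lab[idx])
  if (err_leaf <= err_sub) {
    node$leaf <- TRUE
    node$split_pos <- NULL
    node$children <- NULL
  }
  node
}

fit_gain_ratio_tree <- function(data, prune_frac = 0.2, max_depth = 12L,
                                min_split = 4L, seed = 1L) {
  cand <- data$candidates
  enc <- encode_windows(cand$window_seq)
  lab <- cand$label
  n <- nrow(enc)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, 7L))
  if (prune_frac > 0 && n >= 10L) {
    # stratified hold-out for pruning
    hold <- c(sample(which(lab == 1L),
                     max(1L, round(prune_frac * sum(lab == 1L)))),
              sample(which(lab == -1L),
                     max(1L, round(prune_frac * sum(lab == -1L)))))
    grow <- setdiff(seq_len(n), hold)
  } else {
    hold <- integer(0)
    grow <- seq_len(n)
  }
  root <- grow_tree_node(enc, lab, grow, 0L, max_depth, min_split)
  if (length(hold)) root <- prune_node(root, enc, lab, hold)
  structure(list(root = root, prune_frac = prune_frac), class = "tree_scorer")
}

#' @export
raw_score.tree_scorer <- function(scorer, windows) {
  enc <- encode_windows(windows)
  tree_node_score(scorer$root, enc, seq_len(nrow(enc)))
}
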