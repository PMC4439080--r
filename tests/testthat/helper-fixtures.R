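# Shared fixture builders (all data generated in code).

toy_alignment <- function(seqs, columns = NULL) {
  aligned_seqs(seqs, columns = columns)
}

make_hap_table <- function(seqs, counts = rep(1L, length(seqs)),
                           columns = seq_len(nchar(seqs[1]))) {
  n <- length(seqs)
  labels <- sprintf("H%02d", seq_len(n))
  members <- lapply(seq_len(n), function(i)
    sprintf("%s_m%d", labels[i], seq_len(counts[i])))
  structure(list(
    haplotypes = data.frame(label = labels, sequence = seqs,
                            count = as.integer(counts),
                            stringsAsFactors = FALSE),
    members = stats::setNames(members, labels),
    columns = as.integer(columns)
  ), class = "haplotype_table")
}

make_metadata <- function(n, period = "Medieval", date_early = 1300,
                          date_late = 1300, age_bp = NA, sex = "unknown") {
  data.frame(id = sprintf("s%02d", seq_len(n)), site = "site1",
             region = "region1", period = period,
             date_early = date_early, date_late = date_late,
             age_bp = age_bp, sex = sex, stringsAsFactors = FALSE)
}

random_haplotypes <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  repeat {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(alphabet, len, replace = TRUE), collapse = ""), "")
    if (!anyDuplicated(seqs)) return(seqs)
  }
}

# printed Table-2-style 3x10 modern-panel counts used in several tests
modern_region_counts <- function() {
  m <- rbind(
    common    = c(31, 23, 93, 334, 8, 13, 16, 4, 12, 14),
    ancient   = c(10, 27, 17, 51, 7, 2, 9, 1, 10, 2),
    not_found = c(8, 31, 134, 1152, 35, 11, 1, 20, 10, 8))
  colnames(m) <- paste0("r", 1:10)
  m
}

# enumerate every minimum spanning tree of a complete weighted graph
# (brute force over edge subsets; oracle for small instances)
enumerate_msts <- function(d) {
  n <- nrow(d)
  pairs <- t(combn(n, 2))
  w <- d[pairs]
  subsets <- combn(nrow(pairs), n - 1)
  is_spanning_tree <- function(idx) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (e in idx) {
      a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
      if (a == b) return(FALSE)  # cycle => with n-1 edges, not spanning
      parent[a] <- b
    }
    TRUE
  }
  weights <- colSums(matrix(w[subsets], nrow = n - 1))
  ord <- order(weights)
  best <- NULL; best_w <- Inf
  trees <- list()
  for (k in ord) {
    if (weights[k] > best_w) break
    idx <- subsets[, k]
    if (is_spanning_tree(idx)) {
      if (weights[k] < best_w) best_w <- weights[k]
      trees[[length(trees) + 1]] <- pairs[idx, , drop = FALSE]
    }
  }
  list(weight = best_w, trees = trees)
}
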