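#' Simulate a serial-sample (heterochronous) coalescent alignment
#'
#' Simulates a coalescent genealogy in which each lineage becomes available
#' for coalescence at its sampling age (years BP converted to generations),
#' with pairwise coalescence at rate 1 per 2*Ne generations per pair, then
#' drops Poisson mutations on the branches under the infinite-sites model
#' mapped to `L` distinct positions.  This is the process assumed when
#' quantifying the inflation of nucleotide diversity caused by pooling
#' samples of different ages.
#'
#' Scaling: with `mu` per site per generation, the per-sequence diversity
#' parameter is theta = 4*Ne*mu*L, and for homochronous samples
#' E\[K\] = theta.
#'
#' @param n Number of samples (>= 2).
#' @param ages Ages in years BP, length `n` (default all 0 =
#'   homochronous).
#' @param Ne Effective population size (diploid-equivalent scaling: mean
#'   pairwise coalescence time 2*Ne generations).
#' @param mu Mutation rate per site per generation.
#' @param L Number of sites.
#' @param generation_length Years per generation (converts ages to
#'   generations).
#' @param seed Integer seed; mandatory, output is a pure function of
#'   (config, seed).
#' @return A list with `aln` (an `aligned_seqs`), `samples` (metadata
#'   data.frame with true ages), and `truth` (theta, tree height in
#'   generations, total branch length, mutation count).
#' @export
simulate_serial_coalescent <- function(n, ages = rep(0, n), Ne, mu, L,
                                       generation_length = 7, seed) {
  stopifnot(n >= 2, length(ages) == n, all(ages >= 0), Ne > 0, mu >= 0,
            L >= 1)
  if (missing(seed)) stop("seed is mandatory")
  old <- .Random.seed_get(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  ages_gen <- ages / generation_length
  n_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, n_nodes)
  node_time <- c(ages_gen, rep(NA_real_, n - 1L))
  pending <- order(ages_gen)          # leaf indices by age, ascending
  active <- integer(0)
  tau <- 0
  next_node <- n + 1L
  repeat {
    # ensure at least two active lineages before drawing a waiting time
    while (length(active) < 2L && length(pending)) {
      tau <- max(tau, node_time[pending[1]])
      take <- pending[node_time[pending] <= tau]
      active <- c(active, take)
      pending <- setdiff(pending, take)
    }
    if (length(active) < 2L) break
    k <- length(active)
    w <- stats::rexp(1, rate = k * (k - 1) / 2 / (2 * Ne))
    t_next <- if (length(pending)) node_time[pending[1]] else Inf
    if (tau + w < t_next) {
      tau <- tau + w
      pair <- sample(active, 2L)
      parent[pair] <- next_node
      node_time[next_node] <- tau
      active <- c(setdiff(active, pair), next_node)
      next_node <- next_node + 1L
    } else {
      tau <- t_next
      take <- pending[node_time[pending] <= tau]
      active <- c(active, take)
      pending <- setdiff(pending, take)
    }
  }
  root <- n_nodes
  blen <- ifelse(is.na(parent), 0, node_time[parent] - node_time)

  # infinite-sites mutations: distinct positions, one change each
  n_mut_branch <- stats::rpois(n_nodes, mu * L * blen)
  M <- sum(n_mut_branch)
  if (M > L) stop("more mutations (", M, ") than sites (", L,
                  "); increase L or lower mu")
  positions <- sample.int(L, M)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  seqs <- matrix(NA_character_, n_nodes, L)
  seqs[root, ] <- ref
  mut_of <- split(positions, rep(seq_len(n_nodes), n_mut_branch))
  # children before parents in index order is not guaranteed; walk from root
  children <- split(seq_len(n_nodes)[!is.na(parent)],
                    parent[!is.na(parent)])
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (ch in children[[as.character(v)]]) {
      s <- seqs[v, ]
      for (p in mut_of[[as.character(ch)]])
        s[p] <- sample(setdiff(bases, s[p]), 1)
      seqs[ch, ] <- s
      stack <- c(stack, ch)
    }
  }
  ids <- sprintf("sim%02d", seq_len(n))
  aln <- aligned_seqs(structure(seqs[seq_len(n), , drop = FALSE],
                                dimnames = list(ids, NULL)))
  samples <- data.frame(id = ids, site = "simulated", region = "simulated",
                        period = NA_character_,
                        date_early = 1950 - ages, date_late = 1950 - ages,
                        age_bp = ages, sex = "unknown",
                        stringsAsFactors = FALSE)
  list(aln = aln, samples = samples,
       truth = list(theta = 4 * Ne * mu * L,
                    tree_height = node_time[root],
                    total_branch_length = sum(blen),
                    n_mutations = M))
}

PERIOD_RANGES <- list(Prehistoric = c(-700, 1199), Medieval = c(1200, 1549),
                      "Post-Medieval" = c(1550, 1799),
                      Modern = c(1800, 1950))

#' Simulate a haplogroup panel with known truth labels
#'
#' Generates aligned sequences over the mitochondrial analysis fragments in
#' which each sample carries the diagnostic alleles of its assigned
#' haplogroup (planted along the rule-tree path) plus Poisson-distributed
#' private mutations restricted to non-diagnostic positions, so the
#' classifier's truth is exactly recoverable.  Periods, regions, sexes and
#' Y-chromosomal alleles are assigned per the plan.
#'
#' @param plan A list with elements `cohort_sizes` (named integer vector by
#'   period), `haplogroup_freqs` (named numeric, rule labels, sums to 1),
#'   `private_rate` (expected private mutations per sample),
#'   `y1_freq` (named numeric per period: probability a male carries Y1),
#'   `male_frac` (fraction of males, default 0.2).
#' @param rules A `haplogroup_rules` object (shipped default used if
#'   omitted).
#' @param seed Integer seed; mandatory.
#' @return A list with `aln`, `samples`, `y` (per-male UTY fragments,
#'   `offset`, mapping), and `truth` (data.frame id, haplogroup, period,
#'   y_label).
#' @export
simulate_panel <- function(plan, rules = load_ruleset(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(abs(sum(plan$haplogroup_freqs) - 1) < 1e-8)
  if (any(plan$haplogroup_freqs < 0)) stop("negative haplogroup frequency")
  if (!all(names(plan$haplogroup_freqs) %in% rules$rules))
    stop("haplogroup frequencies name unknown rules")
  old <- .Random.seed_get(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  male_frac <- if (is.null(plan$male_frac)) 0.2 else plan$male_frac
  private_rate <- if (is.null(plan$private_rate)) 0 else plan$private_rate
  ref <- bov_mt_reference()
  cols <- c(region_positions(region_spec(15936, 16012, ref)),  # Q fragment
            region_positions(region_spec(16031, 178, ref)),    # D-loop
            region_positions(region_spec(12911, 13091, ref)))  # ND5
  L <- length(cols)
  bases <- c("A", "C", "G", "T")
  refseq <- stats::setNames(sample(bases, L, replace = TRUE), cols)
  # reference must not accidentally carry a derived diagnostic allele
  diag_pos <- unique(unlist(lapply(rules$sites, names)))
  default_path <- character(0)
  lab <- rules$default_label
  while (!is.na(lab)) { default_path <- c(default_path, lab); lab <- rules$parent[lab] }
  ref_req <- unlist(rules$own_sites[default_path])
  for (lab in rules$rules) {
    s <- rules$own_sites[[lab]]
    for (p in names(s)) {
      if (!(p %in% names(refseq))) next
      want <- if (lab %in% default_path) s[p] else
        sample(setdiff(bases, s[p]), 1)
      refseq[p] <- want
    }
  }
  # reference alleles of the default path win over other rules at shared sites
  for (p in names(ref_req)) if (p %in% names(refseq)) refseq[p] <- ref_req[p]

  path_to <- function(lab) {
    path <- character(0)
    while (!is.na(lab)) { path <- c(lab, path); lab <- rules$parent[lab] }
    path
  }
  periods <- rep(names(plan$cohort_sizes), plan$cohort_sizes)
  n <- length(periods)
  ids <- sprintf("pan%03d", seq_len(n))
  groups <- sample(names(plan$haplogroup_freqs), n, replace = TRUE,
                   prob = plan$haplogroup_freqs)
  m <- matrix(rep(refseq, each = n), n, L,
              dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    for (lab in path_to(groups[i])) {
      s <- rules$own_sites[[lab]]
      for (p in names(s)) if (p %in% names(refseq))
        m[i, match(p, names(refseq))] <- s[p]
    }
    n_priv <- stats::rpois(1, private_rate)
    if (n_priv > 0) {
      free <- which(!(names(refseq) %in% diag_pos))
      at <- sample(free, min(n_priv, length(free)))
      for (p in at) m[i, p] <- sample(setdiff(bases, m[i, p]), 1)
    }
  }
  aln <- aligned_seqs(m, columns = as.integer(cols))

  years <- vapply(periods, function(p) {
    r <- PERIOD_RANGES[[p]]
    round(stats::runif(1, r[1], r[2]))
  }, 0)
  sex <- ifelse(stats::runif(n) < male_frac, "male", "female")
  samples <- data.frame(id = ids, site = "simulated", region = "simulated",
                        period = periods, date_early = years,
                        date_late = years, age_bp = 1950 - years,
                        sex = sex, stringsAsFactors = FALSE)

  # UTY fragments for males: 155 bp, diagnostic transversion at offset 78
  offset <- 78L
  mapping <- c(G = "Y2", T = "Y1")
  yref <- sample(bases, 155, replace = TRUE)
  y_label <- rep(NA_character_, n)
  y_frag <- stats::setNames(vector("list", n), ids)
  for (i in which(sex == "male")) {
    p1 <- plan$y1_freq[[periods[i]]]
    if (is.null(p1) || is.na(p1)) p1 <- 0.5
    y_label[i] <- if (stats::runif(1) < p1) "Y1" else "Y2"
    f <- yref
    f[offset] <- if (y_label[i] == "Y1") "T" else "G"
    y_frag[[i]] <- paste0(f, collapse = "")
  }
  list(aln = aln, samples = samples,
       y = list(fragments = y_frag[!vapply(y_frag, is.null, TRUE)],
                offset = offset, mapping = mapping),
       truth = data.frame(id = ids, haplogroup = groups, period = periods,
                          y_label = y_label, stringsAsFactors = FALSE))
}

#' Simulate multinomial cohort count tables
#'
#' Draws independent multinomial counts per cohort (row), for test
#' calibration and power studies.
#'
#' @param probabilities A list (one element per cohort/row) of probability
#'   vectors over the same categories, or a single vector recycled to all
#'   rows.
#' @param sizes Integer vector of cohort sizes (one per row).
#' @param replicates Number of tables to draw.
#' @param seed Integer seed; mandatory.
#' @return A list of `contingency_table` objects.
#' @export
simulate_cohort_counts <- function(probabilities, sizes, replicates = 1,
                                   seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (!is.list(probabilities))
    probabilities <- rep(list(probabilities), length(sizes))
  stopifnot(length(probabilities) == length(sizes))
  for (p in probabilities) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("probability vectors must be non-negative and sum to 1")
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  k <- length(probabilities[[1]])
  cats <- names(probabilities[[1]])
  if (is.null(cats)) cats <- paste0("c", seq_len(k))
  lapply(seq_len(replicates), function(r) {
    m <- t(vapply(seq_along(sizes), function(i)
      as.integer(stats::rmultinom(1, sizes[i], probabilities[[i]])),
      integer(k)))
    dimnames(m) <- list(paste0("cohort", seq_along(sizes)), cats)
    contingency_table(m)
  })
}
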