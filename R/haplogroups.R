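#' Load a haplogroup diagnostic rule set
#'
#' Rules live in data, not code: each haplogroup or sub-haplogroup is a row
#' of a TSV config with columns `label`, `parent` (`.` for a root) and
#' `sites` (comma-separated `position=base` pairs on the reference; may be
#' empty for a group defined only by its parent's sites, as for the
#' reference-profile cluster).  A child inherits all ancestral site
#' requirements and may never contradict them.
#'
#' The shipped default (`system.file("extdata", "bovine_mt_rules.tsv",
#' package = "archaeopop")`) encodes the taurine T/Q split at position
#' 15953 of V00654 together with representative entries for T1, T1f, T2,
#' T3, T3b, T4, T5, P and R.  Only the 15953 split is anchored in primary
#' literature routinely available; the remaining site/allele pairs are
#' illustrative defaults intended to be replaced by curated values for real
#' analyses.
#'
#' @param path Path to the rule config; defaults to the shipped bovine set.
#' @param default_label Label returned for a profile matching no derived
#'   rule (the all-reference profile); `"T3"` for the shipped set.
#' @return An object of class `haplogroup_rules`: data.frame of rules with
#'   parsed site requirements, plus the default label.
#' @export
load_ruleset <- function(path = system.file("extdata", "bovine_mt_rules.tsv",
                                            package = "archaeopop"),
                         default_label = "T3",
                         reference = bov_mt_reference()) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         na.strings = NULL)
  if (nrow(d) == 0L) stop("empty rule file: ", path)
  stopifnot(all(c("label", "parent", "sites") %in% names(d)))
  if (anyDuplicated(d$label)) stop("duplicate rule label")
  sites <- lapply(d$sites, function(s) {
    s <- trimws(s)
    if (is.na(s) || s == "" || s == ".") return(integer(0))
    parts <- strsplit(strsplit(s, ",")[[1]], "=")
    pos <- as.integer(vapply(parts, `[`, "", 1))
    base <- toupper(trimws(vapply(parts, `[`, "", 2)))
    if (anyNA(pos) || any(pos < 1L) || any(pos > reference$length))
      stop("rule '", d$label[which(d$sites == s)[1]],
           "': position outside reference")
    stats::setNames(base, pos)
  })
  names(sites) <- d$label
  d$parent[d$parent %in% c(".", "")] <- NA

  ## resolve effective (inherited + own) requirements; detects cycles and
  ## parent/child contradictions
  effective <- list(); depth <- integer(nrow(d))
  names(depth) <- d$label
  resolve <- function(lab, seen = character()) {
    if (lab %in% seen) stop("cycle in rule tree at '", lab, "'")
    if (!is.null(effective[[lab]])) return(effective[[lab]])
    i <- match(lab, d$label)
    if (is.na(i)) stop("unknown parent label '", lab, "'")
    own <- sites[[i]]
    par <- d$parent[i]
    if (is.na(par)) {
      eff <- own; depth[lab] <<- 1L
    } else {
      inh <- resolve(par, c(seen, lab))
      shared <- intersect(names(inh), names(own))
      contra <- shared[inh[shared] != own[shared]]
      if (length(contra))
        stop("rule '", lab, "' contradicts parent '", par,
             "' at position ", contra[1])
      eff <- c(inh[setdiff(names(inh), names(own))], own)
      depth[lab] <<- depth[par] + 1L
    }
    effective[[lab]] <<- eff
    eff
  }
  for (lab in d$label) resolve(lab)
  structure(list(rules = d$label, parent = stats::setNames(d$parent, d$label),
                 own_sites = sites, sites = effective[d$label],
                 depth = depth, default_label = default_label,
                 reference = reference),
            class = "haplogroup_rules")
}

#' @export
print.haplogroup_rules <- function(x, ...) {
  cat("Haplogroup rule set:", length(x$rules), "rules; default",
      x$default_label, "\n")
  for (lab in x$rules) {
    s <- x$own_sites[[lab]]
    cat(sprintf("  %-5s parent=%-5s %s\n", lab,
                ifelse(is.na(x$parent[lab]), ".", x$parent[lab]),
                if (length(s)) paste0(names(s), "=", s, collapse = ",") else "-"))
  }
  invisible(x)
}

site_status <- function(symbols, required) {
  # symbols: observed symbol at each required position (NA if not covered)
  vapply(seq_along(required), function(i) {
    sym <- symbols[i]; req <- required[i]
    if (is.na(sym) || sym == "N" || sym == "-") "unknown"
    else if (sym == req) "match"
    else if (req %in% IUPAC[[sym]]) "compatible"  # ambiguity incl. the base
    else "contradict"
  }, "")
}

#' Classify one sequence into a haplogroup
#'
#' Returns the deepest rule all of whose (inherited + own) diagnostic
#' alleles match exactly.  A required site covered by `N`, a gap, or an
#' IUPAC ambiguity that merely includes the required base leaves the rule
#' "not contradicted" but does not let it advance depth — conservative for
#' damaged ancient DNA.  If no diagnostic position of the rule set is
#' covered at all the call is `"unassigned"`; a covered profile matching no
#' derived rule gets the rule set's default label.
#'
#' @param seq A character string (or vector of single symbols) over the
#'   analysis region.
#' @param columns Reference positions of the sequence symbols.
#' @param rules A `haplogroup_rules` object.
#' @return A haplogroup label.
#' @export
classify_mt <- function(seq, columns, rules) {
  sym <- if (length(seq) == 1L && nchar(seq[1]) > 1L) strsplit(toupper(seq), "")[[1]]
         else toupper(seq)
  stopifnot(length(sym) == length(columns))
  lookup <- stats::setNames(sym, columns)
  all_pos <- unique(unlist(lapply(rules$sites, names)))
  covered <- all_pos[all_pos %in% names(lookup) &
                       !(lookup[all_pos] %in% c("N", "-", NA))]
  if (length(covered) == 0L) return("unassigned")
  matched <- character(0)
  any_contradicted <- FALSE
  for (lab in rules$rules) {
    req <- rules$sites[[lab]]
    if (length(req) == 0L) { matched <- c(matched, lab); next }
    st <- site_status(unname(lookup[names(req)]), unname(req))
    if (all(st == "match")) matched <- c(matched, lab)
    if (any(st == "contradict")) any_contradicted <- TRUE
  }
  if (length(matched) == 0L) {
    # a profile contradicting every rule carries an allele outside the
    # configured nomenclature; only uncontradicted-but-undetermined
    # profiles fall back to the default label
    return(if (any_contradicted) "unassigned" else rules$default_label)
  }
  matched[order(-rules$depth[matched], matched)][1]
}

#' Classify every sequence of an alignment
#'
#' @param aln An `aligned_seqs` object whose columns are reference
#'   positions.
#' @param rules A `haplogroup_rules` object.
#' @return A data.frame with `id` and `label`; per-label counts in
#'   `attr(, "counts")`.
#' @export
batch_classify <- function(aln, rules) {
  stopifnot(inherits(aln, "aligned_seqs"))
  if (length(aln$ids) == 0L) {
    out <- data.frame(id = character(0), label = character(0))
    attr(out, "counts") <- table(character(0))
    return(out)
  }
  labels <- vapply(seq_along(aln$ids), function(i)
    classify_mt(aln$matrix[i, ], aln$columns, rules), "")
  out <- data.frame(id = aln$ids, label = labels, stringsAsFactors = FALSE)
  attr(out, "counts") <- table(labels)
  out
}

#' Call the Y-chromosomal haplotype from a UTY intron-19 fragment
#'
#' A single transversion in intron 19 of the UTY gene separates the taurine
#' paternal haplotypes Y1 and Y2.  The base at the diagnostic offset is
#' read and mapped through `mapping`; any other symbol (N, gap, ambiguity)
#' yields `"no_amplification"`.  Which allele corresponds to Y1 is not
#' uniformly reported, so the mapping is configuration; the default maps
#' G to Y2 and T to Y1.
#'
#' @param seq Fragment sequence (string or symbol vector).
#' @param offset 1-based offset of the diagnostic site within the fragment.
#' @param mapping Named character vector allele -> label.
#' @return A list with `allele` and `label`.
#' @export
classify_y <- function(seq, offset, mapping = c(G = "Y2", T = "Y1")) {
  sym <- if (length(seq) == 1L && nchar(seq[1]) > 1L) strsplit(toupper(seq), "")[[1]]
         else toupper(seq)
  if (length(sym) < offset)
    stop("fragment length ", length(sym), " does not cover offset ", offset)
  allele <- sym[offset]
  label <- if (allele %in% names(mapping)) unname(mapping[allele])
           else "no_amplification"
  list(allele = allele, label = label)
}
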