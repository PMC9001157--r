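#' Site counts from an aligned sequence pair
#'
#' Tallies the comparable sites of a pairwise alignment under pairwise
#' deletion: columns containing a gap (`-`) or an ambiguous base (`N`) in
#' either sequence are excluded entirely. Remaining differing columns are
#' split into transitions (A<->G, C<->T) and transversions (everything else),
#' the two substitution classes the Kimura two-parameter model distinguishes.
#'
#' @param aligned_a,aligned_b equal-length gapped nucleotide strings.
#' @return A \code{site_counts} object: \code{n_valid}, \code{n_transition},
#'   \code{n_transversion}.
#' @examples
#' site_counts("AAAA", "GAAA")   # one transition
#' site_counts("A-GTN", "ATGTC") # gap and N columns dropped
#' @export
site_counts <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) stop("aligned length mismatch")
  a <- seq_bytes(toupper(aligned_a)); b <- seq_bytes(toupper(aligned_b))
  bad <- charToRaw("-N")
  valid <- !(a %in% bad | b %in% bad)
  a <- a[valid]; b <- b[valid]
  diff <- a != b
  # purines A,G and pyrimidines C,T: a transition stays within the class
  purine <- charToRaw("AG")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  new_site_counts(sum(valid), sum(ts), sum(diff) - sum(ts))
}

new_site_counts <- function(n_valid, n_transition, n_transversion) {
  structure(list(n_valid = as.integer(n_valid),
                 n_transition = as.integer(n_transition),
                 n_transversion = as.integer(n_transversion)),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf("site_counts: %d comparable sites, %d transitions, %d transversions\n",
              x$n_valid, x$n_transition, x$n_transversion))
  invisible(x)
}

#' Pool site counts across alignment blocks
#'
#' Summing per-block counts is exactly equivalent to computing counts on the
#' concatenated alignment, which is how multi-gene ("concatenated") distances
#' are obtained throughout the package.
#'
#' @param ... \code{site_counts} objects (or a single list of them).
#' @return A pooled \code{site_counts}.
#' @export
pool_site_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "site_counts")) xs <- xs[[1]]
  new_site_counts(sum(vapply(xs, `[[`, 0L, "n_valid")),
                  sum(vapply(xs, `[[`, 0L, "n_transition")),
                  sum(vapply(xs, `[[`, 0L, "n_transversion")))
}

#' Kimura two-parameter distance
#'
#' Substitution-corrected divergence from transition and transversion
#' proportions \eqn{P} and \eqn{Q}:
#' \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).}
#' Outside the formula's domain (\eqn{1 - 2P - Q \le 0} or
#' \eqn{1 - 2Q \le 0}), or with no comparable sites, the distance is
#' undefined and \code{NA} is returned with a \code{"reason"} attribute —
#' never silently coerced to zero or a maximum.
#'
#' @param counts a \code{site_counts} object.
#' @return The K2P distance, or \code{NA} with a reason attribute.
#' @examples
#' k2p(site_counts("ACGT", "ACGT"))            # 0
#' k2p(new_site_counts(100, 25, 0))            # -log(0.5)/2
#' @export
k2p <- function(counts) {
  stopifnot(inherits(counts, "site_counts"))
  if (counts$n_valid == 0L)
    return(structure(NA_real_, reason = "no comparable sites"))
  P <- counts$n_transition / counts$n_valid
  Q <- counts$n_transversion / counts$n_valid
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(structure(NA_real_, reason = "saturated (outside formula domain)"))
  -0.5 * log(w1) - 0.25 * log(w2)
}

# K2P straight from pooled integer counts (row of a pair_stats matrix)
k2p_from_counts <- function(n_valid, n_ts, n_tv) {
  if (n_valid == 0) return(NA_real_)
  w1 <- 1 - 2 * n_ts / n_valid - n_tv / n_valid
  w2 <- 1 - 2 * n_tv / n_valid
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

# per-gene pooled site counts between one baseline sample and many samples;
# returns matrix with rows = samples, cols n_valid/n_transition/n_transversion
pooled_counts_vs_baseline <- function(db, baseline_sample, samples, genes,
                                      params = alignment_params()) {
  acc <- matrix(0L, nrow = length(samples), ncol = 3,
                dimnames = list(samples, c("n_valid", "n_transition", "n_transversion")))
  for (g in genes) {
    base_seq <- db_get_seq(db, baseline_sample, g)
    if (is.na(base_seq)) next
    have <- samples[!is.na(db_get_seq(db, samples, g))]
    if (!length(have)) next
    seqs <- c(base_seq, db_get_seq(db, have, g))
    st <- pair_stats(seqs, rep(1L, length(have)), seq_along(have) + 1L, params)
    acc[have, ] <- acc[have, , drop = FALSE] +
      st[, c("n_valid", "n_transition", "n_transversion"), drop = FALSE]
  }
  acc
}

#' Precompute pairwise alignment statistics per gene
#'
#' Aligns every pair of samples possessing each gene once and stores the
#' alignment statistics. Both the leave-one-out evaluation and the distance
#' matrix consume the same per-pair counts, so sharing a cache halves the
#' cost of a full-database analysis.
#'
#' @param db a [refdb] object.
#' @param genes genes to precompute (default: whole panel).
#' @param params alignment scoring.
#' @return A \code{pair_stats_cache}: per gene, the carrying samples, the
#'   index pairs, and the statistics matrix from the batch aligner.
#' @export
precompute_pair_stats <- function(db, genes = db$gene_panel,
                                  params = alignment_params()) {
  stopifnot(inherits(db, "refdb"))
  cache <- lapply(stats::setNames(genes, genes), function(g) {
    seqs <- db_get_seq(db, db$taxa$sample_id, g)
    have <- which(!is.na(seqs))
    if (length(have) < 2L) return(NULL)
    prs <- utils::combn(length(have), 2L)
    list(samples = db$taxa$sample_id[have],
         pairs = prs,
         stats = pair_stats(seqs[have], prs[1, ], prs[2, ], params))
  })
  structure(cache, class = "pair_stats_cache", params = params)
}

# symmetric matrices of a cached statistic for one gene
cache_matrix <- function(entry, col) {
  n <- length(entry$samples)
  m <- matrix(NA_real_, n, n, dimnames = list(entry$samples, entry$samples))
  m[cbind(entry$pairs[1, ], entry$pairs[2, ])] <- entry$stats[, col]
  m[cbind(entry$pairs[2, ], entry$pairs[1, ])] <- entry$stats[, col]
  m
}

#' K2P distance profile against a baseline sample
#'
#' Distances from one reference sample to every other sample in the database,
#' for a single gene region or for \code{gene = "all"}: the concatenation (in
#' panel order) of the gene regions both samples possess, with missing genes
#' contributing nothing after pairwise deletion. Samples sharing no usable
#' sites with the baseline get \code{NA}.
#'
#' @param db a [refdb] object.
#' @param baseline_sample sample id to measure from.
#' @param gene a gene name from the panel, or \code{"all"}.
#' @param params alignment scoring, see [alignment_params()].
#' @return A named numeric vector of distances (baseline included, at 0).
#' @export
baseline_profile <- function(db, baseline_sample, gene = "all",
                             params = alignment_params()) {
  stopifnot(inherits(db, "refdb"))
  if (!baseline_sample %in% db$taxa$sample_id)
    stop("unknown baseline sample: ", baseline_sample)
  genes <- if (identical(gene, "all")) db$gene_panel else gene
  if (!all(genes %in% db$gene_panel)) stop("gene not in panel: ", gene)
  base_has <- !is.na(db_get_seq(db, baseline_sample, genes))
  if (!any(base_has)) stop("baseline possesses none of the requested genes")
  samples <- db$taxa$sample_id
  acc <- pooled_counts_vs_baseline(db, baseline_sample, samples, genes[base_has], params)
  d <- vapply(seq_len(nrow(acc)), function(i)
    k2p_from_counts(acc[i, 1], acc[i, 2], acc[i, 3]), 0.0)
  names(d) <- samples
  d
}

#' All-pairs concatenated-gene K2P distance matrix
#'
#' For every sample pair, site counts are pooled over all gene regions both
#' samples possess (each gene aligned pairwise, non-comparable columns
#' removed) and converted to a single K2P distance. Pairs with no shared
#' usable sites, or saturated beyond the formula's domain, are \code{NA}.
#'
#' @param db a [refdb] object.
#' @param genes genes to use (default: the whole panel).
#' @param params alignment scoring.
#' @param cache optional [precompute_pair_stats()] result to reuse.
#' @return A symmetric numeric matrix with zero diagonal; \code{NA} marks
#'   undefined entries.
#' @export
all_genes_matrix <- function(db, genes = db$gene_panel, params = alignment_params(),
                             cache = NULL) {
  stopifnot(inherits(db, "refdb"))
  samples <- db$taxa$sample_id
  n <- length(samples)
  if (n < 2L) stop("need at least two samples")
  nv <- ts <- tv <- matrix(0L, n, n, dimnames = list(samples, samples))
  for (g in genes) {
    entry <- if (!is.null(cache)) cache[[g]] else {
      sg <- db_get_seq(db, samples, g)
      have <- which(!is.na(sg))
      if (length(have) < 2L) NULL
      else {
        prs <- utils::combn(length(have), 2L)
        list(samples = samples[have], pairs = prs,
             stats = pair_stats(sg[have], prs[1, ], prs[2, ], params))
      }
    }
    if (is.null(entry)) next
    at <- cbind(match(entry$samples[entry$pairs[1, ]], samples),
                match(entry$samples[entry$pairs[2, ]], samples))
    nv[at] <- nv[at] + entry$stats[, "n_valid"]
    ts[at] <- ts[at] + entry$stats[, "n_transition"]
    tv[at] <- tv[at] + entry$stats[, "n_transversion"]
  }
  d <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  diag(d) <- 0
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- k2p_from_counts(nv[i, j], ts[i, j], tv[i, j])
  }
  d
}

#' UPGMA dendrogram from a distance matrix
#'
#' Agglomerates a (possibly partially undefined) K2P distance matrix into an
#' ultrametric dendrogram. Undefined entries are imputed with the matrix
#' maximum before clustering (with a message), matching the convention that
#' incomparable pairs are at least as divergent as any observed pair.
#'
#' @param d symmetric distance matrix, as from [all_genes_matrix()].
#' @param linkage \code{"upgma"} (average linkage, the default), or
#'   \code{"complete"} / \code{"single"}.
#' @return An [ape::phylo] tree (tip heights at half the merge distances).
#' @export
upgma_dendrogram <- function(d, linkage = c("upgma", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  off <- d[upper.tri(d)]
  if (all(is.na(off))) stop("all pairwise distances undefined")
  if (anyNA(off)) {
    mx <- max(off, na.rm = TRUE)
    message(sum(is.na(off)), " undefined distances imputed at matrix maximum ", signif(mx, 4))
    d[is.na(d)] <- mx
    diag(d) <- 0
  }
  hc <- stats::hclust(stats::as.dist(d),
                      method = switch(linkage, upgma = "average",
                                      complete = "complete", single = "single"))
  ape::as.phylo(hc)
}

#' Gene order for iterative concatenation
#'
#' Standard barcoding loci first (\code{matK}, \code{rbcL},
#' \code{trnH-psbA}, in that order, when present in the panel), the remaining
#' genes in a seed-determined random order.
#'
#' @param panel character vector of gene names.
#' @param seed integer seed for the random tail.
#' @param common the preferred-prefix loci, in priority order.
#' @return A character permutation of \code{panel}.
#' @export
default_gene_order <- function(panel, seed = 1L,
                               common = c("matK", "rbcL", "trnH-psbA")) {
  stopifnot(length(panel) > 0L)
  prefix <- common[common %in% panel]
  rest <- setdiff(panel, prefix)
  tail <- if (length(rest) > 1L) with_seed(seed, sample(rest)) else rest
  c(prefix, tail)
}

#' Comparison group
#'
#' A labelled set of samples whose K2P distance to a common baseline sample
#' is tracked as genes are concatenated, e.g. "within species" or "between
#' family" strata of a study group.
#'
#' @param label group label for output tables.
#' @param member_samples sample ids compared to the baseline.
#' @param category relatedness category (free text, e.g. "within genus").
#' @return A \code{comparison_group} object.
#' @export
comparison_group <- function(label, member_samples, category = label) {
  stopifnot(is.character(member_samples), length(member_samples) > 0L)
  structure(list(label = label, member_samples = member_samples,
                 category = category), class = "comparison_group")
}

#' Iterative gene concatenation distance curves
#'
#' For \eqn{k = 1, \dots, K} genes of a fixed order, computes the K2P
#' distance between the baseline sample and every group member over the
#' concatenation of the first \eqn{k} genes. A member's missing genes enter
#' as all-gap blocks and are removed by pairwise deletion, so each distance
#' is effectively computed over the genes both samples share among the first
#' \eqn{k}.
#'
#' @param db a [refdb] object.
#' @param order character vector: the gene order (see [default_gene_order()]).
#' @param baseline_sample the sample all distances are measured from; must
#'   possess the first gene of the order.
#' @param groups list of [comparison_group()] objects.
#' @param params alignment scoring.
#' @return A long-format data frame: \code{group}, \code{category},
#'   \code{member}, \code{k}, \code{gene_added}, \code{distance}.
#' @export
iterative_concat <- function(db, order, baseline_sample, groups,
                             params = alignment_params()) {
  stopifnot(inherits(db, "refdb"), length(order) > 0L)
  if (!baseline_sample %in% db$taxa$sample_id)
    stop("unknown baseline sample: ", baseline_sample)
  if (is.na(db_get_seq(db, baseline_sample, order[1])))
    stop("baseline lacks the first gene of the order: ", order[1])
  members <- unique(unlist(lapply(groups, `[[`, "member_samples")))
  missing <- setdiff(members, db$taxa$sample_id)
  if (length(missing)) stop("group member absent from db: ", paste(missing, collapse = ", "))
  # per-gene counts vs baseline once, then cumulate along the order
  per_gene <- lapply(order, function(g)
    pooled_counts_vs_baseline(db, baseline_sample, members, g, params))
  rows <- list()
  acc <- matrix(0L, length(members), 3, dimnames = list(members, NULL))
  for (k in seq_along(order)) {
    acc <- acc + per_gene[[k]]
    dk <- vapply(seq_len(nrow(acc)), function(i)
      k2p_from_counts(acc[i, 1], acc[i, 2], acc[i, 3]), 0.0)
    names(dk) <- members
    for (grp in groups) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp$label, category = grp$category,
        member = grp$member_samples, k = k, gene_added = order[k],
        distance = unname(dk[grp$member_samples]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
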