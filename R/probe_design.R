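#' Target sequence record
#'
#' One candidate capture target: a gene-region sequence from a reference
#' taxon, the input unit of probe panel design.
#'
#' @param seq_id unique sequence id.
#' @param gene gene-region name.
#' @param taxon_label source taxon label.
#' @param seq ungapped nucleotide string.
#' @return A \code{target_seq} object.
#' @export
target_seq <- function(seq_id, gene, taxon_label, seq) {
  seq <- clean_seq(seq, seq_id)
  structure(list(seq_id = seq_id, gene = gene, taxon_label = taxon_label,
                 seq = seq), class = "target_seq")
}

#' Extract a target region from a genome by local alignment
#'
#' Locates \code{reference_gene} in \code{genome} by Smith-Waterman local
#' alignment and returns the genome footprint as a new target sequence when
#' the hit is credible: column identity at least \code{min_identity} and the
#' reference footprint covering at least \code{min_coverage} of the
#' reference length. Otherwise returns \code{NULL}.
#'
#' @param reference_gene a [target_seq()].
#' @param genome nucleotide string to search.
#' @param min_identity minimum alignment-column identity (default 0.70).
#' @param min_coverage minimum fraction of the reference covered (default 0.50).
#' @param params alignment scoring.
#' @return A \code{target_seq} for the extracted region, or \code{NULL}.
#' @export
extract_targets <- function(reference_gene, genome, min_identity = 0.70,
                            min_coverage = 0.50, params = alignment_params()) {
  stopifnot(inherits(reference_gene, "target_seq"),
            min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  genome <- clean_seq(genome, "genome")
  aln <- local_align(reference_gene$seq, genome, params)
  if (aln$score <= 0 || aln$n_columns == 0L) return(NULL)
  ref_cov <- (aln$footprint_a[2] - aln$footprint_a[1]) / nchar(reference_gene$seq)
  if (aln_identity(aln, "columns") < min_identity || ref_cov < min_coverage)
    return(NULL)
  target_seq(paste0(reference_gene$seq_id, "_hit"),
             reference_gene$gene, reference_gene$taxon_label,
             substr(genome, aln$footprint_b[1] + 1L, aln$footprint_b[2]))
}

#' Greedy identity clustering of target sequences
#'
#' CD-HIT-style greedy incremental clustering: sequences are visited longest
#' first (ties by \code{seq_id}), each joining the first existing cluster
#' whose representative it matches at identity-over-the-shorter-sequence
#' \code{>= threshold}, else founding a new cluster. Representatives are
#' therefore the longest member of each cluster. As with CD-HIT, two
#' representatives are not guaranteed to be mutually below the threshold.
#'
#' @param seqs list of [target_seq()] objects (one gene region).
#' @param threshold identity cutoff in (0, 1], default 0.95.
#' @param params alignment scoring.
#' @return List of clusters, each \code{list(representative_id, member_ids)}.
#' @export
greedy_cluster <- function(seqs, threshold = 0.95, params = alignment_params()) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!length(seqs)) return(list())
  ids <- vapply(seqs, `[[`, "", "seq_id")
  lens <- vapply(seqs, function(s) nchar(s$seq), 0L)
  ord <- order(-lens, ids)
  reps <- integer(0)            # indices (into seqs) of cluster representatives
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      aln <- global_align(seqs[[i]]$seq, seqs[[reps[ci]]]$seq, params)
      if (aln_identity(aln, "shorter") >= threshold) {
        members[[ci]] <- c(members[[ci]], ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- ids[i]
    }
  }
  lapply(seq_along(reps), function(ci)
    list(representative_id = ids[reps[ci]], member_ids = members[[ci]]))
}

#' Tile 120-mer probes across a target sequence
#'
#' Probes of length \code{probe_len} start at offsets \code{0, step,
#' 2 step, ...} while they fit; with \code{step = probe_len / 2} this is 2X
#' tiling (each probe overlaps half its length). If the last regular probe
#' ends short of the sequence end, one extra end-anchored probe at
#' \code{L - probe_len} is appended so the 3' end is covered. Sequences
#' shorter than \code{probe_len} yield no probes (with a warning).
#'
#' @param seq a [target_seq()].
#' @param probe_len probe length, default 120.
#' @param step tiling step, default \code{probe_len / 2}.
#' @return Data frame with \code{source_id}, \code{start} (0-based),
#'   \code{seq}; zero rows when the sequence is too short.
#' @export
tile_probes <- function(seq, probe_len = 120L, step = probe_len %/% 2L) {
  stopifnot(inherits(seq, "target_seq"), probe_len > 0L, step > 0L)
  L <- nchar(seq$seq)
  empty <- data.frame(source_id = character(), start = integer(),
                      seq = character(), stringsAsFactors = FALSE)
  if (L < probe_len) {
    warning("sequence ", seq$seq_id, " shorter than probe length; skipped")
    return(empty)
  }
  starts <- seq.int(0L, L - probe_len, by = step)
  if (starts[length(starts)] + probe_len < L) starts <- c(starts, L - probe_len)
  data.frame(source_id = seq$seq_id, start = starts,
             seq = substring(seq$seq, starts + 1L, starts + probe_len),
             stringsAsFactors = FALSE)
}

#' Design a capture probe panel
#'
#' Per gene region: cluster the candidate targets at \code{threshold}
#' identity keeping the longest per cluster, then tile probes across each
#' representative. Returns clusters, representatives, probes and summary
#' counts (probes per gene, representative length min/mean/max).
#'
#' @param seqs list of [target_seq()] objects, any mix of genes.
#' @param threshold clustering identity cutoff, default 0.95.
#' @param probe_len,step probe tiling geometry (default 120 / 60, i.e. 2X).
#' @param params alignment scoring.
#' @return A \code{probe_panel}: \code{clusters}, \code{representatives},
#'   \code{probes} (data frame), \code{per_gene} summary data frame.
#' @export
design_panel <- function(seqs, threshold = 0.95, probe_len = 120L,
                         step = probe_len %/% 2L, params = alignment_params()) {
  empty_probes <- data.frame(source_id = character(), start = integer(),
                             seq = character(), stringsAsFactors = FALSE)
  if (!length(seqs))
    return(structure(list(clusters = list(), representatives = list(),
                          probes = empty_probes, per_gene = data.frame()),
                     class = "probe_panel"))
  genes <- unique(vapply(seqs, `[[`, "", "gene"))
  clusters <- list(); rep_seqs <- list(); probes <- list(); per_gene <- list()
  by_id <- stats::setNames(seqs, vapply(seqs, `[[`, "", "seq_id"))
  for (g in genes) {
    gs <- seqs[vapply(seqs, function(s) s$gene == g, TRUE)]
    cl <- greedy_cluster(gs, threshold, params)
    reps <- lapply(cl, function(x) by_id[[x$representative_id]])
    pr <- do.call(rbind, c(lapply(reps, tile_probes, probe_len = probe_len, step = step),
                           make.row.names = FALSE))
    rl <- vapply(reps, function(s) nchar(s$seq), 0L)
    clusters[[g]] <- cl
    rep_seqs <- c(rep_seqs, reps)
    probes[[g]] <- pr
    per_gene[[g]] <- data.frame(
      gene = g, n_sequences = length(gs), n_representatives = length(cl),
      n_probes = if (is.null(pr)) 0L else nrow(pr),
      rep_len_min = min(rl), rep_len_mean = mean(rl), rep_len_max = max(rl),
      stringsAsFactors = FALSE)
  }
  probes <- do.call(rbind, c(probes, make.row.names = FALSE))
  per_gene <- do.call(rbind, c(per_gene, make.row.names = FALSE))
  structure(list(clusters = clusters, representatives = rep_seqs,
                 probes = probes %||% data.frame(),
                 per_gene = per_gene %||% data.frame()),
            class = "probe_panel")
}

#' @export
print.probe_panel <- function(x, ...) {
  n_rep <- length(x$representatives)
  n_pr <- if (is.null(x$probes) || !nrow(x$probes)) 0L else nrow(x$probes)
  cat(sprintf("probe panel: %d genes, %d representatives, %d probes",
              if (is.null(x$per_gene) || !nrow(x$per_gene)) 0L else nrow(x$per_gene),
              n_rep, n_pr))
  if (n_rep) {
    rl <- vapply(x$representatives, function(s) nchar(s$seq), 0L)
    cat(sprintf(" (rep length %d-%d, mean %.0f)", min(rl), max(rl), mean(rl)))
  }
  cat("\n")
  invisible(x)
}

#' Write panel probes as FASTA
#'
#' Headers are \code{source_id|start}.
#'
#' @param panel a \code{probe_panel} from [design_panel()].
#' @param path output FASTA path.
#' @export
write_probes_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "probe_panel"))
  pr <- panel$probes
  seqinr::write.fasta(as.list(pr$seq), paste(pr$source_id, pr$start, sep = "|"),
                      path, nbchar = 80)
  invisible(path)
}
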