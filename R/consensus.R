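#' Read a simplified pileup TSV
#'
#' One base observation per row, tab-separated, with columns
#' \code{position} (0-based), \code{base} (A/C/G/T), \code{base_q},
#' \code{map_q} (phred integers). A header row is required.
#'
#' @param path TSV path.
#' @return Data frame of observations.
#' @export
read_pileup <- function(path) {
  obs <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "base", "base_q", "map_q")
  if (!all(need %in% names(obs)))
    stop("pileup must have columns: ", paste(need, collapse = ", "))
  obs
}

#' Quality-filter base observations into pileup columns
#'
#' An observation is counted only when both its base quality and mapping
#' quality reach the thresholds (observations with quality below 30 are
#' discarded under the defaults). Every position in \code{0:(length-1)}
#' yields a column, zero-depth ones included.
#'
#' @param obs observation data frame (see [read_pileup()]).
#' @param min_base_q,min_map_q phred thresholds, default 30.
#' @param length declared sequence length; default one past the largest
#'   observed position.
#' @return Data frame with \code{position}, counts \code{A,C,G,T}, and
#'   \code{depth}, one row per position.
#' @export
filter_observations <- function(obs, min_base_q = 30L, min_map_q = 30L,
                                length = NULL) {
  stopifnot(is.data.frame(obs))
  if (nrow(obs) && (any(obs$base_q < 0) || any(obs$map_q < 0)))
    stop("negative quality value")
  if (is.null(length)) length <- if (nrow(obs)) max(obs$position) + 1L else 0L
  if (nrow(obs) && max(obs$position) >= length)
    stop("observation position beyond declared length")
  keep <- obs[obs$base_q >= min_base_q & obs$map_q >= min_map_q, , drop = FALSE]
  counts <- matrix(0L, nrow = length, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  if (nrow(keep)) {
    bad <- !keep$base %in% c("A", "C", "G", "T")
    if (any(bad)) stop("non-ACGT base in pileup: ", keep$base[which(bad)[1]])
    tb <- table(factor(keep$position, levels = 0:(length - 1L)),
                factor(keep$base, levels = c("A", "C", "G", "T")))
    counts <- matrix(as.integer(tb), nrow = length, ncol = 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
  }
  data.frame(position = 0:(length - 1L), counts, depth = rowSums(counts))
}

#' Call a depth-masked haploid consensus
#'
#' Per position: below \code{min_depth} quality-passing observations the call
#' is masked to \code{N}; otherwise the single majority base is called
#' (haploid model). An exact tie for the maximum count is also masked —
#' a haploid caller should not invent certainty. Positions with no column
#' are \code{N}.
#'
#' @param columns pileup columns from [filter_observations()].
#' @param length consensus length; default \code{nrow(columns)}.
#' @param min_depth minimum read depth for an unmasked call, default 50.
#' @param sample_id label carried on the result.
#' @return A \code{consensus_seq}: \code{sample_id}, \code{seq} (over
#'   \code{A,C,G,T,N}), \code{masked_positions} (0-based).
#' @export
call_consensus <- function(columns, length = nrow(columns), min_depth = 50L,
                           sample_id = "sample") {
  stopifnot(is.data.frame(columns))
  if (nrow(columns) && length < max(columns$position) + 1L)
    stop("declared length shorter than pileup extent")
  calls <- rep("N", length)
  if (nrow(columns)) {
    cm <- as.matrix(columns[, c("A", "C", "G", "T")])
    top <- max.col(cm, ties.method = "first")
    topcount <- cm[cbind(seq_len(nrow(cm)), top)]
    tie <- rowSums(cm == topcount) > 1L & topcount > 0L
    ok <- columns$depth >= min_depth & !tie & topcount > 0L
    calls[columns$position[ok] + 1L] <- c("A", "C", "G", "T")[top[ok]]
  }
  seq <- paste(calls, collapse = "")
  structure(list(sample_id = sample_id, seq = seq,
                 masked_positions = which(calls == "N") - 1L),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  n <- nchar(x$seq)
  cat(sprintf("consensus '%s': %d bp, %d masked (%.1f%%)\n", x$sample_id, n,
              length(x$masked_positions),
              if (n) 100 * length(x$masked_positions) / n else 0))
  invisible(x)
}

#' Annotate gene regions on a consensus sequence
#'
#' Each reference gene is located on the consensus by local alignment; a
#' gene is reported present when the alignment-column identity reaches
#' \code{min_identity} (default 0.25 — annotation transfer is deliberately
#' permissive; masked \code{N} runs score as mismatches and push degraded
#' regions below it) and the alignment footprint spans at least
#' \code{min_coverage} of the reference gene (local alignment otherwise
#' accepts arbitrarily short chance hits). When a coordinate hint is
#' supplied the search is restricted to the hinted interval widened by
#' \code{flank} bases on either side; the extracted sequence is always
#' exactly the alignment footprint.
#'
#' @param consensus a [call_consensus()] result (or any \code{consensus_seq}).
#' @param reference_genes list of [target_seq()] objects.
#' @param min_identity minimum column identity, default 0.25.
#' @param min_coverage minimum fraction of the reference covered by the
#'   alignment footprint, default 0.5.
#' @param flank search-window widening around a hint, default 100 bp.
#' @param hints optional named list \code{gene -> c(start, end)} (0-based
#'   half-open) of approximate gene coordinates.
#' @param params alignment scoring.
#' @return Data frame: \code{sample_id}, \code{gene}, \code{found},
#'   \code{start}, \code{end} (0-based half-open on the consensus),
#'   \code{identity}, \code{seq}.
#' @export
annotate_genes <- function(consensus, reference_genes, min_identity = 0.25,
                           min_coverage = 0.5, flank = 100L, hints = NULL,
                           params = alignment_params()) {
  stopifnot(inherits(consensus, "consensus_seq"), length(reference_genes) > 0L)
  L <- nchar(consensus$seq)
  rows <- lapply(reference_genes, function(rg) {
    win <- c(0L, L)
    h <- hints[[rg$gene]]
    if (!is.null(h)) win <- c(max(0L, h[1] - flank), min(L, h[2] + flank))
    window_seq <- substr(consensus$seq, win[1] + 1L, win[2])
    absent <- data.frame(sample_id = consensus$sample_id, gene = rg$gene,
                         found = FALSE, start = NA_integer_, end = NA_integer_,
                         identity = NA_real_, seq = NA_character_,
                         stringsAsFactors = FALSE)
    if (nchar(window_seq) == 0L) return(absent)
    aln <- local_align(rg$seq, window_seq, params)
    if (aln$score <= 0 || aln$n_columns == 0L) return(absent)
    idy <- aln_identity(aln, "columns")
    ref_cov <- (aln$footprint_a[2] - aln$footprint_a[1]) / nchar(rg$seq)
    if (idy < min_identity || ref_cov < min_coverage) return(absent)
    st <- win[1] + aln$footprint_b[1]; en <- win[1] + aln$footprint_b[2]
    data.frame(sample_id = consensus$sample_id, gene = rg$gene, found = TRUE,
               start = st, end = en, identity = idy,
               seq = substr(consensus$seq, st + 1L, en),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
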