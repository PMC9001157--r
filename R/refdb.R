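#' Default 20-gene chloroplast target panel
#'
#' Gene regions commonly targeted for plant barcoding by capture panels,
#' headed by the standard barcoding loci. Every function taking a panel
#' accepts a user-supplied character vector instead; nothing in the package
#' logic assumes this particular membership.
#'
#' @return Character vector of 20 gene-region names.
#' @export
default_gene_panel <- function() {
  c("matK", "rbcL", "trnH-psbA", "ndhC", "psbA", "psbH", "psbZ", "rpoC1",
    "petD", "rpl16", "petA", "atpF", "atpH", "accD", "psbK", "ndhF",
    "psbD", "psbE", "rpl32", "ndhJ")
}

taxonomy_ranks <- c("species", "genus", "family", "order", "class")
taxonomy_cols <- c("sample_id", taxonomy_ranks, "location")

#' Multi-locus reference database
#'
#' Couples a five-rank taxonomy table with per-(sample, gene) consensus
#' sequences over a configured gene panel. Sequences may contain \code{N}
#' for depth-masked positions; a (sample, gene) combination that was not
#' recovered is simply absent.
#'
#' @param taxa data frame with columns \code{sample_id}, \code{species},
#'   \code{genus}, \code{family}, \code{order}, \code{class},
#'   \code{location}; sample ids unique, rank fields non-empty.
#' @param sequences data frame with columns \code{sample_id}, \code{gene},
#'   \code{seq} (strings over \code{A,C,G,T,N}); (sample, gene) unique, every
#'   sample present in \code{taxa}, every gene in \code{gene_panel}.
#' @param gene_panel ordered character vector of target gene names.
#' @return A \code{refdb} object.
#' @seealso [read_refdb()], [write_refdb()], [recovery_matrix()]
#' @export
refdb <- function(taxa, sequences, gene_panel = default_gene_panel()) {
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  if (!all(taxonomy_cols %in% names(taxa)))
    stop("taxonomy must have columns: ", paste(taxonomy_cols, collapse = ", "))
  taxa <- taxa[, taxonomy_cols]
  if (anyDuplicated(taxa$sample_id))
    stop("duplicate sample_id in taxonomy: ",
         taxa$sample_id[duplicated(taxa$sample_id)][1])
  for (r in taxonomy_ranks)
    if (any(is.na(taxa[[r]]) | taxa[[r]] == ""))
      stop("empty ", r, " field in taxonomy")
  sequences <- as.data.frame(sequences, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "gene", "seq") %in% names(sequences)))
  bad <- setdiff(sequences$sample_id, taxa$sample_id)
  if (length(bad)) stop("sequence sample not in taxonomy: ", bad[1])
  bad <- setdiff(sequences$gene, gene_panel)
  if (length(bad)) stop("gene not in panel: ", bad[1])
  key <- paste(sequences$sample_id, sequences$gene, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample, gene) record: ",
         sub("\r", " / ", key[duplicated(key)][1]))
  if (any(sequences$seq == "" | is.na(sequences$seq)))
    stop("empty sequence for ",
         sequences$sample_id[which(sequences$seq == "" | is.na(sequences$seq))[1]])
  sequences$seq <- toupper(sequences$seq)
  if (any(grepl("[^ACGTN]", sequences$seq)))
    stop("sequence contains characters outside A,C,G,T,N")
  m <- matrix(NA_character_, nrow(taxa), length(gene_panel),
              dimnames = list(taxa$sample_id, gene_panel))
  m[cbind(sequences$sample_id, sequences$gene)] <- sequences$seq
  structure(list(taxa = taxa, seq_matrix = m, gene_panel = gene_panel),
            class = "refdb")
}

# vectorized sequence lookup; NA where a (sample, gene) is absent
db_get_seq <- function(db, sample_id, gene) {
  if (length(gene) == 1L) db$seq_matrix[sample_id, gene]
  else db$seq_matrix[sample_id, gene]
}

# long-format view of the stored sequences (panel order, then sample order)
db_sequences <- function(db) {
  idx <- which(!is.na(db$seq_matrix), arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  data.frame(sample_id = rownames(db$seq_matrix)[idx[, "row"]],
             gene = colnames(db$seq_matrix)[idx[, "col"]],
             seq = db$seq_matrix[idx], stringsAsFactors = FALSE)
}

#' @export
print.refdb <- function(x, ...) {
  cat(sprintf("refdb: %d samples, %d gene panel, %d sequences\n",
              nrow(x$taxa), length(x$gene_panel), sum(!is.na(x$seq_matrix))))
  cat(sprintf("ranks: %d species, %d genera, %d families, %d orders, %d classes\n",
              length(unique(x$taxa$species)), length(unique(x$taxa$genus)),
              length(unique(x$taxa$family)), length(unique(x$taxa$order)),
              length(unique(x$taxa$class))))
  invisible(x)
}

#' @export
summary.refdb <- function(object, ...) {
  print(object)
  rec <- recovery_matrix(object)
  cat(sprintf("genes recovered per sample: min %d, max %d, mean %.1f\n",
              rec$min, rec$max, rec$mean))
  invisible(rec)
}

#' Read a reference database from FASTA + taxonomy TSV
#'
#' FASTA headers must be \code{sample_id|gene}; the taxonomy TSV must carry
#' the columns \code{sample_id}, \code{species}, \code{genus}, \code{family},
#' \code{order}, \code{class}, \code{location}. Malformed headers, unknown
#' samples and duplicate records raise errors naming the offending record.
#'
#' @param fasta_path path to the sequence FASTA.
#' @param taxonomy_path path to the taxonomy TSV.
#' @param gene_panel gene panel; defaults to the genes present in the FASTA,
#'   in order of first appearance.
#' @return A [refdb] object.
#' @export
read_refdb <- function(fasta_path, taxonomy_path, gene_panel = NULL) {
  taxa <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  fa <- seqinr::read.fasta(fasta_path, as.string = TRUE, forceDNAtolower = FALSE)
  headers <- vapply(fa, function(s) attr(s, "name"), "")
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed FASTA header (want sample_id|gene): ", headers[bad[1]])
  sequences <- data.frame(sample_id = vapply(parts, `[[`, "", 1L),
                          gene = vapply(parts, `[[`, "", 2L),
                          seq = toupper(unlist(fa, use.names = FALSE)),
                          stringsAsFactors = FALSE)
  if (is.null(gene_panel)) gene_panel <- unique(sequences$gene)
  refdb(taxa, sequences, gene_panel)
}

#' Write a reference database to FASTA + taxonomy TSV
#'
#' The inverse of [read_refdb()]: \code{write_refdb()} then \code{read_refdb()}
#' reproduces the database exactly.
#'
#' @param db a [refdb] object.
#' @param fasta_path,taxonomy_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_refdb <- function(db, fasta_path, taxonomy_path) {
  stopifnot(inherits(db, "refdb"))
  sq <- db_sequences(db)
  seqinr::write.fasta(as.list(sq$seq), paste(sq$sample_id, sq$gene, sep = "|"),
                      fasta_path, nbchar = 80)
  utils::write.table(db$taxa, taxonomy_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta_path, taxonomy = taxonomy_path))
}

#' Gene-recovery matrix and summary
#'
#' A gene counts as recovered for a sample when a consensus sequence exists
#' and its fraction of unambiguous (non-\code{N}) bases is at least
#' \code{min_unambiguous_fraction}. Returns the samples-by-genes presence
#' matrix together with per-sample counts and per-gene recovery rates.
#'
#' @param db a [refdb] object.
#' @param min_unambiguous_fraction minimum non-\code{N} fraction for a
#'   sequence to count (default 0.5).
#' @return A \code{recovery_summary}: \code{matrix} (logical), per-sample
#'   \code{counts}, \code{min}/\code{max}/\code{mean}, and per-gene
#'   \code{gene_rate}.
#' @export
recovery_matrix <- function(db, min_unambiguous_fraction = 0.5) {
  stopifnot(inherits(db, "refdb"), nrow(db$taxa) > 0L)
  m <- db$seq_matrix
  frac_ok <- function(s) {
    if (is.na(s)) return(FALSE)
    1 - lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s) >=
      min_unambiguous_fraction
  }
  rec <- apply(m, c(1, 2), frac_ok)
  counts <- rowSums(rec)
  structure(list(matrix = rec, counts = counts,
                 min = min(counts), max = max(counts), mean = mean(counts),
                 gene_rate = colMeans(rec)),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("gene recovery over %d samples x %d genes\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("genes per sample: min %d, max %d, mean %.2f\n",
              x$min, x$max, x$mean))
  cat("per-gene recovery rate:\n")
  print(round(x$gene_rate, 3))
  invisible(x)
}

#' Recovery heatmap
#'
#' Presence/absence image of the recovery matrix, samples on the y-axis and
#' panel genes on the x-axis.
#'
#' @param x a \code{recovery_summary}.
#' @param ... passed to [graphics::image()].
#' @export
plot.recovery_summary <- function(x, ...) {
  m <- x$matrix
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]) * 1,
                  col = c("white", "#2c7fb8"), axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 2, cex.axis = 0.4)
  graphics::box()
  invisible(x)
}
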