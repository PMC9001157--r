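#' Simulation configuration
#'
#' Fixes every knob of the synthetic study generator: the nested taxonomy
#' counts, the gene panel with per-gene lengths and rate multipliers, the
#' K2P substitution parameters, the rank-structured divergence depths, the
#' gene dropout rate, and the pileup model. Everything downstream is
#' reproducible byte-identically from (config, seed).
#'
#' Rank divergences are the expected K2P distance between two samples whose
#' most recent common ancestor sits at that rank (so \code{species} is the
#' within-species divergence); they must increase strictly with rank.
#'
#' @param seed integer master seed.
#' @param n_classes,orders_per_class,families_per_order,genera_per_family,species_per_genus,samples_per_species
#'   nested taxonomy counts. \code{species_per_genus} and
#'   \code{samples_per_species} may be vectors, recycled across genera /
#'   species to produce uneven designs.
#' @param n_samples optional total-sample trim: keep only the first
#'   \code{n_samples} rows of the generated taxonomy.
#' @param gene_panel gene-region names.
#' @param gene_lengths named lengths per gene; default drawn uniformly from
#'   \code{length_range} under the seed.
#' @param length_range range gene lengths are drawn from (default 180-900 bp,
#'   typical for capture-targeted chloroplast regions).
#' @param kappa transition/transversion rate ratio (default 3, a typical
#'   plastid value).
#' @param rank_divergences named expected K2P depths
#'   (species/genus/family/order/class), plus \code{root_divergence} for
#'   between-class pairs.
#' @param root_divergence expected distance between samples of different
#'   classes (default 0.35).
#' @param per_gene_rate_multipliers named positive multipliers; default
#'   lognormal (sdlog 0.3) under the seed, emulating among-gene rate
#'   variation.
#' @param dropout_rate probability a (sample, gene) sequence is missing
#'   (default 0.1, giving ~18 of 20 genes recovered on average).
#' @param pileup list: \code{mean_depth}, \code{depth_sd},
#'   \code{error_rate}, and the quality mixture (\code{base_q_hi/lo},
#'   \code{p_base_lo}, \code{map_q_hi/lo}, \code{p_map_lo}).
#' @return A \code{sim_config} object.
#' @export
sim_config <- function(seed = 1L,
                       n_classes = 2L, orders_per_class = 2L,
                       families_per_order = 2L, genera_per_family = 2L,
                       species_per_genus = 2L, samples_per_species = 3L,
                       n_samples = NULL,
                       gene_panel = default_gene_panel(),
                       gene_lengths = NULL,
                       length_range = c(180L, 900L),
                       kappa = 3,
                       rank_divergences = c(species = 0.001, genus = 0.02,
                                            family = 0.08, order = 0.15,
                                            class = 0.25),
                       root_divergence = 0.35,
                       per_gene_rate_multipliers = NULL,
                       dropout_rate = 0.1,
                       pileup = list(mean_depth = 120, depth_sd = 30,
                                     error_rate = 0.01,
                                     base_q_hi = 40L, base_q_lo = 20L, p_base_lo = 0.1,
                                     map_q_hi = 60L, map_q_lo = 20L, p_map_lo = 0.05)) {
  stopifnot(kappa > 0, dropout_rate >= 0, dropout_rate < 1,
            all(rank_divergences > 0),
            all(diff(rank_divergences[c("species", "genus", "family",
                                        "order", "class")]) > 0),
            root_divergence > rank_divergences["class"],
            pileup$error_rate >= 0, pileup$error_rate < 0.5)
  seed <- as.integer(seed)
  if (is.null(gene_lengths))
    gene_lengths <- with_seed(seed + 17L, stats::setNames(
      sample(length_range[1]:length_range[2], length(gene_panel), replace = TRUE),
      gene_panel))
  if (is.null(per_gene_rate_multipliers))
    per_gene_rate_multipliers <- with_seed(seed + 29L, stats::setNames(
      exp(stats::rnorm(length(gene_panel), 0, 0.3)), gene_panel))
  stopifnot(all(per_gene_rate_multipliers > 0),
            setequal(names(gene_lengths), gene_panel))
  structure(list(seed = seed, n_classes = n_classes,
                 orders_per_class = orders_per_class,
                 families_per_order = families_per_order,
                 genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus,
                 samples_per_species = samples_per_species,
                 n_samples = n_samples,
                 gene_panel = gene_panel,
                 gene_lengths = gene_lengths[gene_panel],
                 kappa = kappa, rank_divergences = rank_divergences,
                 root_divergence = root_divergence,
                 per_gene_rate_multipliers = per_gene_rate_multipliers[gene_panel],
                 dropout_rate = dropout_rate, pileup = pileup),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config (seed %d): %d genes, dropout %.2f, kappa %.1f\n",
              x$seed, length(x$gene_panel), x$dropout_rate, x$kappa))
  invisible(x)
}

locations <- c("SiteA", "SiteB", "SiteC", "SiteD")

#' Simulate a nested five-rank taxonomy
#'
#' Builds sample records nested class > order > family > genus > species,
#' with deterministic names (\code{Cls01}, \code{Ord01_01}, ...,
#' \code{Sp01_01_01}) and cyclic location labels appended to sample ids.
#'
#' @param config a [sim_config()].
#' @return Taxonomy data frame with the seven [refdb] columns.
#' @export
simulate_taxonomy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  spg <- config$species_per_genus; sps <- config$samples_per_species
  gi <- 0L; si <- 0L
  for (cl in seq_len(config$n_classes))
    for (or in seq_len(config$orders_per_class))
      for (fa in seq_len(config$families_per_order))
        for (ge in seq_len(config$genera_per_family)) {
          gi <- gi + 1L
          n_sp <- spg[(gi - 1L) %% length(spg) + 1L]
          for (sp in seq_len(n_sp)) {
            si <- si + 1L
            n_sa <- sps[(si - 1L) %% length(sps) + 1L]
            for (sa in seq_len(n_sa)) {
              cls <- sprintf("Cls%02d", cl)
              ord <- sprintf("Ord%02d_%02d", cl, or)
              fam <- sprintf("Fam%02d_%02d_%02d", cl, or, fa)
              gen <- sprintf("Gen%s_%02d", sub("^Fam", "", fam), ge)
              spe <- sprintf("Sp%s_%02d", sub("^Gen", "", gen), sp)
              loc <- locations[(sa - 1L) %% length(locations) + 1L]
              rows[[length(rows) + 1L]] <- data.frame(
                sample_id = paste0(spe, "_s", sa, "_", loc),
                species = spe, genus = gen, family = fam, order = ord,
                class = cls, location = loc, stringsAsFactors = FALSE)
            }
          }
        }
  taxa <- do.call(rbind, rows)
  if (!is.null(config$n_samples)) {
    stopifnot(config$n_samples <= nrow(taxa))
    taxa <- taxa[seq_len(config$n_samples), ]
  }
  rownames(taxa) <- NULL
  taxa
}

# K2P single-branch evolution of integer-coded sequences (0=A,1=C,2=G,3=T).
# d is the expected substitutions/site on the branch; kappa = alpha/beta.
k2p_evolve <- function(codes, d, kappa) {
  if (d <= 0) return(codes)
  beta <- d / (kappa + 2)
  alpha <- kappa * beta
  e4b <- exp(-4 * beta)
  e2ab <- exp(-2 * (alpha + beta))
  p_ts <- 0.25 + 0.25 * e4b - 0.5 * e2ab
  p_tv <- 0.25 - 0.25 * e4b          # each of the two transversions
  u <- stats::runif(length(codes))
  out <- codes
  ts <- u < p_ts
  tv1 <- !ts & u < p_ts + p_tv
  tv2 <- !ts & !tv1 & u < p_ts + 2 * p_tv
  out[ts] <- (codes[ts] + 2L) %% 4L        # A<->G, C<->T
  out[tv1] <- (codes[tv1] + 1L) %% 4L      # opposite-parity neighbours
  out[tv2] <- (codes[tv2] + 3L) %% 4L
  out
}

codes_to_string <- function(codes) {
  paste(c("A", "C", "G", "T")[codes + 1L], collapse = "")
}

#' Simulate sequences under the rank-structured K2P model
#'
#' For each gene: a uniform-composition root sequence evolves down the
#' ultrametric taxonomy tree under a continuous-time K2P model (transition/
#' transversion ratio \code{kappa}), with branch lengths set so that the
#' expected K2P distance between two samples equals the configured
#' divergence of their most recent common rank, scaled by the gene's rate
#' multiplier. No indels are introduced, so simulated homologs are
#' column-true without alignment.
#'
#' @param config a [sim_config()].
#' @return A \code{sim_truth}: \code{taxonomy}, \code{sequences}
#'   (gene -> named character vector by sample), \code{expected_distance}
#'   (samples x samples matrix of unscaled tree path lengths; multiply by a
#'   gene's rate multiplier for per-gene truth), and the \code{config}.
#' @export
simulate_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  taxa <- simulate_taxonomy(config)
  rd <- config$rank_divergences
  # node heights above the tips (half the expected distance through the node)
  h <- c(species = unname(rd["species"]) / 2, genus = unname(rd["genus"]) / 2,
         family = unname(rd["family"]) / 2, order = unname(rd["order"]) / 2,
         class = unname(rd["class"]) / 2, root = config$root_divergence / 2)
  seqs <- with_seed(config$seed + 101L, {
    lapply(stats::setNames(config$gene_panel, config$gene_panel), function(g) {
      mult <- config$per_gene_rate_multipliers[[g]]
      len <- config$gene_lengths[[g]]
      root <- sample(0:3, len, replace = TRUE)
      out <- vector("list", nrow(taxa))
      # walk the nested taxonomy, evolving one branch per rank transition
      for (cls in unique(taxa$class)) {
        s_cls <- k2p_evolve(root, (h["root"] - h["class"]) * mult, config$kappa)
        t1 <- taxa[taxa$class == cls, ]
        for (ord in unique(t1$order)) {
          s_ord <- k2p_evolve(s_cls, (h["class"] - h["order"]) * mult, config$kappa)
          t2 <- t1[t1$order == ord, ]
          for (fam in unique(t2$family)) {
            s_fam <- k2p_evolve(s_ord, (h["order"] - h["family"]) * mult, config$kappa)
            t3 <- t2[t2$family == fam, ]
            for (gen in unique(t3$genus)) {
              s_gen <- k2p_evolve(s_fam, (h["family"] - h["genus"]) * mult, config$kappa)
              t4 <- t3[t3$genus == gen, ]
              for (spe in unique(t4$species)) {
                s_spe <- k2p_evolve(s_gen, (h["genus"] - h["species"]) * mult, config$kappa)
                idx <- which(taxa$species == spe)
                for (i in idx)
                  out[[i]] <- codes_to_string(
                    k2p_evolve(s_spe, h["species"] * mult, config$kappa))
              }
            }
          }
        }
      }
      stats::setNames(vapply(out, identity, ""), taxa$sample_id)
    })
  })
  # unscaled expected pairwise distance: twice the MRCA height
  n <- nrow(taxa)
  ed <- matrix(0, n, n, dimnames = list(taxa$sample_id, taxa$sample_id))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    mrca <- if (taxa$class[i] != taxa$class[j]) "root"
      else if (taxa$order[i] != taxa$order[j]) "class"
      else if (taxa$family[i] != taxa$family[j]) "order"
      else if (taxa$genus[i] != taxa$genus[j]) "family"
      else if (taxa$species[i] != taxa$species[j]) "genus"
      else "species"
    ed[i, j] <- ed[j, i] <- 2 * h[[mrca]]
  }
  structure(list(taxonomy = taxa, sequences = seqs,
                 expected_distance = ed, config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d samples x %d genes (seed %d)\n",
              nrow(x$taxonomy), length(x$sequences), x$config$seed))
  invisible(x)
}

#' Apply gene dropout to simulated truth
#'
#' Drops each (sample, gene) independently with the configured rate,
#' guaranteeing at least one gene per sample (a sample losing everything is
#' redrawn, up to 100 times). The realized dropout mask is attached to the
#' returned database as attribute \code{"dropout_mask"}.
#'
#' @param truth a [simulate_sequences()] result.
#' @param config a [sim_config()]; defaults to the truth's own.
#' @return A [refdb] with the surviving sequences.
#' @export
apply_dropout <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  taxa <- truth$taxonomy
  genes <- config$gene_panel
  keep <- with_seed(config$seed + 211L, {
    m <- matrix(stats::runif(nrow(taxa) * length(genes)) >= config$dropout_rate,
                nrow(taxa), length(genes), dimnames = list(taxa$sample_id, genes))
    for (i in seq_len(nrow(m))) {
      tries <- 0L
      while (!any(m[i, ])) {
        tries <- tries + 1L
        if (tries > 100L) stop("dropout rate leaves samples empty after 100 redraws")
        m[i, ] <- stats::runif(length(genes)) >= config$dropout_rate
      }
    }
    m
  })
  idx <- which(keep, arr.ind = TRUE)
  sequences <- data.frame(
    sample_id = rownames(keep)[idx[, "row"]],
    gene = colnames(keep)[idx[, "col"]],
    seq = vapply(seq_len(nrow(idx)), function(k)
      truth$sequences[[colnames(keep)[idx[k, "col"]]]][[idx[k, "row"]]], ""),
    stringsAsFactors = FALSE)
  db <- refdb(taxa, sequences, genes)
  attr(db, "dropout_mask") <- !keep
  db
}

#' Simulate a pileup for one true sequence
#'
#' Per position the read depth is a rounded, zero-truncated normal; each
#' observation carries the true base with probability \code{1 - error_rate}
#' (else a uniformly chosen other base) and base/mapping qualities drawn
#' from the configured two-point mixtures, so a controllable fraction fails
#' the quality-30 filters.
#'
#' @param true_seq nucleotide string (the sequence being resequenced).
#' @param config a [sim_config()] (the \code{pileup} component is used).
#' @param seed RNG seed for this pileup; default derived from the config.
#' @return List: \code{observations} (data frame as read by
#'   [read_pileup()]), \code{true_seq}.
#' @export
simulate_pileup <- function(true_seq, config, seed = config$seed + 307L) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$pileup
  true_codes <- match(strsplit(toupper(true_seq), "")[[1]], c("A", "C", "G", "T")) - 1L
  stopifnot(!anyNA(true_codes))
  L <- length(true_codes)
  obs <- with_seed(seed, {
    depth <- pmax(0L, as.integer(round(stats::rnorm(L, p$mean_depth, p$depth_sd))))
    pos <- rep.int(0:(L - 1L), depth)
    tb <- rep.int(true_codes, depth)
    n <- length(pos)
    err <- stats::runif(n) < p$error_rate
    shift <- sample(1:3, n, replace = TRUE)
    base <- ifelse(err, (tb + shift) %% 4L, tb)
    data.frame(position = pos,
               base = c("A", "C", "G", "T")[base + 1L],
               base_q = ifelse(stats::runif(n) < p$p_base_lo, p$base_q_lo, p$base_q_hi),
               map_q = ifelse(stats::runif(n) < p$p_map_lo, p$map_q_lo, p$map_q_hi),
               stringsAsFactors = FALSE)
  })
  list(observations = obs, true_seq = toupper(true_seq))
}

#' Simulate one sequence pair at a fixed K2P divergence
#'
#' Two sequences descended from a common uniform-composition ancestor, each
#' along a branch of \code{d / 2} expected substitutions per site under the
#' K2P model, so their expected pairwise divergence is \code{d}. Useful for
#' calibrating the distance estimator.
#'
#' @param d true expected K2P distance between the pair.
#' @param length sequence length (sites).
#' @param kappa transition/transversion rate ratio.
#' @param seed RNG seed.
#' @return List of two nucleotide strings \code{a} and \code{b}.
#' @examples
#' p <- simulate_k2p_pair(0.05, 2000, kappa = 3, seed = 1)
#' k2p(site_counts(p$a, p$b))
#' @export
simulate_k2p_pair <- function(d, length, kappa = 3, seed = 1L) {
  stopifnot(d >= 0, length > 0, kappa > 0)
  with_seed(seed, {
    root <- sample(0:3, length, replace = TRUE)
    a <- k2p_evolve(root, d / 2, kappa)
    b <- k2p_evolve(root, d / 2, kappa)
    list(a = codes_to_string(a), b = codes_to_string(b))
  })
}

#' Simulate a complete reference database
#'
#' Convenience wrapper: [simulate_sequences()] then [apply_dropout()].
#'
#' @param config a [sim_config()].
#' @return List: \code{db} (a [refdb]), \code{truth} (a \code{sim_truth}).
#' @export
simulate_refdb <- function(config) {
  truth <- simulate_sequences(config)
  list(db = apply_dropout(truth, config), truth = truth)
}
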