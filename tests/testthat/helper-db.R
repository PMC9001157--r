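# shared fixture builders

mk_taxa <- function(ids, species = ids, genus = "GenA", family = "FamA",
                    order = "OrdA", class = "ClsA", location = "SiteA") {
  data.frame(sample_id = ids, species = species, genus = genus, family = family,
             order = order, class = class, location = location,
             stringsAsFactors = FALSE)
}

# build a refdb from a list gene -> named vector (sample -> sequence)
db_from_seqs <- function(taxa, gene_seqs, panel = names(gene_seqs)) {
  seqs <- do.call(rbind, lapply(names(gene_seqs), function(g) {
    v <- gene_seqs[[g]]
    data.frame(sample_id = names(v), gene = g, seq = unname(v),
               stringsAsFactors = FALSE)
  }))
  refdb(taxa, seqs, panel)
}
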