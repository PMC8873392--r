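# Shared fixtures, all built in code.

toy_taxon_table <- function() {
  counts <- rbind(
    s1 = c(Bifidobacterium = 10, Blautia = 20, Faecalibacterium = 30,
           Escherichia = 40),
    s2 = c(Bifidobacterium = 5, Blautia = 0, Faecalibacterium = 15,
           Escherichia = 80)
  )
  taxonomy <- data.frame(
    genus = c("Bifidobacterium", "Blautia", "Faecalibacterium", "Escherichia"),
    phylum = c("Actinobacteria", "Firmicutes", "Firmicutes", "Proteobacteria"),
    stringsAsFactors = FALSE
  )
  taxon_table(counts, taxonomy)
}

random_taxon_table <- function(n_samples = 10, n_genera = 8, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_genera, lambda = 40),
                   n_samples, n_genera,
                   dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                   paste0("g", seq_len(n_genera))))
  taxonomy <- data.frame(
    genus = colnames(counts),
    phylum = rep(c("Firmicutes", "Bacteroidetes"), length.out = n_genera),
    stringsAsFactors = FALSE
  )
  taxon_table(counts, taxonomy)
}

small_cohort <- function(n = 60, seed = 1, ...) {
  simulate_cohort(simulation_config(n_subjects = n, seed = seed, ...))
}

# per-(subject, time point) CLR value of one genus, as a feature table for
# lagged_dataset()
genus_clr_feature <- function(sc, genus, pseudocount = 0.5) {
  do.call(rbind, lapply(names(sc$taxon_tables), function(tp) {
    ct <- clr(sc$taxon_tables[[tp]]$counts, pseudocount = pseudocount)
    d <- data.frame(
      subject_id = sub(paste0("_", tp, "$"), "", rownames(ct)),
      time_point = tp, value = ct[, genus], stringsAsFactors = FALSE)
    names(d)[3] <- genus
    d
  }))
}
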