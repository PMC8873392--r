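test_that("relative abundances are proportions that sum to one", {
  tt <- toy_taxon_table()
  ra <- relative_abundance(tt, "genus")
  expect_equal(unname(ra["s1", ]), c(0.1, 0.2, 0.3, 0.4))
  # single-genus sample
  single <- taxon_table(matrix(7, 1, 1, dimnames = list("s", "g")),
                        data.frame(genus = "g", phylum = "Firmicutes"))
  expect_equal(unname(relative_abundance(single)[1, 1]), 1)
  # property: random tables, rows sum to 1
  for (seed in 1:5) {
    ra <- relative_abundance(random_taxon_table(seed = seed))
    expect_true(all(abs(rowSums(ra) - 1) < 1e-12))
    expect_true(all(ra >= 0 & ra <= 1))
  }
  # all-zero sample names the offender
  bad <- toy_taxon_table()
  bad$counts["s2", ] <- 0
  expect_error(relative_abundance(bad), "s2")
})

test_that("phylum-level aggregation respects the taxonomy map", {
  tt <- toy_taxon_table()
  ph <- relative_abundance(tt, "phylum")
  expect_equal(unname(ph["s1", "Firmicutes"]), 0.5)  # 20 + 30 of 100
  expect_equal(unname(ph["s1", "Actinobacteria"]), 0.1)
})

test_that("F/B ratio divides phylum proportions and is undefined at zero Bacteroidetes", {
  props <- rbind(a = c(Firmicutes = 0.6, Bacteroidetes = 0.2, Other = 0.2),
                 b = c(Firmicutes = 0.5, Bacteroidetes = 0.0, Other = 0.5),
                 c = c(Firmicutes = 0.3, Bacteroidetes = 0.3, Other = 0.4))
  r <- fb_ratio(props)
  expect_equal(unname(r["a"]), 3.0)
  expect_true(is.na(r["b"]))          # infinite ratio -> missing, not error
  expect_equal(unname(r["c"]), 1.0)
  # reciprocal identity when both defined
  swapped <- props[, c("Bacteroidetes", "Firmicutes", "Other")]
  colnames(swapped) <- c("Firmicutes", "Bacteroidetes", "Other")
  both <- !is.na(r) & !is.na(fb_ratio(swapped))
  expect_equal(unname(r[both] * fb_ratio(swapped)[both]), rep(1, sum(both)))
  expect_error(fb_ratio(props[, -2]), "Bacteroidetes")
})

test_that("clr matches its formula, sums to zero, and is scale invariant", {
  expect_equal(clr(c(1, 1, 1, 1)), c(0, 0, 0, 0))
  expect_equal(clr(c(2, 8)), c(-log(2), log(2)), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:10) {
    x <- rpois(12, 30) + 1
    expect_lt(abs(sum(clr(x))), 1e-9)
    k <- runif(1, 0.1, 10)
    expect_equal(clr(k * x), clr(x), tolerance = 1e-9)
  }
  expect_error(clr(c(0, 1, 2)), "pseudocount")
  expect_error(clr(c(-1, 2)), "non-negative")
  # matrix form is row-wise
  m <- rbind(a = c(2, 8), b = c(1, 1))
  expect_equal(clr(m)["a", ], clr(c(2, 8)))
})

test_that("SCFA sum score aggregates proxy counts then CLR-transforms", {
  counts <- rbind(s1 = c(Bifidobacterium = 10, Blautia = 20,
                         Faecalibacterium = 30, Escherichia = 40))
  tax <- data.frame(
    genus = colnames(counts),
    phylum = c("Actinobacteria", "Firmicutes", "Firmicutes", "Proteobacteria"))
  tt <- taxon_table(counts, tax)
  pc <- 0.5
  score <- suppressWarnings(scfa_sum_score(tt, pseudocount = pc))
  # hand oracle: modified table is (SCFA_sum = 60, Escherichia = 40)
  expect_equal(unname(score["s1"]),
               log(60 + pc) - mean(log(c(60, 40) + pc)), tolerance = 1e-12)
  # all features equal after summing -> CLR score 0
  counts2 <- rbind(s1 = c(Bifidobacterium = 20, Blautia = 20, Escherichia = 40))
  tt2 <- taxon_table(counts2, tax[tax$genus %in% colnames(counts2), ])
  expect_equal(unname(suppressWarnings(
    scfa_sum_score(tt2, pseudocount = 0))["s1"]), 0)
})

test_that("SCFA sum score is invariant to proxy ordering and flags missing proxies", {
  tt <- toy_taxon_table()
  proxy <- scfa_producers()
  present <- proxy[proxy$genus %in% colnames(tt$counts), ]
  s1 <- suppressWarnings(scfa_sum_score(tt, proxy))
  s2 <- scfa_sum_score(tt, present[rev(seq_len(nrow(present))), ])
  expect_equal(as.numeric(s1), as.numeric(s2))
  # partial overlap warns and lists a missing genus
  expect_warning(scfa_sum_score(tt, proxy), "Subdoligranulum")
  # no proxy genus at all -> error
  none <- data.frame(genus = "Methanobrevibacter", scfa = "none")
  expect_error(scfa_sum_score(tt, none), "Methanobrevibacter")
  # no non-proxy genus left -> error
  all_prox <- data.frame(genus = colnames(tt$counts), scfa = "x")
  expect_error(scfa_sum_score(tt, all_prox), "non-proxy")
})

test_that("observed richness counts nonzero genera", {
  counts <- rbind(s1 = c(g1 = 0, g2 = 5, g3 = 0, g4 = 1),
                  s2 = c(g1 = 0, g2 = 0, g3 = 0, g4 = 0))
  tax <- data.frame(genus = paste0("g", 1:4), phylum = "Firmicutes")
  r <- observed_richness(taxon_table(counts, tax))
  expect_equal(unname(r), c(2L, 0L))
  # oracle on random masks
  set.seed(3)
  tt <- random_taxon_table(seed = 9)
  tt$counts[sample(length(tt$counts), 30)] <- 0
  expect_equal(unname(observed_richness(tt)),
               unname(apply(tt$counts, 1, function(x) sum(x != 0))))
})

test_that("abundance filter zeroes sub-threshold entries in a single pass", {
  tt <- toy_taxon_table()
  expect_equal(abundance_filter(tt, 0)$counts, tt$counts)
  # one genus at 0.05% with a 0.1% threshold is zeroed
  counts <- rbind(s1 = c(g1 = 1, g2 = 1999))  # g1 at 0.05%
  tax <- data.frame(genus = c("g1", "g2"), phylum = "Firmicutes")
  filtered <- abundance_filter(taxon_table(counts, tax), 0.001)
  expect_equal(unname(filtered$counts["s1", "g1"]), 0)
  expect_equal(unname(filtered$counts["s1", "g2"]), 1999)
  expect_error(abundance_filter(tt, 1), "\\[0, 1\\)")
})

test_that("composition feature bundle is coherent across its parts", {
  tt <- small_cohort(n = 20, seed = 5)$taxon_tables[["10y"]]
  f <- composition_features(tt)
  expect_equal(f$fb_ratio[!is.na(f$fb_ratio)],
               (f$firmicutes / f$bacteroidetes)[!is.na(f$fb_ratio)])
  expect_true(all(f$richness <= ncol(tt$counts)))
  gc <- attr(f, "genus_clr")
  expect_true(all(abs(rowSums(gc)) < 1e-9))
})
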