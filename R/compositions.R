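# Compositional microbiota features: relative abundances, F/B ratio, CLR,
# the aggregated SCFA-producer score, observed richness.

#' Relative abundances at genus or phylum level
#'
#' @param tt a [taxon_table()].
#' @param level `"genus"` or `"phylum"`; phylum-level abundances aggregate
#'   genus counts through the taxonomy map before normalising.
#' @return matrix of proportions (samples x taxa); rows sum to 1.
#' @export
relative_abundance <- function(tt, level = c("genus", "phylum")) {
  level <- match.arg(level)
  m <- tt$counts
  if (level == "phylum") {
    ph <- phylum_of(tt)
    m <- t(rowsum(t(m), group = ph))
  }
  totals <- rowSums(m)
  zero <- totals == 0
  stop_if(any(zero), "all-zero sample(s): %s",
          paste(rownames(m)[zero], collapse = ", "))
  m / totals
}

#' Firmicutes/Bacteroidetes ratio
#'
#' The F/B ratio divides the relative abundance of phylum Firmicutes by that
#' of Bacteroidetes. When a sample contains no Bacteroidetes the ratio is
#' undefined (an infinity, not a number); such samples are returned as `NA`
#' and excluded from downstream ratio analyses rather than floored.
#'
#' @param phylum_props matrix of phylum relative abundances with columns
#'   including `Firmicutes` and `Bacteroidetes` (see [relative_abundance()]).
#' @return named numeric vector, `NA` where Bacteroidetes is absent.
#' @export
fb_ratio <- function(phylum_props) {
  stop_if(!all(c("Firmicutes", "Bacteroidetes") %in% colnames(phylum_props)),
          "phylum proportions must include Firmicutes and Bacteroidetes")
  f <- phylum_props[, "Firmicutes"]
  b <- phylum_props[, "Bacteroidetes"]
  out <- ifelse(b > 0, f / b, NA_real_)
  names(out) <- rownames(phylum_props)
  out
}

#' Centered log-ratio transform
#'
#' `clr(x) = log(x + pc) - mean(log(x + pc))`, natural log. Maps a
#' composition to unconstrained real space; components sum to zero.
#'
#' @param x non-negative numeric vector, or a matrix transformed row-wise.
#' @param pseudocount value added to every entry before taking logs; must be
#'   positive when zeros are present.
#' @return transformed vector or matrix of the same shape.
#' @export
clr <- function(x, pseudocount = 0) {
  stop_if(pseudocount < 0, "pseudocount must be >= 0")
  if (is.matrix(x)) return(t(apply(x, 1, clr, pseudocount = pseudocount)))
  stop_if(any(x < 0), "counts must be non-negative")
  stop_if(pseudocount == 0 && any(x == 0),
          "zero counts require a positive pseudocount")
  lx <- log(x + pseudocount)
  lx - mean(lx)
}

#' Aggregated SCFA-producer score
#'
#' Raw counts of all proxy (SCFA-producer) genera are summed into a single
#' `SCFA_sum` feature which replaces them in the table; the modified table
#' (`SCFA_sum` plus all non-proxy genera) is CLR-transformed and the
#' `SCFA_sum` component returned as the per-sample score.
#'
#' @param tt a [taxon_table()].
#' @param proxy proxy definition: data.frame with a `genus` column; defaults
#'   to the curated list in [scfa_producers()].
#' @param pseudocount added to every entry of the modified table before CLR.
#' @return numeric vector of per-sample scores; the full CLR-transformed
#'   modified table is attached as attribute `"clr_table"`.
#' @export
scfa_sum_score <- function(tt, proxy = scfa_producers(), pseudocount = 0.5) {
  stop_if(nrow(proxy) == 0, "proxy definition is empty")
  stop_if(anyDuplicated(proxy$genus) > 0, "proxy genus names must be unique")
  key <- genus_key(colnames(tt$counts))
  pk <- genus_key(proxy$genus)
  hit <- key %in% pk
  missing <- setdiff(pk, key)
  stop_if(sum(hit) == 0, "no proxy genera found in table; missing: %s",
          paste(proxy$genus[pk %in% missing], collapse = ", "))
  if (length(missing) > 0) {
    warning(sprintf("proxy genera absent from table: %s",
                    paste(proxy$genus[pk %in% missing], collapse = ", ")),
            call. = FALSE)
  }
  stop_if(all(hit), "table has no non-proxy genera to centre against")
  modified <- cbind(SCFA_sum = rowSums(tt$counts[, hit, drop = FALSE]),
                    tt$counts[, !hit, drop = FALSE])
  ct <- clr(modified, pseudocount = pseudocount)
  score <- ct[, "SCFA_sum"]
  names(score) <- rownames(tt$counts)
  attr(score, "clr_table") <- ct
  score
}

#' Observed richness
#'
#' Number of genera with nonzero count per sample.
#'
#' @param tt a [taxon_table()].
#' @return integer vector named by sample.
#' @export
observed_richness <- function(tt) {
  out <- as.integer(rowSums(tt$counts > 0))
  names(out) <- rownames(tt$counts)
  out
}

#' Minimum relative abundance filter
#'
#' Per sample, counts whose within-sample proportion falls below the
#' threshold are zeroed (single pass: proportions are taken against the
#' original totals, so surviving entries are not re-checked against the new
#' total).
#'
#' @param tt a [taxon_table()].
#' @param min_rel_abundance threshold in `[0, 1)`; e.g. `0.001` for 0.1%.
#' @return filtered [taxon_table()].
#' @export
abundance_filter <- function(tt, min_rel_abundance = 0.001) {
  stop_if(min_rel_abundance < 0 || min_rel_abundance >= 1,
          "threshold must be in [0, 1)")
  if (min_rel_abundance == 0) return(tt)
  totals <- rowSums(tt$counts)
  prop <- tt$counts / ifelse(totals == 0, 1, totals)
  cleaned <- tt$counts
  cleaned[prop < min_rel_abundance] <- 0
  taxon_table(cleaned, tt$taxonomy)
}

#' Per-sample composition feature bundle
#'
#' Convenience wrapper computing every feature the downstream analyses use:
#' phylum relative abundances of Firmicutes and Bacteroidetes, the F/B ratio
#' (`NA` when undefined), the CLR-transformed SCFA-producer sum score,
#' CLR values of Firmicutes and Bacteroidetes phylum counts, and observed
#' richness.
#'
#' @param tt a [taxon_table()].
#' @param proxy proxy definition passed to [scfa_sum_score()].
#' @param pseudocount CLR pseudocount.
#' @param clr_scope `"modified"` (CLR on the proxy-modified table, the
#'   default) or `"full"` (CLR on the unmodified genus table) for the
#'   genus-level CLR matrix attached as attribute `"genus_clr"`.
#' @return data.frame with one row per sample.
#' @export
composition_features <- function(tt, proxy = scfa_producers(),
                                 pseudocount = 0.5,
                                 clr_scope = c("modified", "full")) {
  clr_scope <- match.arg(clr_scope)
  ph <- relative_abundance(tt, "phylum")
  getcol <- function(m, nm) if (nm %in% colnames(m)) m[, nm] else rep(0, nrow(m))
  score <- scfa_sum_score(tt, proxy = proxy, pseudocount = pseudocount)
  ph_counts <- t(rowsum(t(tt$counts), group = phylum_of(tt)))
  ph_clr <- clr(ph_counts, pseudocount = pseudocount)
  out <- data.frame(
    sample_id = rownames(tt$counts),
    firmicutes = getcol(ph, "Firmicutes"),
    bacteroidetes = getcol(ph, "Bacteroidetes"),
    fb_ratio = fb_ratio(ph),
    scfa_sum_clr = as.numeric(score),
    firmicutes_clr = getcol(ph_clr, "Firmicutes"),
    bacteroidetes_clr = getcol(ph_clr, "Bacteroidetes"),
    richness = observed_richness(tt),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "genus_clr") <- if (clr_scope == "modified")
    attr(score, "clr_table") else clr(tt$counts, pseudocount = pseudocount)
  out
}
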