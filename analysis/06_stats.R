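#!/usr/bin/env Rscript
# Cross-genotype statistical comparisons with FDR control.
#
# Collects the per-unit tables from the earlier stages (per-fly choice
# means, per-cell FF ratios, per-fly tau among rhythmic flies) and runs the
# two-group workflow on every genotype pair: Anderson-Darling normality
# dispatch to a one-tailed t-test (pooled or Welch by F-test) or
# Mann-Whitney U, then Benjamini-Hochberg adjustment within each family at
# q = 0.1 and the two-tier significance labels (black from raw p, red from
# FDR-adjusted p).

library(crylight)

out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fams <- list()

choice <- read.delim("results/choice/flies.tsv")
fams$choice_percent_lit <- list(data = choice[!choice$excluded, ],
                                value = "mean_percent_lit")

cells <- read.delim("results/ephys/cells.tsv")
fams$ephys_ff_ratio <- list(data = cells[cells$ff_defined, ],
                            value = "ff_ratio")

flies <- read.delim("results/locomotor/flies.tsv")
rhyth <- flies[flies$rhythmic, ]
keep <- names(which(table(rhyth$genotype) >= 3))
fams$locomotor_tau <- list(data = rhyth[rhyth$genotype %in% keep, ],
                           value = "tau_h")

comparisons <- do.call(rbind, lapply(names(fams), function(fam) {
  f <- fams[[fam]]
  compare_groups(f$data, f$value, "genotype", tail = "greater",
                 q = 0.1, family = fam)
}))
write.table(comparisons, file.path(out, "comparisons.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (fam in unique(comparisons$family)) {
  cf <- comparisons[comparisons$family == fam, ]
  message(sprintf("%s: %d contrasts, %d pass FDR (q <= 0.1)",
                  fam, nrow(cf), sum(cf$fdr_pass)))
  hits <- cf[cf$fdr_pass, ]
  if (nrow(hits))
    message(paste(sprintf("  %s vs %s: %s, p = %.3g (FDR %.3g) %s",
                          hits$group_a, hits$group_b, hits$test_used,
                          hits$p_raw, hits$p_fdr, hits$tier_red),
                  collapse = "\n"))
}
message("tables written under ", out)
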