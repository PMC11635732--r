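#!/usr/bin/env Rscript
# Score the two item batteries, apply the inclusion filter, cross-classify,
# and tabulate the 16 joint subcategories.

suppressPackageStartupMessages(library(foodsecx))

tab <- read_microdata_csv("results/synth/microdata.csv")
tab <- apply_inclusion_filter(tab)
cat("exclusions:", paste(names(attr(tab, "exclusions")),
                         attr(tab, "exclusions"), collapse = "; "), "\n")

tab <- classify_table(tab)
tab <- build_multiyear_weights(tab, 6)
write_microdata(tab, "results/synth/classified.csv")

sub <- tabulate_subcategories(tab$afssm_cat, tab$pfs_cat)
write.csv(as.data.frame(sub), "results/appendix_subcategories.csv",
          row.names = FALSE)
cat("joint category counts:\n")
print(table(tab$crossclass_cat))
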