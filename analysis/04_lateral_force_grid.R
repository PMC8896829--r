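#!/usr/bin/env Rscript
# Active vs passive lateral shortening forces in the constriction domain.
#
# Grid over KL_active (myosin-dependent, zero-rest-length springs, zeroed
# on in-silico inhibition) and KL_passive (elastic restoration springs,
# insensitive to inhibition): how much of the cell-shortening force can be
# myosin-dependent, and how the residual passive elasticity shapes the
# furrow after inhibition.

library(furrowsim)

out_dir <- "results/lateral_grid"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

tab <- sweep_lateral(KL_active_values = c(0, 2),
                     KL_passive_values = c(0.2, 2, 20))
utils::write.csv(tab, file.path(out_dir, "lateral_grid.csv"),
                 row.names = FALSE)
print(tab)

late <- tab[tab$KL_active == 2, c("KL_passive", "D_final_late")]
late <- late[order(-late$KL_passive), ]
message("Late-inhibition depth at KL_active = 2:")
for (i in seq_len(nrow(late)))
  message(sprintf("  KL_passive = %5.1f -> D = %.1f um",
                  late$KL_passive[i], late$D_final_late[i]))
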