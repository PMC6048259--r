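#!/usr/bin/env Rscript

# Build the four study systems -- wild-type and mutant toy dimers, each free
# or clamped -- and record exactly which parameters the mutation touches.
#
# Writes: results/systems/*.pdb, results/mutation_parameter_diff.tsv

library(deltabind)

out <- "results/systems"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

seed <- 101L
wt <- build_toy_dimer(5, 4, "WT", seed = seed)
mut <- build_toy_dimer(5, 4, "MUT", seed = seed)

write_pdb(wt, file.path(out, "wt_free.pdb"))
write_pdb(mut, file.path(out, "mut_free.pdb"))
write_pdb(apply_clamp(wt), file.path(out, "wt_clamped.pdb"))
write_pdb(apply_clamp(mut), file.path(out, "mut_clamped.pdb"))

diff <- variant_parameter_diff(wt, mut)
write.table(diff, "results/mutation_parameter_diff.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ref <- reference_configurations(wt)
e <- c(wt_bound = potential_energy(wt, ref$bound)$total,
       wt_dissociated = potential_energy(wt, ref$dissociated)$total,
       mut_bound = potential_energy(mut, ref$bound)$total,
       mut_dissociated = potential_energy(mut, ref$dissociated)$total)

cat("Built 4 systems (", nrow(wt$pos), "beads each ).\n")
cat("The mutation changes", nrow(diff), "parameters:",
    paste(unique(diff$what), collapse = ", "), "\n")
cat(sprintf("Reference energies (kcal/mol): WT bound %.2f vs dissociated %.2f;",
            e["wt_bound"], e["wt_dissociated"]), "\n")
cat(sprintf("  MUT bound %.2f -- the mutant interface is %.2f kcal/mol weaker.\n",
            e["mut_bound"], e["mut_bound"] - e["wt_bound"]))
write.table(data.frame(configuration = names(e), energy_kcal_mol = e),
            "results/reference_energies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
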