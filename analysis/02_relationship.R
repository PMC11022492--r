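#!/usr/bin/env Rscript

## Relationship machinery for the replicate written by 01_simulate.R: builds
## the honeybee relationship factor over queens, sire entries and worker
## groups, exports the sparse inverse and inbreeding coefficients, verifies
## A * A^-1 = I on probe columns, and cross-checks the recursion against
## gene dropping on a mixed toy pedigree.

library(apisim)

out <- "results/replicate"
ped <- read_pedigree(file.path(out, "pedigree.tsv"))

fac <- build_factor(ped)          # per-mating latent sires (production mode)
print(fac)
Ainv <- invert_factor(fac)
export_sparse(Ainv, file.path(out, "ainv.mtx"))
write.table(inbreeding(fac), file.path(out, "inbreeding.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

set.seed(2)
cols <- sample(fac$n, 200)
E <- matrix(0, fac$n, length(cols)); E[cbind(cols, seq_along(cols))] <- 1
err <- max(abs(relationship_matvec(fac, as.matrix(Ainv %*% E)) - E))
cat("max |A A^-1 e - e| over", length(cols), "probe columns:",
    format(err, digits = 3), "\n")

## gene-dropping oracle on a toy covering identified single-sire (S=1, D=8),
## pseudo-sire (S=3, D=8) and open-group matings
toy <- rbind(
  ped_row(1, "QUEEN"), ped_row(2, "QUEEN"), ped_row(3, "QUEEN"),
  ped_row(4, "MATE", style = "OPEN_GROUP", S = 10, D = 8),
  ped_row(5, "MATE", style = "IDENTIFIED_DPQ", member = 2, S = 1, D = 8),
  ped_row(6, "WORKER_GROUP", dam = 1, sire_entry = 5),
  ped_row(7, "QUEEN", dam = 1, sire_entry = 5, birth_year = 1),
  ped_row(8, "QUEEN", dam = 1, sire_entry = 5, birth_year = 1),
  ped_row(9, "MATE", style = "PS_GROUP", dpq_dam = 3, dpq_dam_mate = 4,
          S = 3, D = 8),
  ped_row(10, "WORKER_GROUP", dam = 7, sire_entry = 9),
  ped_row(11, "QUEEN", dam = 7, sire_entry = 9, birth_year = 2),
  ped_row(12, "QUEEN", dam = 8, sire_entry = 9, birth_year = 2),
  ped_row(13, "MATE", style = "IDENTIFIED_DPQ", member = 11, S = 1, D = 8),
  ped_row(14, "WORKER_GROUP", dam = 12, sire_entry = 13),
  ped_row(15, "QUEEN", dam = 12, sire_entry = 13, birth_year = 3))
gd <- gene_drop_check(toy, n_loci = 1e5, seed = 42)
cat("gene dropping vs analytic A (1e5 loci):\n")
cat("  max |analytic - empirical|:", format(gd$max_abs_dev, digits = 3), "\n")
cat("  max deviation in SE units: ", format(gd$max_z, digits = 3), "\n")
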