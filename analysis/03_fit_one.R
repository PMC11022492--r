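#!/usr/bin/env Rscript

## Genetic evaluation of the replicate from 01_simulate.R under the
## correctly specified sire model (SS simulation, identified single sires):
## AI-REML variance components, BLUP breeding values, genetic trends.

library(apisim)

out <- "results/replicate"
ped <- read_pedigree(file.path(out, "pedigree.tsv"))
perf <- read_performance(file.path(out, "performance.tsv"))
truth <- read.delim(file.path(out, "queens_truth.tsv"))

fac <- build_factor(ped)
model <- build_model(perf, fac)
fit <- reml_fit(model, fac)
print(fit)

truthpar <- c(var_w = 10, var_q = 10, var_e = 30)
err <- 100 * (fit$estimates[names(truthpar)] - truthpar) / truthpar
cat("relative errors of variances (%):\n")
print(round(err, 2))
cat("error of r_wq (absolute, truth 0):", round(fit$r_wq, 3), "\n")

ebv <- ebv_table(fit, fac, ped)
## queens_truth ids map to pedigree ids through the performance file
qmap <- integer(nrow(truth))
qmap[perf$colony_id] <- perf$queen_id
bq <- truth[truth$role == "BQ", ]
bq$ped_id <- qmap[bq$id]
## queens without their own record: recover ids via their dam's offspring
## ordering is not needed for trends — restrict to mapped queens
bq <- bq[bq$ped_id > 0, ]
eb <- ebv[match(bq$ped_id, ebv$ped_id), ]
tt <- genetic_trend(data.frame(year = bq$year, w = bq$bw, q = bq$bq))
te <- genetic_trend(data.frame(year = bq$year, w = eb$ebv_w, q = eb$ebv_q))
cat("genetic trend, true:      worker", round(tt[["w"]], 3),
    " queen", round(tt[["q"]], 3), "\n")
cat("genetic trend, estimated: worker", round(te[["w"]], 3),
    " queen", round(te[["q"]], 3), "\n")
cat("trend error (%):          worker",
    round(100 * (te[["w"]] - tt[["w"]]) / tt[["w"]], 1), " queen",
    round(100 * (te[["q"]] - tt[["q"]]) / tt[["q"]], 1), "\n")

res <- data.frame(parameter = names(fit$estimates),
                  estimate = unname(fit$estimates),
                  pred_se = unname(fit$se_pred))
write.table(res, file.path(out, "reml_estimates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ebv, file.path(out, "ebv.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("written:", out, "/{reml_estimates,ebv}.tsv\n")
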