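#!/usr/bin/env Rscript
# Stage 3: evolutionary inference on the species tip values.
#
# Mixed-model tip values (species cell means, colony random intercepts) ->
# divide-by-mean standardization -> Brownian-motion rate per level with a
# paired bootstrap rate comparison; PGLS and sensitivity PGLS for the
# colony/individual pair of each trait; phenospace disparity (sum of
# variances over jointly standardized rhythmicity x period axes).
#
# Usage: Rscript analysis/03_comparative_inference.R [--seed N]
#        [--metrics FILE] [--tree FILE] [--n-boot N] [--out DIR]

suppressPackageStartupMessages(library(rhythmevo))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1L]
}
seed <- as.integer(arg("--seed", "1"))
metrics_file <- arg("--metrics", "results/metrics.csv")
tree_file <- arg("--tree", "results/study/chronogram.nwk")
n_boot <- as.integer(arg("--n-boot", "10000"))
out <- arg("--out", "results")

metrics <- read.csv(metrics_file, stringsAsFactors = FALSE)
tree <- ape::read.tree(tree_file)

tips <- species_tip_values(metrics)
write.csv(tips, file.path(out, "tip_values.csv"), row.names = FALSE)

message("bootstrap rate comparisons (n_boot = ", n_boot, ") ...")
rates <- list(
  rhythmicity = bootstrap_rate_comparison(metrics, tree, "rhythmicity",
                                          n_boot = n_boot, seed = seed),
  period = bootstrap_rate_comparison(metrics, tree, "period",
                                     n_boot = n_boot, seed = seed + 1L))
for (tr in names(rates)) print(rates[[tr]])

as_named <- function(col) setNames(tips[[col]], tips$species)
sd_of <- function(col, lv) {
  d <- metrics[metrics$level == lv, ]
  vapply(split(d[[col]], d$species),
         function(v) if (length(v) > 1) sd(v) else 0, numeric(1))
}
pg <- list(
  rhythmicity = pgls(tree, as_named("individual_rhythmicity"),
                     as_named("colony_rhythmicity")),
  period = pgls(tree, as_named("individual_period_min"),
                as_named("colony_period_min")))
sens <- list(
  rhythmicity = sensitivity_pgls(
    tree, as_named("individual_rhythmicity"), as_named("colony_rhythmicity"),
    x_sd = sd_of("beta", "individual"), y_sd = sd_of("beta", "colony"),
    n_iter = n_boot, seed = seed + 2L),
  period = sensitivity_pgls(
    tree, as_named("individual_period_min"), as_named("colony_period_min"),
    x_sd = sd_of("dominant_period_min", "individual"),
    y_sd = sd_of("dominant_period_min", "colony"),
    n_iter = n_boot, seed = seed + 3L))
for (tr in names(pg)) { print(pg[[tr]]); print(sens[[tr]]) }

phen <- function(prefix) {
  m <- as.matrix(tips[, paste0(prefix, c("_rhythmicity", "_period_min"))])
  dimnames(m) <- list(tips$species, c("rhythmicity", "period"))
  m
}
disp <- disparity_comparison(phen("colony"), phen("individual"),
                             n_boot = n_boot, seed = seed + 4L)
print(disp)

summarize_rate <- function(r)
  list(trait = r$trait, sigma2_colony = r$sigma2_colony,
       sigma2_individual = r$sigma2_individual, p_value = r$p_value,
       n_boot = r$n_boot, summary = r$summary)
jsonlite::write_json(list(
  seed = seed, n_boot = n_boot,
  rates = lapply(rates, summarize_rate),
  pgls = lapply(pg, unclass),
  sensitivity = lapply(sens, function(s)
    list(median_p = s$median_p, median_slope = s$median_slope,
         n_iter = s$n_iter)),
  disparity = list(colony = disp$sum_of_variances_colony,
                   individual = disp$sum_of_variances_individual,
                   p_value = disp$p_value, summary = disp$summary)),
  file.path(out, "inference.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("wrote ", file.path(out, "inference.json"))
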