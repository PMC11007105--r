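#!/usr/bin/env Rscript
# Step 1: build the synthetic study world.
#
# A 12-protein inflammatory panel (Olink-style pQTL GWAS, N = 14,824) is
# screened against seven binary outcomes: a large T2D discovery cohort
# (74,124 cases / 824,006 controls), a smaller replication cohort
# (9,978 / 12,348), and five T2D-complication endpoints with
# FinnGen-R9-shaped case counts. Four proteins carry true causal effects on
# T2D (log-OR per SD chosen to echo the odds ratios such screens report:
# OR 1.16, 0.87, 0.96, 1.30); the complication effects are concentrated in
# the same four proteins. Every outcome also carries 60 polygenic loci of
# its own that act on no protein — these are what make the reverse
# (outcome-as-exposure) analysis of step 3 meaningful.
#
# Outputs (results/data/): per-trait summary-statistics TSVs in the format
# gwas_io reads, the confounder exclusion list for step 3, and the ground
# truth as JSON.

suppressPackageStartupMessages(library(mrscreen))

seed <- 20240328
out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

protein_t2d <- c(TGFA = 0.148, FGF21 = -0.139, GDNF = -0.041, CX3CL1 = 0.262,
                 setNames(rep(0, 8), paste0("null_", 1:8)))
proteins <- names(protein_t2d)

complication_effects <- rbind(
  #          keto  renal  ophth  neuro periph   (log-OR per SD)
  TGFA   = c(1.295, 0,    0.307, 0.637, 0),
  FGF21  = c(0,     0,    0,    -0.261, 0),
  GDNF   = c(0,     0,    0,     0,     0.215),
  CX3CL1 = c(0,     0,    0,     0,     0)
)
complications <- c("t2d_keto", "t2d_renal", "t2d_ophth", "t2d_neuro",
                   "t2d_periph")
colnames(complication_effects) <- complications

effects <- matrix(0, nrow = length(proteins), ncol = 2 + length(complications),
                  dimnames = list(proteins,
                                  c("t2d_discovery", "t2d_replication",
                                    complications)))
effects[, "t2d_discovery"] <- protein_t2d
effects[, "t2d_replication"] <- protein_t2d
effects[rownames(complication_effects), complications] <- complication_effects

outcome_defs <- list(
  t2d_discovery   = list(cases = 74124, controls = 824006, n = 898130),
  t2d_replication = list(cases = 9978,  controls = 12348,  n = 22326),
  t2d_keto        = list(cases = 657,   controls = 308280, n = 308937),
  t2d_renal       = list(cases = 2684,  controls = 308280, n = 310964),
  t2d_ophth       = list(cases = 4172,  controls = 308280, n = 312452),
  t2d_neuro       = list(cases = 1894,  controls = 308280, n = 310174),
  t2d_periph      = list(cases = 2179,  controls = 308280, n = 310459)
)

study <- simulate_screen_study(effects, outcome_defs,
                               n_snps = 60, outcome_own_loci = 60,
                               prop_palindromic = 0.05, prop_swapped = 0.2,
                               seed = seed)

for (p in names(study$exposures))
  write_summary_stats(study$exposures[[p]],
                      file.path(out_dir, paste0("exposure_", p, ".tsv")))
for (o in names(study$outcomes))
  write_summary_stats(study$outcomes[[o]]$records,
                      file.path(out_dir, paste0("outcome_", o, ".tsv")))

# Offline stand-in for a PhenoScanner-style confounder lookup, used by the
# reverse analysis: every protein-instrument SNP is flagged so that reverse
# instruments are the outcomes' own loci only.
writeLines(sort(unlist(study$truth$instruments)),
           file.path(out_dir, "protein_instruments_exclusion.txt"))

jsonlite::write_json(
  list(seed = seed, effects = as.data.frame(effects),
       outcome_defs = outcome_defs),
  file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat(sprintf("wrote %d exposure files, %d outcome files to %s\n",
            length(study$exposures), length(study$outcomes), out_dir))
cat(sprintf("true non-null protein -> T2D effects: %s\n",
            paste(sprintf("%s %.3f", names(protein_t2d)[protein_t2d != 0],
                          protein_t2d[protein_t2d != 0]), collapse = ", ")))
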