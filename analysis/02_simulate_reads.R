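#!/usr/bin/env Rscript

# Simulate paired amplicon reads for two donor conditions over one knock-in
# locus: a high-efficiency long-ssDNA-like condition and a low-efficiency
# ssODN-like condition. Emits FASTQ pairs, truth tables and the locus/edit
# configuration under results/sim/<condition>/.

suppressMessages(library(hdrquant))
dir.create("results", showWarnings = FALSE)

le <- simulate_locus(1)
cat("Simulated locus:", nchar(le$locus$amplicon_seq), "nt amplicon,",
  "Coding-bar enzyme", le$edit$introduced_enzyme, "\n")

conditions <- list(
  lssDNA_like = simulation_config(seed = 101, n_reads = 20000, per_base_error = 0.001),
  ssODN_like = simulation_config(
    seed = 102, n_reads = 20000, per_base_error = 0.001,
    class_proportions = c(
      WT = 0.820, Correct_HDR = 0.005, Incorrect_HDR_substitution = 0.005,
      Incorrect_HDR_indel = 0.010, NHEJ_indel = 0.160
    )
  )
)

for (nm in names(conditions)) {
  out_dir <- file.path("results", "sim", nm)
  sim <- simulate_reads(le$locus, le$edit, conditions[[nm]], out_dir = out_dir)
  tab <- table(sim$truth$true_class)
  cat("\n", nm, ": ", nrow(sim$r1), " read pairs -> ", out_dir, "\n", sep = "")
  print(tab)
}
cat("\nwrote results/sim/<condition>/{R1.fastq,R2.fastq,truth.tsv,locus.yaml}\n")
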