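#!/usr/bin/env Rscript
# Simulate digests of the three pectin substrates by a panel of synthetic
# lyase variants differing in subsite tolerance, and record product
# composition counts over time plus A235 progress curves.
#
# The enzyme panel is a mechanistic caricature of a multigene lyase
# family: variants share the {+1,+3} methyl preference but differ in the
# partial rate for +1-only sites (rho), in acetyl tolerance, and in
# overall turnover. Finding: faster/less picky variants shift product
# mass into short oligomers sooner; the acetyl-tolerant variant keeps
# producing on the highly acetylated substrate.

library(pelprofiler)
dir.create("results", showWarnings = FALSE)
seed <- 20260929

enzymes <- data.frame(
  enzyme = c("vPelA", "vPelB", "vPelC", "vPelD", "vPelF_ac"),
  rho = c(0.25, 0.35, 0.05, 0.10, 0.25),
  acetyl_penalty = c(0.5, 0.5, 0.5, 0.3, 0.9),
  rate_constant = c(1.0, 1.5, 0.02, 0.3, 0.4)
)
substrates <- c("apple", "citrus", "sugarbeet")
time_points <- c(0, 5 / 1440, 20 / 1440, 120 / 1440, 1)  # fraction of run

all_counts <- list()
all_traces <- list()
for (sub in substrates) {
  preset <- pectin_presets(sub)
  spec <- substrate_spec(200, 50, dm = preset$dm, dac = preset$dac,
                         methyl_pattern = "blockwise", block_length = 4L)
  for (e in seq_len(nrow(enzymes))) {
    chains <- generate_chains(spec, seed = seed + e)
    rule <- cleavage_rule(rho = enzymes$rho[e],
                          acetyl_penalty = enzymes$acetyl_penalty[e])
    dig <- simulate_digest(chains, rule,
                           rate_constant = enzymes$rate_constant[e],
                           time_points = time_points,
                           seed = seed + 100 * e)
    for (s in dig$snapshots) {
      cc <- s$compositions
      cc$enzyme <- enzymes$enzyme[e]; cc$substrate <- sub
      cc$time <- s$time
      all_counts[[length(all_counts) + 1L]] <- cc
    }
    tr <- absorbance_trace(dig)
    tr$enzyme <- enzymes$enzyme[e]; tr$substrate <- sub
    all_traces[[length(all_traces) + 1L]] <- tr
  }
}
counts <- do.call(rbind, all_counts)
traces <- do.call(rbind, all_traces)
write.csv(counts, "results/digest_compositions.csv", row.names = FALSE)
write.csv(traces, "results/a235_traces.csv", row.names = FALSE)
cat("wrote", nrow(counts), "composition count rows and",
    nrow(traces), "A235 trace rows\n")

final <- counts[counts$time == max(counts$time) & counts$unsaturated &
                  counts$dp <= 4, ]
agg <- aggregate(count ~ enzyme + substrate, final, sum)
cat("short unsaturated products (DP <= 4) at end of run:\n")
print(agg[order(agg$substrate, -agg$count), ], row.names = FALSE)
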